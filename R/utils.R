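#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pf pchisq qchisq qbeta quantile rnbinom rpois
#'   rbinom runif rnorm uniroot optimize nlminb p.adjust fisher.test
#'   setNames dhyper lm ks.test rbeta complete.cases sd var aggregate
#' @importFrom utils head tail
NULL

# round to 3 significant figures, the convention used for dose labels
# (0.316, 3.16, 31.6, ...)
signif3 <- function(x) signif(x, 3)

# format a dose for use in sample ids / display: 3 sig figs, no sci notation
# below 1e5
format_dose <- function(x) {
  vapply(x, function(d) {
    if (d == 0) return("0")
    format(signif3(d), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

# evaluate `expr` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    abort("a finite integer `seed` is required")
  }
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# wide feature-by-sample tibble (feature_id + one column per sample) -> matrix
as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot_cols(x, "feature_id", "counts/matrix table")
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

# matrix -> wide tibble, preserving attributes passed through `attrs`
as_feature_tibble <- function(m, attrs = NULL) {
  out <- tibble(feature_id = rownames(m) %||% character(0))
  out <- dplyr::bind_cols(out, as_tibble(m, .name_repair = "minimal"))
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  out
}
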