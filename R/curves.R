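# Dose-response curve families on the log2-response scale.
#
# The same evaluators serve both the synthetic-data truth tables and the
# fitting engine, so recovered parameters are directly comparable with the
# generating ones. All curves are functions of dose on the natural (uM)
# scale, not log-dose. `dose_scale` rescales dose inside the power family
# only (d/dose_scale)^p, which keeps the coefficient box well conditioned
# during fitting; with dose_scale = 1 the parameterization is the natural
# one.

CURVE_FAMILIES <- c("null", "linear", "poly2", "poly3", "power", "hill",
                    "exp", "exp3")

# number of mean parameters per family
n_mean_params <- function(family) {
  switch(family,
    null = 1L, linear = 2L, poly2 = 3L, poly3 = 4L,
    power = 3L, hill = 4L, exp = 3L, exp3 = 3L,
    abort(sprintf("unknown curve family '%s'", family))
  )
}

#' Evaluate a dose-response curve
#'
#' @param family One of `"null"`, `"linear"`, `"poly2"`, `"poly3"`,
#'   `"power"`, `"hill"`, `"exp3"` (alias `"exp"`).
#' @param params Numeric parameter vector. `linear`/`poly*`: polynomial
#'   coefficients from intercept upward. `power`: `(a, b, p)` for
#'   `a + b * (d / dose_scale)^p`. `hill`: `(v0, v, k, n)` for
#'   `v0 + v * d^n / (k^n + d^n)`. `exp3`: `(a, b, c)` for
#'   `a + b * (1 - exp(-d / c))`.
#' @param dose Numeric vector of doses (uM).
#' @param dose_scale Dose rescaling used by the power family (default 1).
#' @return Numeric vector of responses on the log2 scale.
#' @export
eval_curve <- function(family, params, dose, dose_scale = 1) {
  p <- as.numeric(params)
  need <- n_mean_params(family)
  if (length(p) < need) {
    abort(sprintf("family '%s' needs %d parameters, got %d",
                  family, need, length(p)))
  }
  switch(family,
    null   = rep(p[1], length(dose)),
    linear = p[1] + p[2] * dose,
    poly2  = p[1] + p[2] * dose + p[3] * dose^2,
    poly3  = p[1] + p[2] * dose + p[3] * dose^2 + p[4] * dose^3,
    power  = p[1] + p[2] * (dose / dose_scale)^p[3],
    hill   = {
      dn <- dose^p[4]
      p[1] + p[2] * ifelse(dose == 0, 0, dn / (p[3]^p[4] + dn))
    },
    exp    = ,
    exp3   = p[1] + p[2] * (1 - exp(-dose / p[3]))
  )
}

# |f(d) - f(0)| as a function of d, used by BMD root finding and truth tables
curve_abs_change <- function(family, params, dose, dose_scale = 1) {
  abs(eval_curve(family, params, dose, dose_scale) -
        eval_curve(family, params, 0, dose_scale))
}
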