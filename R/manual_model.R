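#' Build an age model from explicit coefficients
#'
#' Constructs an `age_model` without fitting, for hypothetical scenarios
#' and toy calculations: supply the coefficients of one of the sex
#' structures, a residual variance, and a weighting. For structure `"v"`,
#' pass per-sex coefficient vectors and variances as named lists.
#'
#' @param coefficients Named numeric vector matching the structure's
#'   design columns (e.g. `c(intercept=, sexM=, age=)` for `"ii"`), or for
#'   `"v"` a list with elements `F` and `M`, each `c(intercept=, age=)`.
#' @param sigma2 Residual variance (unbiased scale); for `"v"` a list with
#'   elements `F` and `M`.
#' @param weighting One of [weightings()].
#' @param sex_model One of [sex_models()].
#' @return An `age_model` usable with [posterior()], [prediction_band()]
#'   and [predict_majority()]. Its coefficient covariance is zero (the
#'   coefficients are taken as known).
#' @export
make_age_model <- function(coefficients, sigma2, weighting = "inv_age",
                           sex_model = "ii") {
  stopifnot(sex_model %in% sex_models(), weighting %in% weightings())
  mk_fit <- function(b, s2) {
    b <- unlist(b)
    structure(list(coefficients = b,
                   vcov = matrix(0, length(b), length(b),
                                 dimnames = list(names(b), names(b))),
                   sigma2 = s2, sigma2_ml = s2, n = NA_integer_,
                   p = length(b), aic = NA_real_,
                   pvalues = setNames(rep(NA_real_, length(b)), names(b))),
              class = "wls_fit")
  }
  expected <- switch(sex_model,
                     i = c("intercept", "age"),
                     ii = c("intercept", "sexM", "age"),
                     iii = c("intercept", "age_F", "age_M"),
                     iv = c("intercept", "sexM", "age_F", "age_M"),
                     v = c("intercept", "age"))
  if (sex_model == "v") {
    stopifnot(is.list(coefficients), all(c("F", "M") %in% names(coefficients)),
              is.list(sigma2))
    for (s in c("F", "M"))
      if (!all(expected %in% names(coefficients[[s]])))
        stop("structure v needs per-sex coefficients named ",
             paste(expected, collapse = ", "))
    fits <- list(F = mk_fit(coefficients$F, sigma2$F),
                 M = mk_fit(coefficients$M, sigma2$M))
  } else {
    if (!all(expected %in% names(coefficients)))
      stop("structure ", sex_model, " needs coefficients named ",
           paste(expected, collapse = ", "))
    fits <- list(mk_fit(coefficients, sigma2))
  }
  structure(list(fits = fits, sex_model = sex_model, weighting = weighting,
                 aic = NA_real_, k = NA_real_,
                 age_pvalues = NA_real_, n = NA_integer_,
                 outcome = NULL, teeth = NULL),
            class = "age_model")
}
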