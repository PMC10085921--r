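#' Enumerate the tooth sets of the exploration grid
#'
#' The four third molars analysed separately, followed by the seven averaged
#' combinations: both uppers, both lowers, the two diagonal pairs, the two
#' ipsilateral pairs, and all four.
#'
#' @return Named list of 11 integer vectors of FDI codes.
#' @export
enumerate_toothsets <- function() {
  sets <- list(18L, 28L, 38L, 48L,
               c(18L, 28L), c(38L, 48L), c(18L, 48L), c(28L, 38L),
               c(18L, 38L), c(28L, 48L), c(18L, 28L, 38L, 48L))
  names(sets) <- vapply(sets, paste, "", collapse = "+")
  sets
}

#' Sex-model structures of the exploration
#'
#' @return Character vector `c("i","ii","iii","iv","v")`: (i) sex not
#'   considered; (ii) sex-specific intercepts, common slope; (iii)
#'   sex-specific slopes, common intercept; (iv) sex-specific slopes and
#'   intercepts; (v) fully separate models per sex (as iv, plus separate
#'   residual variance).
#' @export
sex_models <- function() c("i", "ii", "iii", "iv", "v")

#' Variance weightings of the exploration
#'
#' Weighting names follow the regression weight \eqn{w_i}: `constant`
#' (\eqn{w_i = 1}), `age` (\eqn{w_i = age_i}, residual variance shrinking
#' with age) and `inv_age` (\eqn{w_i = 1/age_i}, residual variance growing
#' proportionally to age).
#'
#' @return Character vector `c("constant","age","inv_age")`.
#' @export
weightings <- function() c("constant", "age", "inv_age")

weight_values <- function(weighting, age) {
  switch(weighting,
         constant = rep(1, length(age)),
         age = age,
         inv_age = 1 / age,
         stop("unknown weighting: ", weighting))
}

#' Design matrix for a sex model
#'
#' Structures i-iv: i `[1, age]`; ii `[1, isMale, age]`; iii
#' `[1, age:F, age:M]`; iv `[1, isMale, age:F, age:M]`. Structure v reuses
#' the model-i design per sex and is assembled at the fitting level.
#'
#' @param series An outcome series (data frame with `sex`, `age_years`).
#' @param sex_model One of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @return Numeric matrix with named columns.
#' @export
design_matrix <- function(series, sex_model) {
  n <- nrow(series)
  if (n == 0) stop("empty series")
  age <- series$age_years
  if (sex_model == "i")
    return(matrix(c(rep(1, n), age), n, 2,
                  dimnames = list(NULL, c("intercept", "age"))))
  is_m <- as.numeric(series$sex == "M")
  if (length(unique(series$sex)) < 2)
    stop("sex model ", sex_model, " requires both sexes in the data")
  switch(sex_model,
         ii = matrix(c(rep(1, n), is_m, age), n, 3,
                     dimnames = list(NULL, c("intercept", "sexM", "age"))),
         iii = matrix(c(rep(1, n), age * (1 - is_m), age * is_m), n, 3,
                      dimnames = list(NULL, c("intercept", "age_F", "age_M"))),
         iv = matrix(c(rep(1, n), is_m, age * (1 - is_m), age * is_m), n, 4,
                     dimnames = list(NULL, c("intercept", "sexM", "age_F", "age_M"))),
         stop("unknown sex model: ", sex_model))
}

#' Weighted least-squares fit
#'
#' Coefficients minimise \eqn{\sum_i w_i (y_i - x_i \beta)^2}. Two residual
#' variance estimates are kept: the maximum-likelihood scale
#' \eqn{\hat\sigma^2_{ML} = \sum w e^2 / n} feeding the AIC, and the
#' unbiased scale \eqn{\sum w e^2 / (n - p)} feeding the coefficient
#' covariance \eqn{\hat\sigma^2 (X'WX)^{-1}} and Wald t tests with
#' \eqn{n - p} degrees of freedom.
#'
#' @param X Full-column-rank design matrix with named columns.
#' @param y Numeric response vector.
#' @param w Positive weights (default all 1).
#' @return Object of class `wls_fit`: `coefficients`, `vcov`, `sigma2`
#'   (unbiased), `sigma2_ml`, `residuals`, `fitted`, `weights`, `n`, `p`,
#'   `df_residual`, `logLik`, `aic` (with k = p + 1 for the variance),
#'   `pvalues`.
#' @export
fit_wls <- function(X, y, w = rep(1, length(y))) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(w) == n)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  if (n <= p) stop("need more observations than coefficients")
  fit <- stats::lm.wfit(X, y, w)
  if (fit$rank < p)
    stop("singular design: rank ", fit$rank, " < ", p, " columns")
  beta <- fit$coefficients
  e <- y - drop(X %*% beta)
  wrss <- sum(w * e^2)
  sigma2_ml <- wrss / n
  sigma2 <- wrss / (n - p)
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(XtWXinv) <- list(colnames(X), colnames(X))
  vc <- sigma2 * XtWXinv
  se <- sqrt(diag(vc))
  tval <- beta / se
  pv <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  if (sigma2_ml <= 0) {
    ll <- Inf      # degenerate: zero residual variance
    aic <- -Inf
  } else {
    ll <- -(n / 2) * log(2 * pi * sigma2_ml) + sum(log(w)) / 2 - n / 2
    aic <- -2 * ll + 2 * (p + 1)
  }
  structure(list(coefficients = beta, vcov = vc, sigma2 = sigma2,
                 sigma2_ml = sigma2_ml, residuals = e,
                 fitted = drop(X %*% beta), weights = w, n = n, p = p,
                 df_residual = n - p, logLik = ll, aic = aic,
                 pvalues = pv), class = "wls_fit")
}

#' @export
logLik.wls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 1, nobs = object$n,
            class = "logLik")
}

#' AIC of a fitted model
#'
#' \eqn{AIC = -2\hat\ell + 2k} with \eqn{k} counting the regression
#' coefficients plus one variance parameter; for sex structure v the AICs
#' (and parameter counts) of the two per-sex fits are summed.
#'
#' @param fit A `wls_fit` or `age_model`.
#' @return AIC value; `-Inf` flags a degenerate zero-variance fit.
#' @export
model_aic <- function(fit) {
  if (inherits(fit, "age_model")) return(fit$aic)
  fit$aic
}

# mu(age, sex) for any fitted structure, vectorised over age
model_mean <- function(model, age, sex) {
  cf <- function(f) f$coefficients
  if (model$sex_model == "v") {
    f <- model$fits[[sex]]
    if (is.null(f)) stop("sex '", sex, "' absent from model")
    b <- cf(f)
    return(b[["intercept"]] + b[["age"]] * age)
  }
  b <- cf(model$fits[[1]])
  is_m <- as.numeric(sex == "M")
  switch(model$sex_model,
         i = b[["intercept"]] + b[["age"]] * age,
         ii = b[["intercept"]] + b[["sexM"]] * is_m + b[["age"]] * age,
         iii = b[["intercept"]] +
           (if (is_m) b[["age_M"]] else b[["age_F"]]) * age,
         iv = b[["intercept"]] + b[["sexM"]] * is_m +
           (if (is_m) b[["age_M"]] else b[["age_F"]]) * age)
}

# residual variance at a given age (and sex, for structure v):
# sigma2 * v(age) with v = 1/w per the model's weighting
model_variance <- function(model, age, sex = NULL) {
  s2 <- if (model$sex_model == "v") {
    if (is.null(sex) || is.null(model$fits[[sex]]))
      stop("structure v needs a sex present in the model")
    model$fits[[sex]]$sigma2
  } else {
    model$fits[[1]]$sigma2
  }
  s2 / weight_values(model$weighting, age)
}

#' Fit one (sex structure, weighting) candidate on an outcome series
#'
#' @param series Outcome series from [outcome_series()].
#' @param sex_model One of [sex_models()].
#' @param weighting One of [weightings()].
#' @return Object of class `age_model`: per-sex or pooled `wls_fit`s, the
#'   summed AIC, and the age p-values (`common`, or `F`/`M`).
#' @export
fit_age_model <- function(series, sex_model = "i", weighting = "constant") {
  stopifnot(sex_model %in% sex_models(), weighting %in% weightings())
  if (sex_model == "v") {
    if (length(unique(series$sex)) < 2)
      stop("sex model v requires both sexes in the data")
    fits <- lapply(c(F = "F", M = "M"), function(s) {
      sub <- series[series$sex == s, , drop = FALSE]
      fit_wls(design_matrix(sub, "i"), sub$y,
              weight_values(weighting, sub$age_years))
    })
    aic <- fits$F$aic + fits$M$aic
    k <- (fits$F$p + 1) + (fits$M$p + 1)
    pvals <- c(F = fits$F$pvalues[["age"]], M = fits$M$pvalues[["age"]])
  } else {
    X <- design_matrix(series, sex_model)
    fit <- fit_wls(X, series$y, weight_values(weighting, series$age_years))
    fits <- list(fit)
    aic <- fit$aic
    k <- fit$p + 1
    pvals <- if (sex_model %in% c("i", "ii")) {
      c(common = fit$pvalues[["age"]])
    } else {
      c(F = fit$pvalues[["age_F"]], M = fit$pvalues[["age_M"]])
    }
  }
  structure(list(fits = fits, sex_model = sex_model, weighting = weighting,
                 aic = aic, k = k, age_pvalues = pvals,
                 n = nrow(series),
                 outcome = attr(series, "outcome"),
                 teeth = attr(series, "teeth")),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("age_model: sex structure %s, weighting %s, n = %d, AIC = %.2f\n",
              x$sex_model, x$weighting, x$n, x$aic))
  cat("  age p-value(s):",
      paste(names(x$age_pvalues),
            format(x$age_pvalues, digits = 3), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

# ranking p-value: common-slope p where there is one; otherwise the larger
# per-sex p (both sexes must carry signal)
ranking_p <- function(model) {
  if (length(model$age_pvalues) == 1) model$age_pvalues[[1]]
  else max(model$age_pvalues)
}

#' Select sex structure and variance weighting by AIC
#'
#' Fits all 15 candidates (5 sex structures x 3 weightings) and returns the
#' minimum-AIC fit. Ties are broken toward fewer parameters, then toward
#' the weighting order constant, age, 1/age.
#'
#' @param series Outcome series from [outcome_series()].
#' @return The winning `age_model`, with the full candidate grid (sex
#'   structure, weighting, AIC, k) in attribute `grid`.
#' @export
select_model <- function(series) {
  grid <- expand.grid(sex_model = sex_models(), weighting = weightings(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      fit_age_model(series, grid$sex_model[i], grid$weighting[i]),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, TRUE)
  grid$aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic, 0)
  grid$k <- vapply(fits, function(f) if (is.null(f)) NA_real_ else as.numeric(f$k), 0)
  usable <- ok & is.finite(grid$aic)
  if (!any(usable)) stop("all candidate fits degenerate: cannot select a model")
  ord <- order(!usable, grid$aic, grid$k,
               match(grid$weighting, weightings()))
  best <- fits[[ord[1]]]
  attr(best, "grid") <- grid
  best
}

#' Run the full exploration over outcomes and tooth sets
#'
#' For each (transformation outcome, tooth set) candidate, builds the ln
#' outcome series, selects sex structure and weighting by AIC, and records
#' the ranking p-value of the age variable. Candidates whose data are
#' insufficient (e.g. too few participants with all member teeth) are
#' recorded as skipped rather than dropped silently.
#'
#' @param cohort Cohort data frame (already filtered of excluded
#'   participants).
#' @param outcomes Spec rows to explore, typically the retained set from
#'   [redundancy_filter()].
#' @param toothsets List of tooth sets (default [enumerate_toothsets()]).
#' @param average Passed to [outcome_series()].
#' @return Object of class `exploration_report`: a data frame with one row
#'   per candidate (`outcome`, `teeth`, `n`, `sex_model`, `weighting`,
#'   `aic`, `p_common`, `p_F`, `p_M`, `p_rank`, `note`), sorted ascending
#'   by `p_rank`, skipped candidates last.
#' @export
explore <- function(cohort, outcomes, toothsets = enumerate_toothsets(),
                    average = c("ratio", "log")) {
  average <- match.arg(average)
  rows <- list()
  for (i in seq_len(nrow(outcomes))) {
    for (ts_name in names(toothsets)) {
      spec <- outcomes[i, ]
      res <- tryCatch({
        series <- outcome_series(cohort, spec, toothsets[[ts_name]], average)
        model <- select_model(series)
        pv <- model$age_pvalues
        data.frame(outcome = spec$label, teeth = ts_name,
                   n = model$n, sex_model = model$sex_model,
                   weighting = model$weighting, aic = model$aic,
                   p_common = if ("common" %in% names(pv)) pv[["common"]] else NA_real_,
                   p_F = if ("F" %in% names(pv)) pv[["F"]] else NA_real_,
                   p_M = if ("M" %in% names(pv)) pv[["M"]] else NA_real_,
                   p_rank = ranking_p(model), note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(outcome = spec$label, teeth = ts_name, n = NA_integer_,
                   sex_model = NA_character_, weighting = NA_character_,
                   aic = NA_real_, p_common = NA_real_, p_F = NA_real_,
                   p_M = NA_real_, p_rank = NA_real_,
                   note = paste("skipped:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  report <- do.call(rbind, rows)
  report <- report[order(is.na(report$p_rank), report$p_rank), ]
  rownames(report) <- NULL
  class(report) <- c("exploration_report", "data.frame")
  report
}

#' Refit the best exploration candidate on a cohort
#'
#' @param cohort Cohort data frame.
#' @param report An `exploration_report`.
#' @param toothsets The tooth-set list used for the exploration.
#' @param average Passed to [outcome_series()].
#' @return The selected `age_model` for the top-ranked candidate.
#' @export
refit_best <- function(cohort, report, toothsets = enumerate_toothsets(),
                       average = c("ratio", "log")) {
  average <- match.arg(average)
  best <- report[!is.na(report$p_rank), ][1, ]
  series <- outcome_series(cohort, best$outcome, toothsets[[best$teeth]],
                           average)
  select_model(series)
}
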