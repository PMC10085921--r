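#' Uniform prior over age
#'
#' The default support, 14.0 to 23.0 years, reflects the age window in
#' which third-molar tissue measurement is informative: below 14 the tooth
#' is not suitable for measurement, and the upper bound trades the risk of
#' falsely classifying a person as older than 18 (raised by a higher upper
#' bound) against the converse.
#'
#' @param lower,upper Support bounds in decimal years.
#' @return Object of class `age_prior`.
#' @export
age_prior <- function(lower = 14.0, upper = 23.0) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("prior requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "age_prior")
}

#' Likelihood of an observed ln ratio at a hypothetical age
#'
#' Normal density of the observation `y` around the fitted mean
#' \eqn{\mu(age, sex)}, with variance \eqn{\hat\sigma^2 v(age)} where
#' \eqn{v} is the inverse of the model's regression weight (so `v = age`
#' under the selected 1/age weighting). The fitted coefficients are
#' conditioned on as known (plug-in); `inflate` optionally adds the
#' mean-prediction variance \eqn{x' \Sigma x} for a sensitivity check.
#'
#' @param y Observed ln outcome value.
#' @param age Age(s) in years at which to evaluate.
#' @param sex `"F"` or `"M"`.
#' @param model A fitted `age_model`.
#' @param inflate Add coefficient uncertainty to the variance.
#' @return Density values, same length as `age`.
#' @export
likelihood <- function(y, age, sex, model, inflate = FALSE) {
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  if (model$sex_model == "v" && is.null(model$fits[[sex]]))
    stop("sex '", sex, "' absent from model")
  mu <- model_mean(model, age, sex)
  v <- model_variance(model, age, sex)
  if (inflate) v <- v + mean_prediction_variance(model, age, sex)
  dnorm(y, mean = mu, sd = sqrt(v))
}

# x' Sigma x for the mean prediction at (age, sex), vectorised over age
mean_prediction_variance <- function(model, age, sex) {
  is_m <- as.numeric(sex == "M")
  if (model$sex_model == "v") {
    f <- model$fits[[sex]]
    X <- cbind(1, age)
  } else {
    f <- model$fits[[1]]
    X <- switch(model$sex_model,
                i = cbind(1, age),
                ii = cbind(1, is_m, age),
                iii = cbind(1, age * (1 - is_m), age * is_m),
                iv = cbind(1, is_m, age * (1 - is_m), age * is_m))
  }
  rowSums((X %*% f$vcov) * X)
}

#' Posterior distribution of age given an observed ln ratio
#'
#' Applies Bayes' theorem on a regular age grid: the posterior density is
#' proportional to likelihood times the uniform prior, normalised by the
#' trapezoidal rule, and zero outside the prior support.
#'
#' @param y Observed ln outcome value (finite).
#' @param sex `"F"` or `"M"`.
#' @param model A fitted `age_model`.
#' @param prior An [age_prior()].
#' @param grid_step Grid resolution in years (default 0.01).
#' @param inflate Passed to [likelihood()].
#' @return Object of class `age_posterior`: `age` (grid), `density`
#'   (normalised), `y`, `sex`, `prior`.
#' @export
posterior <- function(y, sex, model, prior = age_prior(), grid_step = 0.01,
                      inflate = FALSE) {
  if (!is.finite(y)) stop("observed value must be finite")
  grid <- seq(prior$lower, prior$upper, by = grid_step)
  if (grid[length(grid)] < prior$upper) grid <- c(grid, prior$upper)
  # work on the log density so observations far from the regression line
  # (many residual SDs away) do not underflow to an all-zero likelihood
  mu <- model_mean(model, grid, sex)
  v <- model_variance(model, grid, sex)
  if (inflate) v <- v + mean_prediction_variance(model, grid, sex)
  loglik <- dnorm(y, mean = mu, sd = sqrt(v), log = TRUE)
  if (!any(is.finite(loglik)))
    stop("degenerate posterior: likelihood vanishes over the whole prior support")
  lik <- exp(loglik - max(loglik[is.finite(loglik)]))
  dens <- lik / trapz(grid, lik)   # flat prior cancels in the normalisation
  structure(list(age = grid, density = dens, y = y, sex = sex,
                 prior = prior), class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat(sprintf("age_posterior (%s, y = %.4f) on [%.1f, %.1f]: mode %.2f y, P(>18) = %.3f\n",
              x$sex, x$y, x$prior$lower, x$prior$upper,
              posterior_mode(x), prob_over(x)))
  invisible(x)
}

#' Probability that the individual is older than a threshold age
#'
#' Trapezoidal integral of the posterior density above `threshold`; the
#' grid is cut exactly at the threshold by linear interpolation.
#'
#' @param post An [posterior()] result.
#' @param threshold Age threshold in years (default 18, the age of
#'   majority).
#' @return Probability in \[0, 1\].
#' @export
prob_over <- function(post, threshold = 18.0) {
  stopifnot(inherits(post, "age_posterior"))
  a <- post$age; d <- post$density
  if (threshold <= a[1]) {
    if (threshold < a[1])
      warning("threshold below the prior support: probability is exactly 1")
    return(1)
  }
  if (threshold >= a[length(a)]) {
    if (threshold > a[length(a)])
      warning("threshold above the prior support: probability is exactly 0")
    return(0)
  }
  d_thr <- approx(a, d, xout = threshold)$y
  keep <- a > threshold
  min(max(trapz(c(threshold, a[keep]), c(d_thr, d[keep])), 0), 1)
}

#' Posterior mode and median age
#'
#' @param post An `age_posterior`.
#' @return Mode (grid argmax) or median (first grid age at which the
#'   cumulative trapezoidal mass reaches one half) in years.
#' @export
posterior_mode <- function(post) post$age[which.max(post$density)]

#' @rdname posterior_mode
#' @export
posterior_median <- function(post) {
  a <- post$age; d <- post$density
  cum <- c(0, cumsum((d[-1] + d[-length(d)]) * diff(a) / 2))
  a[which(cum >= 0.5)[1]]
}

#' Expectation and prediction band of the selected model
#'
#' The regression expectation \eqn{\mu(age, sex)} with the individual-level
#' band \eqn{\mu \pm level \cdot \sqrt{\hat\sigma^2 v(age)}}; `level = 2`
#' gives the 95% (2 SD) prediction interval. Under the 1/age weighting the
#' band half-width grows with the square root of age.
#'
#' @param model A fitted `age_model`.
#' @param ages Numeric vector of ages in years.
#' @param sex `"F"` or `"M"`.
#' @param level Band half-width in residual standard deviations.
#' @return Data frame `age`, `expectation`, `lower`, `upper`.
#' @export
prediction_band <- function(model, ages, sex, level = 2) {
  mu <- model_mean(model, ages, sex)
  half <- level * sqrt(model_variance(model, ages, sex))
  data.frame(age = ages, expectation = mu, lower = mu - half,
             upper = mu + half)
}

#' Predict majority probabilities for new individuals
#'
#' Hypothetical or measured observations are accepted either as raw ratios
#' (the ln transform is applied internally) or as ln ratios, per `unit`.
#'
#' @param model A fitted `age_model`.
#' @param newdata Data frame with columns `id`, `sex`, `value`.
#' @param unit `"ratio"` or `"lnratio"`.
#' @param prior An [age_prior()].
#' @param threshold Majority threshold in years.
#' @param grid_step Posterior grid resolution.
#' @return Data frame `id`, `sex`, `y`, `post_mode`, `post_median`,
#'   `p_over`, plus the posteriors as attribute `posteriors`.
#' @export
predict_majority <- function(model, newdata, unit = c("ratio", "lnratio"),
                             prior = age_prior(), threshold = 18.0,
                             grid_step = 0.01) {
  unit <- match.arg(unit)
  stopifnot(all(c("id", "sex", "value") %in% names(newdata)))
  y <- if (unit == "ratio") {
    if (any(newdata$value <= 0)) stop("ratios must be positive to take ln")
    log(newdata$value)
  } else {
    newdata$value
  }
  posts <- vector("list", nrow(newdata))
  out <- data.frame(id = newdata$id, sex = newdata$sex, y = y,
                    post_mode = NA_real_, post_median = NA_real_,
                    p_over = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(newdata))) {
    post <- posterior(y[i], newdata$sex[i], model, prior, grid_step)
    posts[[i]] <- post
    out$post_mode[i] <- posterior_mode(post)
    out$post_median[i] <- posterior_median(post)
    out$p_over[i] <- prob_over(post, threshold)
  }
  attr(out, "posteriors") <- posts
  out
}
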