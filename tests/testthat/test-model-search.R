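test_that("the tooth-set grid is four singletons plus seven combinations", {
  sets <- enumerate_toothsets()
  expect_equal(length(sets), 11)
  expect_equal(sum(lengths(sets) == 1), 4)
  expect_equal(sum(lengths(sets) > 1), 7)
  expect_equal(sets[["18+28"]], c(18L, 28L))
  expect_equal(sets[["18+28+38+48"]], c(18L, 28L, 38L, 48L))
  multi <- sets[lengths(sets) > 1]
  expect_setequal(names(multi), c("18+28", "38+48", "18+48", "28+38",
                                  "18+38", "28+48", "18+28+38+48"))
})

test_that("design matrices carry the structure of each sex model", {
  co <- toy_cohort()
  s <- outcome_series(co, "4a", 28L)
  Xi <- design_matrix(s, "i")
  expect_equal(dim(Xi), c(6, 2))
  expect_equal(colnames(Xi), c("intercept", "age"))
  Xiv <- design_matrix(s, "iv")
  expect_equal(ncol(Xiv), 4)
  # model ii equals hand-built columns
  Xii <- design_matrix(s, "ii")
  expect_equal(unname(Xii),
               unname(cbind(1, as.numeric(s$sex == "M"), s$age_years)))
  # model iii splits the slope by sex
  Xiii <- design_matrix(s, "iii")
  expect_equal(Xiii[, "age_F"] + Xiii[, "age_M"], s$age_years)
  expect_true(all(Xiii[s$sex == "M", "age_F"] == 0))
  # single-sex data cannot identify sex terms
  s_f <- s[s$sex == "F", ]
  expect_error(design_matrix(s_f, "ii"), "both sexes")
})

test_that("an exact line is fitted with zero residuals", {
  X <- cbind(intercept = 1, age = c(1, 2, 3))
  f <- fit_wls(X, c(1, 2, 3))
  expect_equal(unname(f$coefficients), c(0, 1))
  expect_equal(f$residuals, rep(0, 3))
  expect_equal(f$aic, -Inf)  # zero-variance degenerate guard
})

test_that("rescaling all weights leaves the fit unchanged", {
  set.seed(8)
  X <- cbind(intercept = 1, age = runif(20, 14, 24))
  y <- -1.3 - 0.06 * X[, 2] + rnorm(20, 0, 0.2)
  w <- 1 / X[, 2]
  f1 <- fit_wls(X, y, w)
  f2 <- fit_wls(X, y, 7.3 * w)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$pvalues, f2$pvalues)
  expect_equal(f1$aic, f2$aic)
})

test_that("WLS matches the dense normal-equations oracle", {
  age <- c(14.2, 15.8, 17.4, 19.1, 21.3, 23.6)
  X <- cbind(intercept = 1, age = age)
  y <- c(-2.1, -2.2, -2.35, -2.4, -2.55, -2.7)
  w <- 1 / age
  f <- fit_wls(X, y, w)
  expect_equal(f$coefficients, wls_oracle(X, y, w), tolerance = 1e-12)
  # and on random full-rank fixtures
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    X <- cbind(intercept = 1, a = rnorm(n), b = runif(n))
    y <- rnorm(n)
    w <- runif(n, 0.2, 3)
    f <- fit_wls(X, y, w)
    rel <- max(abs(f$coefficients - wls_oracle(X, y, w))) /
      max(abs(f$coefficients))
    expect_lt(rel, 1e-8)
  }
})

test_that("rank-deficient designs are rejected", {
  X <- cbind(intercept = 1, age = 1:5, twice = 2 * (1:5))
  expect_error(fit_wls(X, rnorm(5)), "singular")
})

test_that("one redundant-direction coefficient costs exactly +2 AIC", {
  set.seed(15)
  age <- runif(30, 14, 24)
  X <- cbind(intercept = 1, age = age)
  y <- -1.3 - 0.06 * age + rnorm(30, 0, 0.2)
  w <- 1 / age
  f1 <- fit_wls(X, y, w)
  # add a column W-orthogonal to the residuals: the fit and residual
  # variance are unchanged, only the parameter count grows by one
  z0 <- rnorm(30)
  e <- f1$residuals
  z <- z0 - e * sum(w * z0 * e) / sum(w * e * e)
  f2 <- fit_wls(cbind(X, z = z), y, w)
  expect_equal(f2$sigma2_ml * f2$n, f1$sigma2_ml * f1$n, tolerance = 1e-10)
  expect_equal(f2$aic - f1$aic, 2, tolerance = 1e-8)
})

test_that("the weighted log-likelihood matches a per-observation density oracle", {
  set.seed(31)
  age <- runif(25, 14, 24)
  X <- cbind(intercept = 1, age = age)
  y <- -1.3 - 0.06 * age + rnorm(25, 0, 0.2)
  for (w in list(rep(1, 25), 1 / age)) {
    f <- fit_wls(X, y, w)
    # each observation is Normal(mu_i, sigma2_ml / w_i)
    ll <- sum(dnorm(y, f$fitted, sqrt(f$sigma2_ml / w), log = TRUE))
    expect_equal(f$logLik, ll, tolerance = 1e-10)
    expect_equal(f$aic, -2 * ll + 2 * (f$p + 1), tolerance = 1e-10)
  }
  # unweighted case agrees with the standard linear-model AIC
  f0 <- fit_wls(X, y)
  expect_equal(f0$aic, AIC(lm(y ~ age)), tolerance = 1e-10)
})

test_that("separate per-sex variances cannot beat the pooled model on pooled data", {
  set.seed(4)
  n <- 300
  sex <- rep(c("F", "M"), each = n / 2)
  age <- runif(n, 14, 24)
  y <- -1.3 + 0.11 * (sex == "M") - 0.06 * age + rnorm(n, 0, 0.2)
  s <- data.frame(participant_id = as.character(1:n), sex = sex,
                  age_years = age, y = y, stringsAsFactors = FALSE)
  m_iv <- fit_age_model(s, "iv", "constant")
  m_v <- fit_age_model(s, "v", "constant")
  expect_gte(m_v$aic, m_iv$aic - 2)  # v pays for its extra variance
  # and the richest mean structure cannot have larger weighted RSS
  rss <- function(m) sum(vapply(m$fits, function(f)
    sum(f$weights * f$residuals^2), 0))
  for (sm in c("i", "ii", "iii")) {
    expect_gte(rss(fit_age_model(s, sm, "constant")), rss(m_iv) - 1e-10)
  }
})

test_that("selection fits all fifteen candidates and reports the grid", {
  co <- generate_cohort(generator_config(n_participants = 120, seed = 2))
  s <- outcome_series(co, "4a", 28L)
  m <- select_model(s)
  grid <- attr(m, "grid")
  expect_equal(nrow(grid), 15)
  expect_true(all(!is.na(grid$aic)))
  expect_equal(m$aic, min(grid$aic))
})

test_that("null-slope age p-values are uniform", {
  set.seed(99)
  pv <- replicate(1000, {
    n <- 50
    age <- runif(n, 14, 24)
    y <- rnorm(n, 0, 0.2)
    fit_wls(cbind(intercept = 1, age = age), y)$pvalues[["age"]]
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("under no sex effect and constant variance the simplest model is modal", {
  sel <- character(15)
  for (r in 1:15) {
    cfg <- generator_config(n_participants = 500, intercept_f = -1.3,
                            intercept_m = -1.3, variance_law = "constant",
                            sigma2 = 0.036, seed = 200 + r)
    s <- outcome_series(generate_cohort(cfg), "4a", 28L)
    m <- select_model(s)
    sel[r] <- paste(m$sex_model, m$weighting)
  }
  tab <- sort(table(sel), decreasing = TRUE)
  expect_equal(names(tab)[1], "i constant")
})

test_that("exploration ranks candidates by the age p-value", {
  co <- generate_cohort(generator_config(n_participants = 150, seed = 3))
  filt <- redundancy_filter(co)
  report <- explore(co, filt$retained)
  expect_s3_class(report, "exploration_report")
  expect_equal(nrow(report), 7 * 11)
  ok <- !is.na(report$p_rank)
  expect_true(all(diff(report$p_rank[ok]) >= 0))
  # the ranking p of a model-ii winner equals its Wald age p
  row <- report[ok & report$sex_model == "ii", ][1, ]
  s <- outcome_series(co, row$outcome,
                      enumerate_toothsets()[[row$teeth]])
  refit <- fit_age_model(s, "ii", row$weighting)
  expect_equal(row$p_rank, refit$age_pvalues[["common"]], tolerance = 1e-12)
  expect_equal(row$p_common, refit$fits[[1]]$pvalues[["age"]], tolerance = 1e-12)
})

test_that("a tooth set carrying the only signal wins the exploration", {
  # uppers follow the age trend, lowers are pure noise
  cfg <- generator_config(n_participants = 150, agenesis_prob = 0, seed = 23)
  co <- generate_cohort(cfg)
  set.seed(24)
  for (t in c(38, 48)) {
    n <- nrow(co)
    shuffled <- sample(n)  # break the age link, keep the marginals
    for (p in c("pulp_ml_", "predentine_ml_", "hard_ml_"))
      co[[paste0(p, t)]] <- co[[paste0(p, t)]][shuffled]
  }
  specs <- enumerate_outcomes()
  report <- explore(co, specs[specs$label == "4a", ])
  best <- report[1, ]
  expect_true(best$teeth %in% c("18+28", "18", "28"))
  lower_rows <- report$teeth %in% c("38", "48", "38+48")
  expect_true(all(report$p_rank[lower_rows] >
                    best$p_rank, na.rm = TRUE))
})

test_that("insufficient-data candidates are recorded as skipped", {
  co <- generate_cohort(generator_config(n_participants = 40, seed = 6))
  co$pulp_ml_48 <- NA  # tooth 48 absent everywhere
  specs <- enumerate_outcomes()
  report <- explore(co, specs[specs$label == "4a", , drop = FALSE])
  skipped <- report[report$note != "", ]
  expect_true(all(grepl("skipped", skipped$note)))
  expect_true("48" %in% skipped$teeth)
  expect_equal(nrow(report), 11)
})
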