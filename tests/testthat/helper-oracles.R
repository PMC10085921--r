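# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: textbook formulas, dense normal equations,
# per-voxel loops.

# Pearson correlation by the textbook sum formula
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# WLS coefficients by dense normal equations (X'WX)^-1 X'Wy
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)[, 1]
}

# per-voxel label tally by explicit loop
tally_oracle <- function(intensities, mask, hard_max, predentine_max) {
  counts <- c(hard = 0L, predentine = 0L, pulp = 0L)
  for (i in seq_along(intensities)) {
    if (!mask[i]) next
    v <- floor(intensities[i])
    if (v <= hard_max) counts["hard"] <- counts["hard"] + 1L
    else if (v <= predentine_max) counts["predentine"] <- counts["predentine"] + 1L
    else counts["pulp"] <- counts["pulp"] + 1L
  }
  counts
}

# a small deterministic cohort with explicit volumes for both sexes
toy_cohort <- function() {
  df <- data.frame(
    participant_id = sprintf("T%02d", 1:6),
    sex = c("F", "F", "M", "M", "F", "M"),
    age_years = c(15, 17, 19, 21, 22, 23),
    stringsAsFactors = FALSE)
  df$age_days <- as.integer(round(df$age_years * 365.25))
  for (t in c(18, 28, 38, 48)) {
    df[[paste0("pulp_ml_", t)]] <- c(0.06, 0.055, 0.05, 0.045, 0.04, 0.035) + t / 1e4
    df[[paste0("predentine_ml_", t)]] <- c(0.020, 0.018, 0.016, 0.014, 0.012, 0.010)
    df[[paste0("hard_ml_", t)]] <- c(0.70, 0.71, 0.75, 0.76, 0.72, 0.77)
  }
  df
}
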