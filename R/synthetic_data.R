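#' Configuration for the synthetic cohort generator
#'
#' Collects the generating parameters of the simulated study population:
#' a log-linear decline of the (pulp + predentine)/total volume ratio with
#' age, sex-specific intercepts with a common slope, a residual-variance law,
#' per-sex median tissue volumes, and a per-tooth agenesis probability.
#'
#' The defaults emulate the structure the analysis assumes for in-vivo data:
#' 99 enrolled participants aged 14-24 years, about two thirds female, the
#' ln tissue ratio falling by 0.06 per year with intercepts placing the
#' female/male ratios near 0.087 and 0.097 at age 18, residual variance
#' proportional to age, and median hard-tissue/pulp/predentine volumes of
#' 0.712/0.052/0.016 ml (females) and 0.788/0.065/0.020 ml (males).
#'
#' @param n_participants Number of participants to simulate.
#' @param sex_ratio Fraction female, in \[0, 1\].
#' @param age_range_years Length-2 numeric, minimum and maximum age in
#'   decimal years; ages are drawn uniformly on this interval.
#' @param slope Change in ln ratio per year of age (negative: the pulp and
#'   predentine compartments shrink as the tooth mineralises).
#' @param intercept_f,intercept_m ln ratio at age zero for females/males.
#' @param sigma2 Base residual variance of the ln ratio.
#' @param variance_law One of `"constant"`, `"proportional_to_age"`,
#'   `"inverse_age"`: residual variance is `sigma2`, `sigma2 * age`, or
#'   `sigma2 / age`.
#' @param tissue_scale Named list with elements `F` and `M`, each a named
#'   numeric vector `c(hard=, pulp=, predentine=)` of median volumes in ml.
#' @param agenesis_prob Per-tooth probability that a third molar is
#'   congenitally absent (all its volumes missing).
#' @param hard_sdlog Log-scale standard deviation of the hard-tissue volume
#'   around its per-sex median.
#' @param pulp_fraction Median share of pulp within pulp + predentine.
#' @param pulp_fraction_logit_sd Between-tooth spread of the pulp share on
#'   the logit scale; keeps pulp/total and predentine/total informative
#'   about each other without being collinear.
#' @param seed Integer seed; every draw of the generator flows from it.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 99,
                             sex_ratio = 0.67,
                             age_range_years = c(14, 24),
                             slope = -0.06,
                             intercept_f = -1.36,
                             intercept_m = -1.25,
                             sigma2 = 0.002,
                             variance_law = c("proportional_to_age",
                                              "constant", "inverse_age"),
                             tissue_scale = list(
                               F = c(hard = 0.712, pulp = 0.052, predentine = 0.016),
                               M = c(hard = 0.788, pulp = 0.065, predentine = 0.020)),
                             agenesis_prob = 0.1,
                             hard_sdlog = 0.15,
                             pulp_fraction = 0.76,
                             pulp_fraction_logit_sd = 0.2,
                             seed = 1) {
  variance_law <- match.arg(variance_law)
  if (length(n_participants) != 1 || is.na(n_participants) || n_participants < 0)
    stop_field("n_participants", "must be a single non-negative count")
  if (length(sex_ratio) != 1 || is.na(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop_field("sex_ratio", "must lie in [0, 1]")
  if (length(age_range_years) != 2 || age_range_years[1] >= age_range_years[2])
    stop_field("age_range_years", "must be (min, max) with min < max")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop_field("sigma2", "must be a positive variance")
  if (length(agenesis_prob) != 1 || agenesis_prob < 0 || agenesis_prob >= 1)
    stop_field("agenesis_prob", "must lie in [0, 1)")
  for (s in c("F", "M")) {
    ts <- tissue_scale[[s]]
    if (is.null(ts) || any(!is.finite(ts)) || any(ts <= 0))
      stop_field("tissue_scale", sprintf("entry '%s' must be positive volumes", s))
  }
  if (!is.finite(slope)) stop_field("slope", "must be finite")
  if (pulp_fraction <= 0 || pulp_fraction >= 1)
    stop_field("pulp_fraction", "must lie in (0, 1)")
  structure(list(
    n_participants = as.integer(n_participants), sex_ratio = sex_ratio,
    age_range_years = as.numeric(age_range_years), slope = slope,
    intercept_f = intercept_f, intercept_m = intercept_m, sigma2 = sigma2,
    variance_law = variance_law, tissue_scale = tissue_scale,
    agenesis_prob = agenesis_prob, hard_sdlog = hard_sdlog,
    pulp_fraction = pulp_fraction,
    pulp_fraction_logit_sd = pulp_fraction_logit_sd,
    seed = as.integer(seed)), class = "generator_config")
}

#' FDI codes of the four third molars
#' @return Integer vector `c(18, 28, 38, 48)`.
#' @export
third_molars <- function() c(18L, 28L, 38L, 48L)

# variance multiplier v(age) such that Var(eps) = sigma2 * v(age)
variance_multiplier <- function(law, age) {
  switch(law,
         constant = rep(1, length(age)),
         proportional_to_age = age,
         inverse_age = 1 / age,
         stop("unknown variance law: ", law))
}

#' Simulate a cohort of participants with third-molar tissue volumes
#'
#' Draws ages uniformly, assigns sex by `sex_ratio`, and for each present
#' tooth generates pulp, predentine and hard-tissue volumes such that the
#' natural logarithm of (pulp + predentine)/total follows
#' `intercept_sex + slope * age` plus Gaussian noise with variance
#' `sigma2 * v(age)` per the configured variance law. Hard-tissue volume is
#' drawn log-normally around its per-sex median; pulp + predentine is then
#' solved from the generated ratio and split by a logit-normal pulp share,
#' so the headline ratio obeys its generating law exactly while all volumes
#' stay strictly positive.
#'
#' @param config A [generator_config()].
#' @return A data frame with one row per participant: `participant_id`,
#'   `sex` (`"F"`/`"M"`), `age_days`, `age_years`, `excluded_reason`
#'   (all `"none"`), and per tooth `t` in 18/28/38/48 the columns
#'   `pulp_ml_t`, `predentine_ml_t`, `hard_ml_t` (`NA` = agenesis).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  teeth <- third_molars()
  cols <- as.vector(t(outer(teeth, c("pulp_ml_", "predentine_ml_", "hard_ml_"),
                            function(t, p) paste0(p, t))))
  if (n == 0L) {
    empty <- data.frame(participant_id = character(), sex = character(),
                        age_days = integer(), age_years = numeric(),
                        excluded_reason = character(),
                        stringsAsFactors = FALSE)
    for (cn in cols) empty[[cn]] <- numeric()
    return(empty)
  }
  with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")
    age_years <- runif(n, config$age_range_years[1], config$age_range_years[2])
    age_days <- round(age_years * 365.25)
    age_years <- age_days / 365.25
    df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                     sex = sex, age_days = as.integer(age_days),
                     age_years = age_years,
                     excluded_reason = "none",
                     stringsAsFactors = FALSE)
    intercept <- ifelse(sex == "F", config$intercept_f, config$intercept_m)
    vmult <- variance_multiplier(config$variance_law, age_years)
    for (t in teeth) {
      present <- runif(n) >= config$agenesis_prob
      eps <- rnorm(n, 0, sqrt(config$sigma2 * vmult))
      ratio <- exp(intercept + config$slope * age_years + eps)
      ratio <- pmin(ratio, 0.95)  # guard: ratio must stay below 1
      hard_med <- vapply(sex, function(s) config$tissue_scale[[s]][["hard"]], 0)
      hard <- exp(log(hard_med) + rnorm(n, 0, config$hard_sdlog))
      total <- hard / (1 - ratio)
      soft <- total * ratio
      share <- plogis(qlogis(config$pulp_fraction) +
                        rnorm(n, 0, config$pulp_fraction_logit_sd))
      pulp <- soft * share
      predentine <- soft * (1 - share)
      pulp[!present] <- NA_real_
      predentine[!present] <- NA_real_
      hard[!present] <- NA_real_
      df[[paste0("pulp_ml_", t)]] <- pulp
      df[[paste0("predentine_ml_", t)]] <- predentine
      df[[paste0("hard_ml_", t)]] <- hard
    }
    df
  })
}

#' Enrollment ledger reproducing the study's exclusion accounting
#'
#' Builds a fixed 99-participant ledger with the four exclusion categories
#' and their counts: missing third molars (4), tooth unsuitable for
#' segmentation (15), movement artifacts (7), incorrect use of the dental
#' cotton rolls (6); the remaining 67 participants are unflagged. Reasons
#' are mutually exclusive, assigned in that priority order.
#'
#' @return A data frame with `participant_id` and `exclusion_reason`
#'   (one of `"none"`, `"missing_molars"`, `"unsuitable_tooth"`,
#'   `"movement_artifact"`, `"cotton_roll_error"`).
#' @export
make_exclusion_fixture <- function() {
  reasons <- c(rep("none", 67),
               rep("missing_molars", 4),
               rep("unsuitable_tooth", 15),
               rep("movement_artifact", 7),
               rep("cotton_roll_error", 6))
  data.frame(participant_id = sprintf("P%03d", seq_along(reasons)),
             exclusion_reason = reasons, stringsAsFactors = FALSE)
}

#' Simulate a voxel phantom of a segmented tooth
#'
#' Builds a 3D integer intensity image plus tooth mask in which exactly
#' `class_counts` voxels carry intensities in each tissue band of the
#' default threshold scheme (hard 0-63, predentine 64-100, pulp >= 101)
#' before noise. Voxels outside the mask are background (intensity 0).
#' Optional additive Gaussian intensity noise is rounded to integers and
#' clamped at zero, so with `noise_sd = 0` threshold classification
#' recovers the generating counts exactly.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param spacing_mm Positive length-3 voxel edge lengths in mm.
#' @param class_counts Integer length-3 voxel counts `c(hard, predentine,
#'   pulp)`.
#' @param noise_sd Standard deviation of additive intensity noise.
#' @param seed Integer seed.
#' @return A [voxel_grid()] with attribute `class_counts` (the generating
#'   counts) and `clean_intensities` (the pre-noise image).
#' @export
generate_phantom <- function(shape, spacing_mm = c(0.37, 0.37, 0.37),
                             class_counts, noise_sd = 0, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0))
  class_counts <- as.integer(class_counts)
  stopifnot(length(class_counts) == 3, all(class_counts >= 0))
  n_mask <- sum(class_counts)
  if (n_mask > prod(shape))
    stop("class_counts total ", n_mask, " exceeds grid capacity ", prod(shape))
  with_seed(seed, {
    intens <- integer(prod(shape))
    mask <- logical(prod(shape))
    # tissue voxels occupy a contiguous block; intensities drawn uniformly
    # within each band so band edges are exercised
    bands <- list(hard = c(0L, 63L), predentine = c(64L, 100L),
                  pulp = c(101L, 163L))
    pos <- 1L
    for (k in 1:3) {
      if (class_counts[k] > 0) {
        b <- bands[[k]]
        idx <- pos:(pos + class_counts[k] - 1L)
        intens[idx] <- sample(b[1]:b[2], class_counts[k], replace = TRUE)
        mask[idx] <- TRUE
        pos <- pos + class_counts[k]
      }
    }
    clean <- intens
    if (noise_sd > 0) {
      noisy <- intens[mask] + round(rnorm(n_mask, 0, noise_sd))
      intens[mask] <- pmax(noisy, 0L)
    }
    grid <- voxel_grid(array(intens, dim = shape), spacing_mm,
                       array(mask, dim = shape))
    attr(grid, "class_counts") <- setNames(class_counts,
                                           c("hard", "predentine", "pulp"))
    attr(grid, "clean_intensities") <- array(clean, dim = shape)
    grid
  })
}

#' Write a simulated cohort to CSV
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#' @param path File written by [write_cohort()] or following its schema.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "sex", "age_years")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file lacks required columns: ", paste(missing, collapse = ", "))
  df
}
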