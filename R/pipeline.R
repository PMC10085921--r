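#' Pipeline configuration
#'
#' Aggregates the constants of the full analysis. All defaults are the
#' package's standard operating values: thresholds 63/100, redundancy
#' threshold 0.999, uniform age prior on \[14, 23\] years, majority
#' threshold 18 years, ratio-mean averaging across tooth sets, and the
#' 1/age-style weighting convention in which the regression weight is the
#' reciprocal of the residual-variance multiplier.
#'
#' @param cohort_path Optional path to a cohort CSV; when `NULL` a cohort
#'   is simulated from `generator`.
#' @param generator A [generator_config()] used when simulating.
#' @param exclusions `"fixture"` (apply [make_exclusion_fixture()], valid
#'   for 99-participant cohorts), `"none"`, or a path to a ledger CSV with
#'   columns `participant_id`, `exclusion_reason`.
#' @param scheme A [threshold_scheme()].
#' @param r_threshold Redundancy threshold on |Pearson R|.
#' @param prior An [age_prior()].
#' @param majority_threshold Age threshold for the reported probability.
#' @param average Tooth-set averaging mode (`"ratio"` or `"log"`).
#' @param predict_path Optional CSV of (id, sex, value) to predict for.
#' @param predict_unit `"ratio"` or `"lnratio"` for `predict_path` values.
#' @param seed Integer seed for the simulation stage.
#' @param out_dir Output directory for all artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL,
                            generator = generator_config(seed = seed),
                            exclusions = "fixture",
                            scheme = threshold_scheme(),
                            r_threshold = 0.999,
                            prior = age_prior(),
                            majority_threshold = 18.0,
                            average = c("ratio", "log"),
                            predict_path = NULL,
                            predict_unit = c("ratio", "lnratio"),
                            seed = 1,
                            out_dir = "molarAge_run") {
  average <- match.arg(average)
  predict_unit <- match.arg(predict_unit)
  if (r_threshold <= 0 || r_threshold > 1)
    stop_field("r_threshold", "must lie in (0, 1]")
  if (majority_threshold < prior$lower || majority_threshold > prior$upper)
    warning("majority threshold lies outside the prior support; ",
            "probabilities will be exactly 0 or 1")
  stopifnot(inherits(scheme, "threshold_scheme"), inherits(prior, "age_prior"))
  structure(list(cohort_path = cohort_path, generator = generator,
                 exclusions = exclusions, scheme = scheme,
                 r_threshold = r_threshold, prior = prior,
                 majority_threshold = majority_threshold, average = average,
                 predict_path = predict_path, predict_unit = predict_unit,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Remove excluded participants and account for every exclusion
#'
#' @param ledger Data frame `participant_id`, `exclusion_reason` (reason
#'   `"none"` keeps the participant).
#' @param cohort Cohort data frame; every ledger id must exist in it.
#' @return List: `cohort` (retained rows, input order preserved) and
#'   `counts` (named integer vector per reason plus `enrolled` and
#'   `analyzed`).
#' @export
apply_exclusions <- function(ledger, cohort) {
  stopifnot(all(c("participant_id", "exclusion_reason") %in% names(ledger)))
  unknown <- setdiff(ledger$participant_id, cohort$participant_id)
  if (length(unknown))
    stop("ledger names participants absent from the cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  reason <- setNames(ledger$exclusion_reason, ledger$participant_id)
  r <- reason[cohort$participant_id]
  r[is.na(r)] <- "none"
  kept <- cohort[r == "none", , drop = FALSE]
  kept$excluded_reason <- NULL
  excl <- table(factor(r[r != "none"],
                       levels = c("missing_molars", "unsuitable_tooth",
                                  "movement_artifact", "cotton_roll_error")))
  counts <- c(enrolled = nrow(cohort), as.vector(excl), analyzed = nrow(kept))
  names(counts) <- c("enrolled", names(excl), "analyzed")
  list(cohort = kept, counts = counts)
}

read_ledger <- function(exclusions) {
  if (identical(exclusions, "fixture")) return(make_exclusion_fixture())
  if (identical(exclusions, "none")) return(NULL)
  read.csv(exclusions, stringsAsFactors = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' @param model An `age_model`.
#' @param path Output path.
#' @param extra Named list merged into the document (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, extra = list()) {
  per_fit <- function(f) list(coefficients = as.list(f$coefficients),
                              vcov = f$vcov, sigma2 = f$sigma2,
                              sigma2_ml = f$sigma2_ml, n = f$n,
                              aic = f$aic)
  doc <- c(list(sex_model = model$sex_model, weighting = model$weighting,
                aic = model$aic, k = model$k,
                age_pvalues = as.list(model$age_pvalues),
                outcome = model$outcome, teeth = model$teeth,
                fits = lapply(model$fits, per_fit)), extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# fingerprint of the analysis parameters; output location excluded so the
# same analysis hashes identically wherever it is written
analysis_hash <- function(config) {
  config$out_dir <- NULL
  config_hash(unclass(config))
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the complete analysis pipeline
#'
#' Stages, in fixed order: cohort acquisition (read or simulate),
#' exclusion accounting, transformation-outcome enumeration, redundancy
#' filtering, exploration over outcomes x tooth sets, refit of the
#' selected model, and optional prediction for new observations. Every
#' stage writes its artifact under `config$out_dir`; a run manifest
#' records the configuration hash, seed and per-stage counts. Identical
#' configurations and seeds give identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit one message per stage.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  warn_log <- character()
  t0 <- Sys.time()

  # stage 1: cohort
  cohort <- if (is.null(config$cohort_path)) {
    generate_cohort(config$generator)
  } else {
    read_cohort(config$cohort_path)
  }
  write_cohort(cohort, out("cohort.csv"))
  stage_log(verbose, "cohort", nrow(cohort), " participants")

  # stage 2: exclusions
  ledger <- read_ledger(config$exclusions)
  if (is.null(ledger)) {
    analyzed <- cohort
    counts <- c(enrolled = nrow(cohort), analyzed = nrow(cohort))
  } else {
    ex <- apply_exclusions(ledger, cohort)
    analyzed <- ex$cohort
    counts <- ex$counts
  }
  stage_log(verbose, "exclusions", counts[["analyzed"]], " of ",
            counts[["enrolled"]], " analyzed")

  # stage 3-4: outcomes + redundancy filter
  specs <- enumerate_outcomes()
  filt <- redundancy_filter(analyzed, specs, third_molars(),
                            config$r_threshold, config$average)
  write.csv(data.frame(label = filt$retained$label), out("retained.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(filt$correlation), out("correlation.csv"))
  stage_log(verbose, "redundancy", nrow(filt$retained), " of ",
            nrow(specs), " outcomes retained")

  # stage 5: exploration
  toothsets <- enumerate_toothsets()
  report <- explore(analyzed, filt$retained, toothsets, config$average)
  write.csv(report, out("exploration.csv"), row.names = FALSE)
  n_skipped <- sum(report$note != "")
  if (n_skipped > 0)
    warn_log <- c(warn_log, sprintf("%d exploration candidates skipped", n_skipped))
  stage_log(verbose, "explore", nrow(report), " candidates (",
            n_skipped, " skipped)")

  # stage 6: selected model
  model <- refit_best(analyzed, report, toothsets, config$average)
  write_model_json(model, out("selected_model.json"),
                   extra = list(seed = config$seed,
                                config_hash = analysis_hash(config)))
  stage_log(verbose, "fit", "outcome ", model$outcome, " on ",
            paste(model$teeth, collapse = "+"),
            ", sex structure ", model$sex_model, ", weighting ", model$weighting)

  # stage 7: prediction (optional)
  n_pred <- 0L
  if (!is.null(config$predict_path)) {
    newdata <- read.csv(config$predict_path, stringsAsFactors = FALSE)
    pred <- predict_majority(model, newdata, config$predict_unit,
                             config$prior, config$majority_threshold)
    write.csv(pred, out("predictions.csv"), row.names = FALSE)
    n_pred <- nrow(pred)
    stage_log(verbose, "predict", n_pred, " individuals")
  }

  manifest <- list(
    config_hash = analysis_hash(config),
    seed = config$seed,
    counts = as.list(counts),
    outcomes_enumerated = nrow(specs),
    outcomes_retained = nrow(filt$retained),
    exploration_rows = nrow(report),
    exploration_skipped = n_skipped,
    selected = list(outcome = model$outcome,
                    teeth = paste(model$teeth, collapse = "+"),
                    sex_model = model$sex_model,
                    weighting = model$weighting,
                    aic = model$aic,
                    age_pvalues = as.list(model$age_pvalues)),
    predictions = n_pred,
    warnings = warn_log,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("molarAge")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [pipeline_config()]; nested keys
#' `generator:` override [generator_config()] fields, `prior:` the prior
#' bounds, `scheme:` the thresholds.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1
  gen_args <- if (!is.null(y$generator)) y$generator else list()
  if (is.null(gen_args$seed)) gen_args$seed <- seed
  gen <- do.call(generator_config, gen_args)
  prior <- if (!is.null(y$prior)) do.call(age_prior, y$prior) else age_prior()
  scheme <- if (!is.null(y$scheme)) do.call(threshold_scheme, y$scheme) else threshold_scheme()
  args <- list(generator = gen, prior = prior, scheme = scheme, seed = seed)
  for (k in c("cohort_path", "exclusions", "r_threshold",
              "majority_threshold", "average", "predict_path",
              "predict_unit", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}
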