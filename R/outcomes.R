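#' Enumerate the ten tissue-volume transformation outcomes
#'
#' Four transformation families of the three tooth tissue volumes yield ten
#' outcomes: the total volume (1); odds-style ratios x/(total - x) (2a-2c);
#' simple shares x/total (3a-3c); and two-tissue shares (x + y)/total
#' (4a-4c). Within families 2 and 3 the single tissue x runs over pulp,
#' predentine, hard; in family 4 the pairs are (pulp, predentine),
#' (pulp, hard), (predentine, hard).
#'
#' @return Data frame with columns `label`, `family`, `x`, `y` (NA where
#'   unused), in enumeration order.
#' @export
enumerate_outcomes <- function() {
  data.frame(
    label = c("1", "2a", "2b", "2c", "3a", "3b", "3c", "4a", "4b", "4c"),
    family = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
    x = c(NA, "pulp", "predentine", "hard",
          "pulp", "predentine", "hard",
          "pulp", "pulp", "predentine"),
    y = c(NA, NA, NA, NA, NA, NA, NA, "predentine", "hard", "hard"),
    stringsAsFactors = FALSE)
}

outcome_spec <- function(label) {
  specs <- enumerate_outcomes()
  row <- specs[specs$label == label, ]
  if (nrow(row) != 1) stop("unknown outcome label: ", label)
  row
}

#' Evaluate one transformation outcome on a tooth's tissue volumes
#'
#' @param volumes A [tooth_volumes()] object, or any list/row carrying
#'   `pulp_ml`, `predentine_ml`, `hard_ml`.
#' @param spec An outcome label (e.g. `"4a"`) or a single row of
#'   [enumerate_outcomes()].
#' @return The outcome value: a dimensionless ratio, or ml for family 1.
#' @export
compute_outcome <- function(volumes, spec) {
  if (is.character(spec)) spec <- outcome_spec(spec)
  p <- volumes$pulp_ml; d <- volumes$predentine_ml; h <- volumes$hard_ml
  if (any(!is.finite(c(p, d, h))) || any(c(p, d, h) <= 0))
    stop("all tissue volumes must be strictly positive (ln transform domain)")
  total <- p + d + h
  tv <- c(pulp = p, predentine = d, hard = h)
  switch(as.character(spec$family),
         "1" = total,
         "2" = tv[[spec$x]] / (total - tv[[spec$x]]),
         "3" = tv[[spec$x]] / total,
         "4" = (tv[[spec$x]] + tv[[spec$y]]) / total)
}

# per-participant outcome matrix for one tooth: rows of cohort, NA if absent
cohort_tooth_outcome <- function(cohort, spec, tooth) {
  p <- cohort[[paste0("pulp_ml_", tooth)]]
  d <- cohort[[paste0("predentine_ml_", tooth)]]
  h <- cohort[[paste0("hard_ml_", tooth)]]
  if (is.null(p) || is.null(d) || is.null(h))
    stop("cohort lacks volume columns for tooth ", tooth)
  total <- p + d + h
  tv <- list(pulp = p, predentine = d, hard = h)
  switch(as.character(spec$family),
         "1" = total,
         "2" = tv[[spec$x]] / (total - tv[[spec$x]]),
         "3" = tv[[spec$x]] / total,
         "4" = (tv[[spec$x]] + tv[[spec$y]]) / total)
}

#' ln outcome series for a tooth set
#'
#' Computes the outcome per member tooth, averages across the set, and takes
#' the natural logarithm. Participants lacking any member tooth are dropped
#' (their count is recorded in attribute `n_dropped`). Averaging is either
#' of the per-tooth ratios (default) or of their logarithms, exposed for
#' sensitivity analysis.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for the schema).
#' @param spec Outcome label or row of [enumerate_outcomes()].
#' @param teeth Integer vector of FDI codes (subset of 18/28/38/48).
#' @param average `"ratio"` (mean of ratios, then ln) or `"log"` (mean of
#'   ln ratios).
#' @return Data frame `participant_id`, `sex`, `age_years`, `y` (the ln
#'   response), with attributes `outcome`, `teeth`, `n_dropped`.
#' @export
outcome_series <- function(cohort, spec, teeth, average = c("ratio", "log")) {
  average <- match.arg(average)
  if (is.character(spec)) spec <- outcome_spec(spec)
  teeth <- as.integer(teeth)
  if (length(teeth) == 0 || !all(teeth %in% third_molars()))
    stop("teeth must be a nonempty subset of 18/28/38/48")
  vals <- sapply(teeth, function(t) cohort_tooth_outcome(cohort, spec, t))
  vals <- matrix(vals, nrow = nrow(cohort))
  keep <- rowSums(is.na(vals)) == 0
  y <- if (average == "ratio") {
    log(rowMeans(vals[keep, , drop = FALSE]))
  } else {
    rowMeans(log(vals[keep, , drop = FALSE]))
  }
  if (!any(keep))
    stop("no participant has all member teeth present: empty outcome series")
  out <- data.frame(participant_id = cohort$participant_id[keep],
                    sex = cohort$sex[keep],
                    age_years = cohort$age_years[keep],
                    y = y, stringsAsFactors = FALSE)
  attr(out, "outcome") <- spec$label
  attr(out, "teeth") <- teeth
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Drop transformation outcomes that duplicate others
#'
#' Computes pairwise Pearson correlations between the ln outcome series
#' (absolute value, so near-perfect negative log-linear relations count as
#' overlap) and removes redundant outcomes at `|R| >= r_threshold`. Of an
#' overlapping pair, the outcome appearing later in the enumeration is
#' kept: the later families are the simpler bounded shares, and this
#' retention rule removes the odds-style family-2 outcomes when they
#' duplicate them. Implemented as a reverse-order greedy scan, which makes
#' the filter idempotent.
#'
#' Redundancy is assessed before any tooth-set averaging: by default each
#' tooth contributes its own outcome values and the correlations are
#' computed over the pooled (participant, tooth) observations, so the
#' per-tooth algebraic links between transformations are seen undiluted.
#' Setting `per_tooth = FALSE` instead correlates the averaged-then-logged
#' series of the given tooth set.
#'
#' @param cohort Cohort data frame.
#' @param specs Outcome specs to consider (rows of [enumerate_outcomes()]).
#' @param teeth Teeth contributing observations.
#' @param r_threshold Overlap threshold on |Pearson R| (default 0.999).
#' @param average Passed to [outcome_series()] when `per_tooth = FALSE`.
#' @param per_tooth Pool per-tooth observations (default) or use the
#'   averaged tooth-set series.
#' @return List with `retained` (spec rows in enumeration order),
#'   `dropped` (data frame label/overlaps_with/r), `correlation` (the full
#'   |R| matrix), and `flagged` (labels whose series were constant, skipped
#'   in comparisons).
#' @export
redundancy_filter <- function(cohort, specs = enumerate_outcomes(),
                              teeth = third_molars(), r_threshold = 0.999,
                              average = c("ratio", "log"),
                              per_tooth = TRUE) {
  average <- match.arg(average)
  if (r_threshold <= 0 || r_threshold > 1)
    stop("r_threshold must lie in (0, 1]")
  m <- nrow(specs)
  series <- lapply(seq_len(m), function(i) {
    if (per_tooth) {
      parts <- lapply(teeth, function(t)
        outcome_series(cohort, specs[i, ], t)$y)
      do.call(c, parts)
    } else {
      outcome_series(cohort, specs[i, ], teeth, average)$y
    }
  })
  n_obs <- lengths(series)
  if (any(n_obs < 3))
    stop("need at least 3 participants in every outcome series")
  ymat <- vapply(series, identity, numeric(n_obs[1]))
  constant <- apply(ymat, 2, function(v) isTRUE(all.equal(var(v), 0)) || var(v) == 0)
  R <- matrix(NA_real_, m, m, dimnames = list(specs$label, specs$label))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (!constant[i] && !constant[j])
        R[i, j] <- abs(cor(ymat[, i], ymat[, j]))
    }
  }
  keep <- logical(m)
  dropped <- data.frame(label = character(), overlaps_with = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  for (i in rev(seq_len(m))) {
    partners <- which(keep & !is.na(R[i, ]) & seq_len(m) != i)
    over <- partners[R[i, partners] >= r_threshold]
    if (length(over)) {
      j <- over[which.max(R[i, over])]
      dropped <- rbind(data.frame(label = specs$label[i],
                                  overlaps_with = specs$label[j],
                                  r = R[i, j], stringsAsFactors = FALSE),
                       dropped)
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = specs[keep, , drop = FALSE],
       dropped = dropped,
       correlation = R,
       flagged = specs$label[constant])
}
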