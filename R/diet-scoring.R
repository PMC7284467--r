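#' @title Diet-quality index scoring
#' @description Declarative construction of the AHEI, DASH, and
#'   Mediterranean-style Diet Score (MDS) indices from food-group level
#'   intake tables, plus the FFQ validity filter and index standardization.
#' @name diet-scoring
NULL

SCORING_METHODS <- c("anchored_linear", "quintile_rank", "quartile_rank",
                     "alcohol_window", "alcohol_graded")

#' Declare a single diet-index component
#'
#' A component maps one intake field to points via one of five methods:
#' `anchored_linear` (linear interpolation between a worst and a best
#' anchor, clamped), `quintile_rank` / `quartile_rank` (points by empirical
#' quantile bin, optionally sex-stratified), `alcohol_window` (0/1 for
#' sex-specific moderate consumption), or `alcohol_graded` (windowed with
#' partial credit for abstainers, used by the AHEI alcohol component).
#'
#' @param name component label.
#' @param intake_field column of the intake table consumed by this component.
#' @param method one of `r paste(SCORING_METHODS, collapse=", ")`.
#' @param direction `"direct"` (more intake, more points) or `"reverse"`.
#'   For `anchored_linear` the direction is encoded by the anchor order
#'   (reverse components put the worst anchor at the high intake).
#' @param points_min,points_max integer point range of the component.
#' @param sex_specific logical; compute quantile cut-points within sex strata.
#' @param anchors numeric `c(worst, best)` for `anchored_linear`.
#' @param window named list with per-sex `c(low, high)` g/day bounds for the
#'   alcohol methods, e.g. `list(female = c(5, 15), male = c(10, 25))`.
#' @param heavy named list of per-sex upper cut-offs above which
#'   `alcohol_graded` scores 0 (defaults to `high + 10`).
#' @param abstainer_points points given to zero intake under `alcohol_graded`.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(name, intake_field, method,
                           direction = c("direct", "reverse"),
                           points_min = 0L, points_max = 10L,
                           sex_specific = FALSE, anchors = NULL,
                           window = NULL, heavy = NULL,
                           abstainer_points = 2.5) {
  direction <- match.arg(direction)
  method <- match.arg(method, SCORING_METHODS)
  if (method == "anchored_linear") {
    if (is.null(anchors) || length(anchors) != 2L || !all(is.finite(anchors)))
      stop("component '", name, "': anchored_linear requires finite anchors c(worst, best)")
    if (anchors[1] == anchors[2])
      stop("component '", name, "': anchors must differ")
  }
  if (method %in% c("alcohol_window", "alcohol_graded") && is.null(window))
    stop("component '", name, "': alcohol methods require a per-sex window")
  if (method == "alcohol_window") {
    points_min <- 0L; points_max <- 1L
  } else if (points_min >= points_max) {
    stop("component '", name, "': points_min must be < points_max")
  }
  structure(list(name = name, intake_field = intake_field, method = method,
                 direction = direction, points_min = as.integer(points_min),
                 points_max = as.integer(points_max),
                 sex_specific = isTRUE(sex_specific),
                 anchors = anchors, window = window, heavy = heavy,
                 abstainer_points = abstainer_points),
            class = "component_spec")
}

#' Assemble and validate a diet index configuration
#'
#' Validates the structural composition of the index at load time:
#' component maxima must sum to `expected_max`, the AHEI must have 11
#' components of 10 points each (maximum 110), the DASH score 8 quintile
#' components scored 1-5 (maximum 40), and the MDS 8 quartile components
#' scored 0-3 plus one 0/1 moderate-alcohol component (maximum 25).
#'
#' @param index_name `"AHEI"`, `"DASH"`, or `"MDS"`.
#' @param components list of [component_spec()] objects.
#' @param expected_max expected maximum total (110, 40 or 25).
#' @return an object of class `diet_index_config`.
#' @export
diet_index_config <- function(index_name = c("AHEI", "DASH", "MDS"),
                              components, expected_max) {
  index_name <- match.arg(index_name)
  stopifnot(length(components) > 0L,
            all(vapply(components, inherits, TRUE, "component_spec")))
  pmx <- vapply(components, `[[`, 0L, "points_max")
  pmn <- vapply(components, `[[`, 0L, "points_min")
  if (sum(pmx) != expected_max)
    stop("index ", index_name, ": component maxima sum to ", sum(pmx),
         ", expected ", expected_max)
  meth <- vapply(components, `[[`, "", "method")
  ok <- switch(index_name,
    AHEI = length(components) == 11L && all(pmx == 10L) && expected_max == 110L,
    DASH = length(components) == 8L && all(meth == "quintile_rank") &&
      all(pmn == 1L & pmx == 5L) && expected_max == 40L,
    MDS  = sum(meth == "quartile_rank") == 8L &&
      sum(meth == "alcohol_window") == 1L && length(components) == 9L &&
      all(pmx[meth == "quartile_rank"] == 3L) && expected_max == 25L)
  if (!ok)
    stop("index ", index_name, ": component composition violates the index definition")
  structure(list(index_name = index_name, components = components,
                 expected_max = as.integer(expected_max)),
            class = "diet_index_config")
}

## -- shipped default configurations ------------------------------------------
## Anchors and alcohol windows are package defaults (from the standard
## AHEI-2010 / MDS literature), expressed in the units of the corresponding
## generator fields; quantile-based components are unit-free.

#' Default AHEI configuration (11 components, 0-110)
#'
#' Anchored-linear components with shipped default anchors in the units of
#' the synthetic generator's intake fields; sugar-sweetened beverages and
#' fruit juice, red/processed meat, trans fat and sodium are reverse-scored
#' (worst anchor at high intake). Alcohol uses graded sex-specific windows
#' with partial credit (2.5/10) for abstainers.
#' @return a `diet_index_config`.
#' @export
ahei_config <- function() {
  cs <- list(
    component_spec("vegetables", "vegetables", "anchored_linear",
                   anchors = c(0, 5)),
    component_spec("fruits", "fruits", "anchored_linear", anchors = c(0, 4)),
    component_spec("nuts_legumes", "nuts_legumes", "anchored_linear",
                   anchors = c(0, 1)),
    component_spec("whole_grains", "whole_grains", "anchored_linear",
                   anchors = c(0, 3)),
    component_spec("omega3", "omega3_mg_d", "anchored_linear",
                   anchors = c(0, 250)),
    component_spec("pufa", "pufa_pct_kcal", "anchored_linear",
                   anchors = c(2, 10)),
    component_spec("ssb_fruit_juice", "ssb_fruit_juice", "anchored_linear",
                   direction = "reverse", anchors = c(2.5, 0)),
    component_spec("red_processed_meat", "red_processed_meat",
                   "anchored_linear", direction = "reverse",
                   anchors = c(1.5, 0)),
    component_spec("trans_fat", "trans_pct_kcal", "anchored_linear",
                   direction = "reverse", anchors = c(4, 0.5)),
    component_spec("sodium", "sodium_mg_d", "anchored_linear",
                   direction = "reverse", anchors = c(4000, 1500)),
    component_spec("alcohol", "alcohol_g_d", "alcohol_graded",
                   points_min = 0L, points_max = 10L,
                   window = list(female = c(5, 15), male = c(10, 25)),
                   heavy = list(female = 25, male = 35)))
  diet_index_config("AHEI", cs, 110L)
}

#' Default DASH configuration (8 quintile components, 8-40)
#'
#' Quintiles are computed on the full analysis sample (not sex-stratified);
#' sodium, red/processed meat and sugar-sweetened beverages are
#' reverse-scored (first quintile earns 5 points).
#' @return a `diet_index_config`.
#' @export
dash_config <- function() {
  q <- function(name, field, dir = "direct")
    component_spec(name, field, "quintile_rank", direction = dir,
                   points_min = 1L, points_max = 5L)
  cs <- list(
    q("fruits_juice", "fruits_juice"),
    q("vegetables", "vegetables"),
    q("nuts_legumes", "nuts_legumes"),
    q("whole_grains", "whole_grains"),
    q("low_fat_dairy", "low_fat_dairy"),
    q("sodium", "sodium_mg_d", "reverse"),
    q("red_processed_meat", "red_processed_meat", "reverse"),
    q("ssb", "ssb", "reverse"))
  diet_index_config("DASH", cs, 40L)
}

#' Default MDS configuration (8 sex-specific quartile components + alcohol, 0-25)
#'
#' All quartile components (including the MUFA:SFA ratio) use sex-specific
#' cut-points; red/processed meat is reverse-scored. Moderate alcohol
#' consumption scores 1 point within sex-specific g/day windows
#' (women 5-15, men 10-25 by default), 0 otherwise.
#' @return a `diet_index_config`.
#' @export
mds_config <- function() {
  q <- function(name, field, dir = "direct")
    component_spec(name, field, "quartile_rank", direction = dir,
                   points_min = 0L, points_max = 3L, sex_specific = TRUE)
  cs <- list(
    q("vegetables", "vegetables"),
    q("fruits", "fruits"),
    q("nuts", "nuts"),
    q("legumes", "legumes"),
    q("whole_grains", "whole_grains"),
    q("fish", "fish"),
    q("red_processed_meat", "red_processed_meat", "reverse"),
    q("mufa_sfa", "mufa_sfa_ratio"),
    component_spec("alcohol", "alcohol_g_d", "alcohol_window",
                   window = list(female = c(5, 15), male = c(10, 25))))
  diet_index_config("MDS", cs, 25L)
}

#' FFQ validity filter
#'
#' A record is valid when it has fewer than 13 blank items and an estimated
#' daily energy intake of at least 600 kcal and below 4000 kcal (women) or
#' 4200 kcal (men). The reason names the first failed rule.
#'
#' @param blank_items integer vector of blank FFQ items per participant.
#' @param energy_kcal numeric vector of estimated daily energy intake.
#' @param sex character/factor vector, `"female"` or `"male"`.
#' @param max_blanks,min_kcal,max_kcal_female,max_kcal_male filter thresholds.
#' @return data.frame with logical `valid` and character `reason`
#'   (`NA` when valid).
#' @export
validate_ffq <- function(blank_items, energy_kcal, sex,
                         max_blanks = 13L, min_kcal = 600,
                         max_kcal_female = 4000, max_kcal_male = 4200) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male")))
    stop("unknown sex category: ",
         paste(unique(setdiff(sex, c("female", "male"))), collapse = ", "))
  n <- length(blank_items)
  stopifnot(length(energy_kcal) == n, length(sex) == n)
  upper <- ifelse(sex == "female", max_kcal_female, max_kcal_male)
  reason <- rep(NA_character_, n)
  blank_bad <- is.na(blank_items) | blank_items >= max_blanks
  low_bad <- is.na(energy_kcal) | energy_kcal < min_kcal
  high_bad <- !is.na(energy_kcal) & energy_kcal >= upper
  # first failed rule wins: blanks, then lower energy bound, then upper
  reason[high_bad] <- "energy_above_limit"
  reason[low_bad] <- "energy_below_600"
  reason[blank_bad] <- "blank_items"
  data.frame(valid = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Score an anchored-linear component
#'
#' Linear interpolation between `points_min` at the worst anchor and
#' `points_max` at the best anchor, clamped to the point range. Reverse
#' components are expressed by placing the worst anchor at the high intake.
#'
#' @param intake numeric vector of intakes (NA treated as zero intake).
#' @param spec a `component_spec` with `method = "anchored_linear"`.
#' @return numeric vector of points.
#' @export
score_anchored_component <- function(intake, spec) {
  if (spec$method != "anchored_linear")
    stop("spec method is not anchored_linear")
  if (is.null(spec$anchors)) stop("missing anchors for component ", spec$name)
  intake[is.na(intake)] <- 0
  worst <- spec$anchors[1]; best <- spec$anchors[2]
  frac <- (intake - worst) / (best - worst)
  pts <- spec$points_min + frac * (spec$points_max - spec$points_min)
  pmin(pmax(pts, spec$points_min), spec$points_max)
}

#' Quantile-rank scoring (DASH quintiles, MDS sex-specific quartiles)
#'
#' Cut-points are the empirical quantiles of the (stratum-specific) sample;
#' values tied with a cut-point fall in the lower bin. When zero-inflation
#' collapses adjacent cut-points, the merged bins receive the lowest
#' applicable bin's points and a warning is issued.
#'
#' @param intakes numeric vector.
#' @param n_bins 4 or 5.
#' @param direction `"direct"` or `"reverse"`; reverse maps bin `b` to
#'   `points_for_bins[n_bins + 1 - b]`.
#' @param points_for_bins points per bin, lowest bin first; length `n_bins`.
#' @param by_sex optional stratification vector (e.g. sex); cut-points are
#'   computed within each stratum.
#' @return numeric vector of points, one per participant.
#' @export
quantile_rank_scores <- function(intakes, n_bins,
                                 direction = c("direct", "reverse"),
                                 points_for_bins, by_sex = NULL) {
  direction <- match.arg(direction)
  if (!n_bins %in% c(4L, 5L)) stop("n_bins must be 4 or 5")
  if (length(points_for_bins) != n_bins)
    stop("points_for_bins must have length n_bins")
  intakes[is.na(intakes)] <- 0
  out <- numeric(length(intakes))
  strata <- if (is.null(by_sex)) rep("all", length(intakes)) else as.character(by_sex)
  if (length(strata) != length(intakes)) stop("by_sex length mismatch")
  for (s in unique(strata)) {
    idx <- strata == s
    x <- intakes[idx]
    if (length(x) < n_bins)
      stop("stratum '", s, "' has fewer observations (", length(x),
           ") than bins (", n_bins, ")")
    qs <- stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                          names = FALSE, type = 7)
    u <- unique(qs)
    if (length(u) < length(qs))
      warning("stratum '", s, "': duplicated quantile cut-points merged; ",
              "affected participants receive the lowest applicable bin")
    # interval index: number of unique cut-points strictly below x
    cnt <- vapply(intakes[idx], function(v) sum(u < v), integer(1))
    # map interval back to original bin number (lowest applicable on merge)
    orig_bin <- c(1L, match(u, qs) + 1L)[cnt + 1L]
    bin <- if (direction == "direct") orig_bin else n_bins + 1L - orig_bin
    out[idx] <- points_for_bins[bin]
  }
  out
}

#' Moderate-alcohol scoring for the MDS (0/1)
#'
#' One point iff alcohol intake lies within the participant's sex-specific
#' moderate window (inclusive bounds); zero otherwise (over- or
#' under-consumption).
#'
#' @param alcohol_g_day numeric, g/day; NA treated as 0.
#' @param sex `"female"`/`"male"` vector.
#' @param window per-sex list of `c(low, high)` bounds.
#' @return integer vector of 0/1 points.
#' @export
score_alcohol_mds <- function(alcohol_g_day, sex, window) {
  if (is.null(window)) stop("alcohol window not configured")
  sex <- as.character(sex)
  alcohol_g_day[is.na(alcohol_g_day)] <- 0
  lo <- vapply(sex, function(s) window[[s]][1], 0)
  hi <- vapply(sex, function(s) window[[s]][2], 0)
  as.integer(alcohol_g_day >= lo & alcohol_g_day <= hi)
}

# AHEI-style graded alcohol: full points inside the sex-specific window,
# partial credit for abstainers, linear decline to 0 at the heavy cut-off.
score_alcohol_graded <- function(alcohol_g_day, sex, spec) {
  sex <- as.character(sex)
  alcohol_g_day[is.na(alcohol_g_day)] <- 0
  pts <- numeric(length(alcohol_g_day))
  for (i in seq_along(alcohol_g_day)) {
    w <- spec$window[[sex[i]]]
    heavy <- if (!is.null(spec$heavy)) spec$heavy[[sex[i]]] else w[2] + 10
    a <- alcohol_g_day[i]
    pts[i] <- if (a == 0) {
      spec$abstainer_points
    } else if (a < w[1]) {
      spec$abstainer_points +
        (a / w[1]) * (spec$points_max - spec$abstainer_points)
    } else if (a <= w[2]) {
      spec$points_max
    } else if (a < heavy) {
      spec$points_max * (heavy - a) / (heavy - w[2])
    } else 0
  }
  pmin(pmax(pts, spec$points_min), spec$points_max)
}

#' Score a cohort on a diet index
#'
#' Applies every component of the configuration to the intake table and sums
#' to the index total. Quantile components use the supplied cohort as the
#' reference sample for cut-points (sex-stratified where configured). Blank
#' (NA) intake fields are treated as zero intake.
#'
#' @param intakes data.frame with a `participant_id` column and the intake
#'   fields named by the configuration.
#' @param config a [diet_index_config()].
#' @param sex per-participant sex vector; required for sex-specific and
#'   alcohol components.
#' @return data.frame: `participant_id`, one points column per component,
#'   and `total`.
#' @export
score_index <- function(intakes, config, sex = NULL) {
  stopifnot(inherits(config, "diet_index_config"),
            "participant_id" %in% names(intakes))
  pmx <- vapply(config$components, `[[`, 0L, "points_max")
  if (sum(pmx) != config$expected_max)
    stop("configuration violates expected_max ", config$expected_max)
  missing_fields <- setdiff(vapply(config$components, `[[`, "", "intake_field"),
                            names(intakes))
  if (length(missing_fields))
    stop("intake table lacks fields: ", paste(missing_fields, collapse = ", "))
  res <- data.frame(participant_id = intakes$participant_id,
                    stringsAsFactors = FALSE)
  for (cs in config$components) {
    x <- intakes[[cs$intake_field]]
    pts <- switch(cs$method,
      anchored_linear = score_anchored_component(x, cs),
      quintile_rank = quantile_rank_scores(
        x, 5L, cs$direction, seq.int(cs$points_min, cs$points_max),
        by_sex = if (cs$sex_specific) sex else NULL),
      quartile_rank = quantile_rank_scores(
        x, 4L, cs$direction, seq.int(cs$points_min, cs$points_max),
        by_sex = if (cs$sex_specific) sex else NULL),
      alcohol_window = score_alcohol_mds(x, sex, cs$window),
      alcohol_graded = score_alcohol_graded(x, sex, cs))
    res[[cs$name]] <- pts
  }
  res$total <- rowSums(res[, vapply(config$components, `[[`, "", "name"),
                           drop = FALSE])
  res
}

#' Standardize an index to mean 0, SD 1
#'
#' @param totals numeric vector of index totals (at least two distinct
#'   values); sample standard deviation is used.
#' @return standardized numeric vector.
#' @export
standardize_index <- function(totals) {
  if (length(totals) < 2L || length(unique(totals)) < 2L)
    stop("cannot standardize a constant (or length-1) index")
  (totals - mean(totals)) / stats::sd(totals)
}
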