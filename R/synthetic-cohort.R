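#' @title Synthetic cohort generation
#' @description Seeded generator producing intake, covariate and two-platform
#'   marker tables with the marginal structure of a middle-aged community
#'   cohort (sex-specific Gaussian marginals truncated at zero) and
#'   user-planted linear diet-index effects on markers, so that the full
#'   downstream analysis is testable without any real data.
#' @name synthetic-cohort
NULL

#' Default per-sex intake marginals
#'
#' Food-group and nutrient means/SDs by sex for a middle-aged US community
#' cohort; units follow the source summary table (servings/day for
#' vegetables, fruits and low-fat dairy; servings/week for nuts, legumes,
#' whole grains, meat, fish and sweetened beverages; g/day alcohol; %kcal
#' fats; mg/day omega-3). Sodium is not reported in that table; its
#' defaults (mg/day) are package-chosen plausible values.
#'
#' @return data.frame with columns `field`, `unit`, `mean_male`, `sd_male`,
#'   `mean_female`, `sd_female`.
#' @export
default_intake_params <- function() {
  p <- rbind(
    c("vegetables",         "svg/d",  2.0,  1.3,   2.4,  1.7),
    c("fruits",             "svg/d",  1.2,  1.0,   1.4,  1.2),
    c("low_fat_dairy",      "svg/d",  0.8,  0.9,   0.9,  1.0),
    c("nuts",               "svg/wk", 0.4,  0.6,   0.2,  0.4),
    c("legumes",            "svg/wk", 0.3,  0.3,   0.3,  0.3),
    c("whole_grains",       "svg/wk", 1.2,  1.2,   1.2,  1.2),
    c("red_processed_meat", "svg/wk", 0.9,  0.7,   0.6,  0.5),
    c("fish",               "svg/wk", 0.3,  0.3,   0.3,  0.3),
    c("ssb_fruit_juice",    "svg/wk", 1.4,  1.2,   1.1,  1.2),
    c("ssb",                "svg/wk", 0.5,  0.8,   0.3,  0.6),
    c("fruit_juice",        "svg/wk", 0.9,  0.9,   0.8,  0.9),
    c("alcohol_g_d",        "g/d",   15.4, 20.0,   6.7, 11.2),
    c("mufa_sfa_ratio",     "ratio",  1.1,  0.2,   1.1,  0.2),
    c("pufa_pct_kcal",      "%kcal",  5.7,  1.7,   6.0,  1.7),
    c("trans_pct_kcal",     "%kcal",  1.6,  0.8,   1.4,  0.7),
    c("omega3_mg_d",        "mg/d", 257.8, 235.5, 253.2, 217.8),
    c("sodium_mg_d",        "mg/d", 2900,  900,   2500,  800))
  data.frame(field = p[, 1], unit = p[, 2],
             mean_male = as.numeric(p[, 3]), sd_male = as.numeric(p[, 4]),
             mean_female = as.numeric(p[, 5]), sd_female = as.numeric(p[, 6]),
             stringsAsFactors = FALSE)
}

#' Default covariate marginals
#' @return nested list of per-sex means/SDs and prevalences for age,
#'   physical activity index, BMI, smoking and the two medication flags.
#' @export
default_covariate_params <- function() {
  list(age = list(male = c(mean = 55.7, sd = 9.9),
                  female = c(mean = 54.5, sd = 9.6)),
       physical_activity = list(male = c(mean = 36.0, sd = 7.4),
                                female = c(mean = 33.4, sd = 4.7)),
       bmi = list(male = c(mean = 28.2, sd = 4.1),
                  female = c(mean = 26.7, sd = 5.4)),
       smoker_prev = c(male = 0.18, female = 0.18),
       lipid_med_prev = c(male = 0.10, female = 0.06),
       htn_med_prev = c(male = 0.23, female = 0.17))
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the analyzed metabolite sample: 2208 participants
#' (52% women), 1373 proteins assayed in two batches and 216 metabolites.
#'
#' @param n_participants cohort size (>= 1).
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @param sex_fraction_female proportion of women in `[0, 1]`.
#' @param intake_params as [default_intake_params()].
#' @param covariate_params as [default_covariate_params()].
#' @param energy_params per-sex `c(mean, sd)` kcal/day.
#' @param n_proteins,n_metabolites marker namespace sizes.
#' @param protein_batch_sizes optional integer pair; by default proteins are
#'   assigned to batches 1/2 by deterministic alternation.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 2208L, seed = 1L,
                        sex_fraction_female = 1154 / 2208,
                        intake_params = default_intake_params(),
                        covariate_params = default_covariate_params(),
                        energy_params = list(male = c(mean = 1992, sd = 642),
                                             female = c(mean = 1742, sd = 566)),
                        n_proteins = 1373L, n_metabolites = 216L,
                        protein_batch_sizes = NULL) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("n_participants must be a positive integer")
  if (sex_fraction_female < 0 || sex_fraction_female > 1)
    stop("sex_fraction_female must lie in [0, 1]")
  if (any(intake_params$sd_male < 0) || any(intake_params$sd_female < 0))
    stop("intake SDs must be non-negative")
  prevs <- unlist(covariate_params[c("smoker_prev", "lipid_med_prev",
                                     "htn_med_prev")])
  if (any(prevs < 0 | prevs > 1)) stop("prevalences must lie in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 sex_fraction_female = sex_fraction_female,
                 intake_params = intake_params,
                 covariate_params = covariate_params,
                 energy_params = energy_params,
                 n_proteins = as.integer(n_proteins),
                 n_metabolites = as.integer(n_metabolites),
                 protein_batch_sizes = protein_batch_sizes),
            class = "cohort_spec")
}

#' Plan planted diet-index effects on markers
#'
#' Effects are defined on the standardized index scale: a planted entry
#' `beta_per_sd` adds `beta_per_sd * z(index)` to the marker. Markers not
#' named in any entry carry no planted effect (nulls). Protein effects are
#' planted on the log scale (the matrix is delivered exponentiated, as
#' assay output is strictly positive).
#'
#' @param entries data.frame with columns `index` (AHEI/DASH/MDS), `marker`
#'   (e.g. `"met_0001"`, `"prot_0001"`), `beta_per_sd`; may be empty.
#' @param noise_sd marker noise SD (>= 0; 0 permitted for exact-recovery
#'   checks).
#' @param covariate_effects optional named numeric vector of coefficients
#'   applied to every marker (names among `age`, `bmi`,
#'   `physical_activity`, `energy_kcal`, `smoker`, `lipid_med`, `htn_med`,
#'   `sex_female`).
#' @return object of class `effect_plan`.
#' @export
effect_plan <- function(entries = NULL, noise_sd = 1,
                        covariate_effects = NULL) {
  if (is.null(entries))
    entries <- data.frame(index = character(), marker = character(),
                          beta_per_sd = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("index", "marker", "beta_per_sd") %in% names(entries)))
  if (!all(entries$index %in% c("AHEI", "DASH", "MDS")))
    stop("plan indices must be AHEI, DASH or MDS")
  if (anyDuplicated(entries[, c("index", "marker")]))
    stop("marker ids must be unique per index in the plan")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(entries = entries, noise_sd = noise_sd,
                 covariate_effects = covariate_effects),
            class = "effect_plan")
}

trunc_norm <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Generate a synthetic cohort
#'
#' Draws intakes and covariates from independent sex-specific truncated
#' Gaussians, scores the three diet indices on the generated intakes,
#' standardizes them, and builds marker matrices as
#' `sum(planted beta * z(index)) + covariate effects + N(0, noise_sd)`.
#' Proteins are exponentiated (strictly positive raw scale) and carry batch
#' labels assigned by deterministic alternation unless batch sizes are
#' fixed in the spec; metabolites are delivered unbatched on the linear
#' scale. Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param plan an [effect_plan()].
#' @return object of class `synthetic_cohort`: list with `intakes`,
#'   `covariates` (data.frames), `proteins`, `metabolites`
#'   ([marker_matrix()] objects), `true_scores` (per-index standardized
#'   totals used for planting) and `truth` (the plan echo).
#' @export
generate_cohort <- function(spec, plan = effect_plan()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(plan, "effect_plan"))
  prot_ids <- sprintf("prot_%04d", seq_len(spec$n_proteins))
  met_ids <- sprintf("met_%04d", seq_len(spec$n_metabolites))
  unknown <- setdiff(plan$entries$marker, c(prot_ids, met_ids))
  if (length(unknown))
    stop("plan references unknown marker ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  set.seed(spec$seed)
  n <- spec$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  n_f <- round(n * spec$sex_fraction_female)
  sex <- c(rep("female", n_f), rep("male", n - n_f))

  cp <- spec$covariate_params
  draw2 <- function(par, trunc = TRUE) {
    v <- numeric(n)
    for (s in c("female", "male")) {
      i <- sex == s
      v[i] <- stats::rnorm(sum(i), par[[s]]["mean"], par[[s]]["sd"])
    }
    if (trunc) pmax(v, 0) else v
  }
  drawflag <- function(prev) {
    v <- integer(n)
    for (s in c("female", "male")) {
      i <- sex == s
      v[i] <- stats::rbinom(sum(i), 1L, prev[[s]])
    }
    v
  }
  covariates <- data.frame(
    participant_id = ids, sex = sex,
    age = draw2(cp$age),
    physical_activity = draw2(cp$physical_activity),
    bmi = draw2(cp$bmi),
    smoker = drawflag(as.list(cp$smoker_prev)),
    lipid_med = drawflag(as.list(cp$lipid_med_prev)),
    htn_med = drawflag(as.list(cp$htn_med_prev)),
    energy_kcal = draw2(spec$energy_params),
    stringsAsFactors = FALSE)

  ip <- spec$intake_params
  intakes <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(ip))) {
    v <- numeric(n)
    for (s in c("female", "male")) {
      i <- sex == s
      mu <- if (s == "female") ip$mean_female[r] else ip$mean_male[r]
      sg <- if (s == "female") ip$sd_female[r] else ip$sd_male[r]
      v[i] <- trunc_norm(sum(i), mu, sg)
    }
    intakes[[ip$field[r]]] <- v
  }
  # derived combination fields consumed by the index configurations
  intakes$nuts_legumes <- intakes$nuts + intakes$legumes
  intakes$fruits_juice <- intakes$fruits + intakes$fruit_juice
  intakes$blank_items <- 0L
  intakes$energy_kcal <- covariates$energy_kcal

  # true standardized indices for effect planting
  z <- sapply(list(AHEI = ahei_config(), DASH = dash_config(),
                   MDS = mds_config()),
              function(cfg) standardize_index(
                score_index(intakes, cfg, sex = sex)$total))
  rownames(z) <- ids

  build_markers <- function(marker_ids) {
    m <- length(marker_ids)
    M <- matrix(stats::rnorm(n * m, 0, plan$noise_sd), n, m,
                dimnames = list(ids, marker_ids))
    for (r in seq_len(nrow(plan$entries))) {
      e <- plan$entries[r, ]
      if (e$marker %in% marker_ids)
        M[, e$marker] <- M[, e$marker] + e$beta_per_sd * z[, e$index]
    }
    if (!is.null(plan$covariate_effects)) {
      ce <- plan$covariate_effects
      X <- cbind(age = covariates$age, bmi = covariates$bmi,
                 physical_activity = covariates$physical_activity,
                 energy_kcal = covariates$energy_kcal,
                 smoker = covariates$smoker, lipid_med = covariates$lipid_med,
                 htn_med = covariates$htn_med,
                 sex_female = as.numeric(sex == "female"))
      use <- intersect(names(ce), colnames(X))
      if (length(use))
        M <- M + X[, use, drop = FALSE] %*% matrix(ce[use], ncol = 1) %*%
          matrix(1, 1, m)
    }
    M
  }

  prot_lin <- build_markers(prot_ids)
  met <- build_markers(met_ids)

  if (!is.null(spec$protein_batch_sizes)) {
    bs <- spec$protein_batch_sizes
    if (sum(bs) != n) stop("protein_batch_sizes must sum to n_participants")
    batch <- rep(c(1L, 2L), times = bs)
  } else {
    batch <- rep_len(c(1L, 2L), n)
  }

  structure(list(
    intakes = intakes,
    covariates = covariates,
    proteins = marker_matrix(exp(prot_lin), platform = "protein",
                             batch = batch),
    metabolites = marker_matrix(met, platform = "metabolite"),
    true_scores = z,
    truth = plan), class = "synthetic_cohort")
}

#' Inject FFQ blanks and covariate missingness
#'
#' Blank FFQ items are drawn per participant as Binomial(126, rate); the
#' `blank_items` count is incremented and up to that many base intake
#' fields are set to NA (blank, distinguishable from a zero intake).
#' Covariate missingness sets one randomly chosen adjustable covariate to
#' NA per affected participant.
#'
#' @param cohort a `synthetic_cohort`.
#' @param ffq_blank_rate,covariate_missing_rate rates in `[0, 1)`.
#' @param seed integer seed for the missingness mask.
#' @param n_ffq_items nominal number of questionnaire items (126).
#' @return the cohort with a `missingness` report attached
#'   (`n_with_blanks`, `n_missing_covariate`).
#' @export
inject_missingness <- function(cohort, ffq_blank_rate = 0,
                               covariate_missing_rate = 0, seed = 1L,
                               n_ffq_items = 126L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (ffq_blank_rate < 0 || ffq_blank_rate >= 1 ||
      covariate_missing_rate < 0 || covariate_missing_rate >= 1)
    stop("missingness rates must lie in [0, 1)")
  if (ffq_blank_rate == 0 && covariate_missing_rate == 0) {
    cohort$missingness <- list(n_with_blanks = 0L, n_missing_covariate = 0L)
    return(cohort)
  }
  set.seed(seed)
  n <- nrow(cohort$intakes)
  blanks <- stats::rbinom(n, n_ffq_items, ffq_blank_rate)
  cohort$intakes$blank_items <- cohort$intakes$blank_items + blanks
  base_fields <- setdiff(names(cohort$intakes),
                         c("participant_id", "blank_items", "energy_kcal",
                           "nuts_legumes", "fruits_juice"))
  for (i in which(blanks > 0)) {
    k <- min(blanks[i], length(base_fields))
    cohort$intakes[i, sample(base_fields, k)] <- NA_real_
  }
  miss_cov <- which(stats::runif(n) < covariate_missing_rate)
  adj <- c("age", "physical_activity", "bmi", "smoker", "lipid_med",
           "htn_med", "energy_kcal")
  for (i in miss_cov)
    cohort$covariates[i, sample(adj, 1L)] <- NA
  cohort$missingness <- list(n_with_blanks = sum(blanks > 0),
                             n_missing_covariate = length(miss_cov))
  cohort
}

#' Write a synthetic cohort as delimited text plus a truth echo
#'
#' Writes `intakes.tsv`, `covariates.tsv`, `proteins.tsv`,
#' `metabolites.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("intakes.tsv", "covariates.tsv", "proteins.tsv",
                            "metabolites.tsv", "truth.json"))
  data.table::fwrite(cohort$intakes, paths[1], sep = "\t")
  data.table::fwrite(cohort$covariates, paths[2], sep = "\t")
  data.table::fwrite(marker_matrix_to_df(cohort$proteins), paths[3], sep = "\t")
  data.table::fwrite(marker_matrix_to_df(cohort$metabolites), paths[4], sep = "\t")
  jsonlite::write_json(list(entries = cohort$truth$entries,
                            noise_sd = cohort$truth$noise_sd,
                            covariate_effects = as.list(cohort$truth$covariate_effects)),
                       paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
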