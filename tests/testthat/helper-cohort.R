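# shared small fixtures, all generated in code

small_spec <- function(n = 200, seed = 42, n_prot = 10, n_met = 20, ...)
  cohort_spec(n_participants = n, seed = seed, n_proteins = n_prot,
              n_metabolites = n_met, ...)

small_cohort <- function(n = 200, seed = 42, plan = effect_plan(), ...)
  generate_cohort(small_spec(n = n, seed = seed, ...), plan)

# standardized index columns for a generated cohort
std_scores <- function(cohort) {
  sx <- cohort$covariates$sex
  out <- data.frame(participant_id = cohort$intakes$participant_id,
                    stringsAsFactors = FALSE)
  for (cfg in list(ahei_config(), dash_config(), mds_config()))
    out[[cfg$index_name]] <-
      standardize_index(score_index(cohort$intakes, cfg, sex = sx)$total)
  out
}

# an intake table where one participant dominates (or is dominated on
# reverse components) so they land in the extreme quantile of everything
adversarial_intakes <- function(n = 100, best_row = 1L) {
  set.seed(9)
  fields <- default_intake_params()$field
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)))
  for (f in fields) df[[f]] <- runif(n, 1, 2)
  df$nuts_legumes <- df$nuts + df$legumes
  df$fruits_juice <- df$fruits + df$fruit_juice
  df$blank_items <- 0L
  df$energy_kcal <- runif(n, 1500, 2500)
  df
}

# tiny GMT written to a temp file
write_tmp_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
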