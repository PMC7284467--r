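#' @title End-to-end pipeline
#' @description One-config orchestration of simulate/ingest -> validate ->
#'   score -> preprocess -> scan -> correlate -> enrich -> overlap with a
#'   reproducible run manifest.
#' @name pipeline
NULL

# deterministic per-stage seed fan-out; kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

#' Build and validate a run configuration
#'
#' All analysis thresholds live here with their standard defaults: FDR
#' alpha 0.05, FFQ validity at 13 blank items and 600/4000/4200 kcal/day,
#' pathway size bounds 5-2000.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param simulate list of [cohort_spec()] arguments (a cohort is
#'   generated) or `NULL` to ingest `inputs` instead.
#' @param inputs named list of paths (`intakes`, `covariates`, `proteins`,
#'   `metabolites`) when not simulating.
#' @param plan an [effect_plan()] for simulation.
#' @param alpha FDR significance threshold in (0, 1).
#' @param fdr_family `"per_index"` or `"pooled"`.
#' @param ffq list of validity-filter thresholds.
#' @param enrichment list with `gmt` path and optional `universe`,
#'   `min_size`, `max_size`.
#' @param overlap list with `qtl` and `gwas` table paths.
#' @return validated `run_config` object.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = list(),
                       inputs = NULL, plan = effect_plan(),
                       alpha = 0.05,
                       fdr_family = c("per_index", "pooled"),
                       ffq = list(max_blanks = 13L, min_kcal = 600,
                                  max_kcal_female = 4000,
                                  max_kcal_male = 4200),
                       enrichment = NULL, overlap = NULL) {
  fdr_family <- match.arg(fdr_family)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (is.null(simulate) && is.null(inputs))
    stop("either simulate parameters or input paths must be given")
  if (!is.null(inputs)) {
    simulate <- NULL  # explicit inputs take precedence over the default sim
    need <- c("intakes", "covariates", "proteins", "metabolites")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs lack paths: ", paste(miss, collapse = ", "))
    absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(absent)) stop("input paths not found: ",
                             paste(absent, collapse = ", "))
  }
  for (nm in c("gmt")) {
    if (!is.null(enrichment) && !file.exists(enrichment[[nm]]))
      stop("enrichment path not found: ", enrichment[[nm]])
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, plan = plan,
                 alpha = alpha, fdr_family = fdr_family, ffq = ffq,
                 enrichment = enrichment, overlap = overlap),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the eight stages in order (simulate-or-ingest, validate, score,
#' preprocess, scan, correlate, enrich, overlap), writing each stage's
#' artifacts under `config$out_dir` and recording row counts and MD5
#' hashes in a run manifest. Deterministic given the config seed; a
#' failing stage aborts the run with prior outputs preserved.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("dietomics")),
                   stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, outputs = basename(outputs),
           md5 = unname(tools::md5sum(outputs)), counts = counts)
  }
  outp <- function(f) file.path(config$out_dir, f)

  ## stage 1: simulate or ingest ------------------------------------------
  if (!is.null(config$simulate)) {
    spec <- do.call(cohort_spec,
                    c(config$simulate,
                      list(seed = stage_seed(config$seed, "simulate"))))
    cohort <- generate_cohort(spec, config$plan)
    paths <- write_cohort(cohort, config$out_dir)
    note("simulate", paths, list(n = spec$n_participants))
    intakes <- cohort$intakes; covariates <- cohort$covariates
    proteins <- cohort$proteins; metabolites <- cohort$metabolites
  } else {
    intakes <- as.data.frame(data.table::fread(config$inputs$intakes))
    covariates <- as.data.frame(data.table::fread(config$inputs$covariates))
    proteins <- read_marker_matrix(config$inputs$proteins, "protein")
    metabolites <- read_marker_matrix(config$inputs$metabolites, "metabolite")
    note("ingest", unlist(config$inputs), list(n = nrow(intakes)))
  }

  ## stage 2: FFQ validity -------------------------------------------------
  sex <- covariates$sex[match(intakes$participant_id,
                              covariates$participant_id)]
  v <- do.call(validate_ffq,
               c(list(blank_items = intakes$blank_items,
                      energy_kcal = intakes$energy_kcal, sex = sex),
                 config$ffq))
  vpath <- outp("ffq_validity.tsv")
  data.table::fwrite(cbind(participant_id = intakes$participant_id, v),
                     vpath, sep = "\t")
  note("validate", vpath, list(n_valid = sum(v$valid),
                               n_invalid = sum(!v$valid)))

  ## stage 3: score --------------------------------------------------------
  keep <- v$valid
  scores <- data.frame(participant_id = intakes$participant_id[keep],
                       stringsAsFactors = FALSE)
  for (cfg in list(ahei_config(), dash_config(), mds_config())) {
    sc <- score_index(intakes[keep, , drop = FALSE], cfg, sex = sex[keep])
    scores[[cfg$index_name]] <- sc$total
  }
  spath <- outp("scores.tsv")
  data.table::fwrite(scores, spath, sep = "\t")
  note("score", spath, list(n = nrow(scores)))

  ## stage 4: preprocess proteins + align ----------------------------------
  prot_pp <- preprocess_proteins(proteins, covariates)
  aligned <- list(protein = align_tables(scores, covariates, prot_pp),
                  metabolite = align_tables(scores, covariates, metabolites))
  excl <- lapply(aligned, `[[`, "report")
  epath <- outp("exclusions.json")
  jsonlite::write_json(excl, epath, auto_unbox = TRUE, digits = NA)
  note("preprocess", epath,
       list(analyzed_proteins = excl$protein$analyzed,
            analyzed_metabolites = excl$metabolite$analyzed))

  ## stage 5: association scan ---------------------------------------------
  recs <- lapply(aligned, function(al) {
    std <- al$data
    for (ix in c("AHEI", "DASH", "MDS"))
      std[[ix]] <- standardize_index(std[[ix]])
    run_scan(std, al$markers, al$data, alpha = config$alpha,
             fdr_family = config$fdr_family)
  })
  scan_tab <- do.call(rbind, recs)
  rownames(scan_tab) <- NULL
  scpath <- outp("scan.tsv")
  data.table::fwrite(scan_tab, scpath, sep = "\t")
  ov <- lapply(recs, overlap_sets)
  ovpath <- outp("venn_counts.json")
  jsonlite::write_json(lapply(ov, `[[`, "counts"), ovpath,
                       auto_unbox = TRUE, digits = NA)
  note("scan", c(scpath, ovpath),
       list(n_models = nrow(scan_tab),
            n_fdr_sig = sum(scan_tab$fdr_sig)))

  ## stage 6: correlation structure ----------------------------------------
  cor_paths <- character(); ncors <- list()
  for (pf in names(aligned)) {
    sig <- unique(scan_tab$marker[scan_tab$platform == pf & scan_tab$fdr_sig])
    path <- outp(paste0("correlation_", pf, ".tsv"))
    if (length(sig) >= 2L) {
      al <- aligned[[pf]]
      covs <- data.frame(age = al$data$age,
                         sex_female = as.numeric(al$data$sex == "female"))
      cm <- correlation_matrix(al$markers$values[, sig, drop = FALSE], covs)
      ord <- cluster_order(cm)
      write_correlation_matrix(cm[ord, ord], path)
    } else {
      data.table::fwrite(data.frame(marker = sig), path, sep = "\t")
    }
    cor_paths <- c(cor_paths, path)
    ncors[[pf]] <- length(sig)
  }
  note("correlate", cor_paths, ncors)

  ## stage 7: enrichment ----------------------------------------------------
  enpath <- outp("enrichment.tsv")
  if (!is.null(config$enrichment)) {
    coll <- read_gmt(config$enrichment$gmt, config$enrichment$universe)
    coll <- filter_pathways(coll,
                            config$enrichment$min_size %||% 5L,
                            config$enrichment$max_size %||% 2000L)
    sig_prot <- unique(scan_tab$marker[scan_tab$platform == "protein" &
                                         scan_tab$fdr_sig])
    en <- suppressWarnings(ora_test(sig_prot, coll))
    data.table::fwrite(en, enpath, sep = "\t")
    note("enrich", enpath,
         list(n_pathways = nrow(en), n_mapped = attr(en, "n_mapped"),
              n_unmapped = attr(en, "n_unmapped")))
  } else {
    data.table::fwrite(data.frame(pathway = character()), enpath, sep = "\t")
    note("enrich", enpath, list(n_pathways = 0L))
  }

  ## stage 8: QTL/GWAS overlap ----------------------------------------------
  ovp <- outp("qtl_overlap.tsv")
  if (!is.null(config$overlap)) {
    qtl <- as.data.frame(data.table::fread(config$overlap$qtl))
    gwas <- if (!is.null(config$overlap$gwas))
      as.data.frame(data.table::fread(config$overlap$gwas)) else NULL
    sig_all <- unique(scan_tab$marker[scan_tab$fdr_sig])
    rep_tab <- overlap_report(sig_all, qtl, gwas)
    data.table::fwrite(rep_tab, ovp, sep = "\t")
    note("overlap", ovp, list(n_rows = nrow(rep_tab)))
  } else {
    data.table::fwrite(data.frame(marker_id = character()), ovp, sep = "\t")
    note("overlap", ovp, list(n_rows = 0L))
  }

  mpath <- outp("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
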