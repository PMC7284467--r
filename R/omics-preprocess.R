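#' @title Marker matrices and preprocessing
#' @description Container for participant x marker matrices and the protein
#'   preprocessing chain: per-batch natural-log transform, least-squares
#'   age/sex adjustment, and standardization to mean 0, SD 1. Metabolites
#'   are analyzed on their delivered scale.
#' @name omics-preprocess
NULL

#' Construct a marker matrix
#'
#' @param values numeric matrix, participants in rows (rownames are
#'   participant ids), markers in columns (colnames are marker ids).
#' @param platform `"protein"` or `"metabolite"`.
#' @param batch optional per-participant batch labels; required for
#'   proteins.
#' @return object of class `marker_matrix`: list with `values`, `platform`,
#'   `batch`.
#' @export
marker_matrix <- function(values, platform = c("protein", "metabolite"),
                          batch = NULL) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("marker matrix requires participant rownames and marker colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicated marker ids")
  if (platform == "protein") {
    if (is.null(batch)) stop("protein matrices require batch labels")
    if (length(batch) != nrow(values))
      stop("batch labels must match the number of participants")
  }
  structure(list(values = values, platform = platform, batch = batch),
            class = "marker_matrix")
}

marker_matrix_to_df <- function(mm) {
  df <- data.frame(participant_id = rownames(mm$values),
                   stringsAsFactors = FALSE)
  if (!is.null(mm$batch)) df$batch <- mm$batch
  cbind(df, as.data.frame(mm$values, optional = TRUE))
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row with `participant_id`, an optional batch column,
#' and one column per marker.
#'
#' @param path TSV/CSV path.
#' @param platform `"protein"` or `"metabolite"`.
#' @param batch_col batch column name (default `"batch"`); ignored for
#'   metabolites.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, platform = c("protein", "metabolite"),
                               batch_col = "batch") {
  platform <- match.arg(platform)
  df <- as.data.frame(data.table::fread(path))
  stopifnot("participant_id" %in% names(df))
  batch <- NULL
  if (batch_col %in% names(df)) {
    batch <- df[[batch_col]]
    df[[batch_col]] <- NULL
  }
  vals <- as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
  rownames(vals) <- df$participant_id
  marker_matrix(vals, platform, batch = if (platform == "protein") batch)
}

# residualize all columns of Y on cbind(1, covars) with one QR decomposition
residualize <- function(Y, covars) {
  X <- cbind(`(Intercept)` = rep(1, nrow(Y)), covars)
  qr.resid(qr(X), Y)
}

#' Preprocess a protein matrix (per-batch log, age/sex adjust, standardize)
#'
#' Within each batch, raw values are natural-log transformed, residualized
#' on age and a binary sex indicator by least squares, then scaled so that
#' every marker has mean 0 and sample SD 1 within the batch.
#'
#' @param raw a protein [marker_matrix()] with strictly positive values.
#' @param covariates data.frame with `participant_id`, `age`, `sex`
#'   aligned to (a superset of) the matrix rows.
#' @return a `marker_matrix` of preprocessed values (same shape and batch).
#' @export
preprocess_proteins <- function(raw, covariates) {
  stopifnot(inherits(raw, "marker_matrix"))
  if (raw$platform != "protein") stop("expected a protein marker matrix")
  V <- raw$values
  bad <- which(V <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive value for marker '", colnames(V)[bad[1, 2]],
         "', participant '", rownames(V)[bad[1, 1]],
         "'; raw protein values must be > 0 before log transform")
  idx <- match(rownames(V), covariates$participant_id)
  if (anyNA(idx)) stop("covariates missing for some matrix participants")
  age <- covariates$age[idx]
  sexf <- as.numeric(as.character(covariates$sex[idx]) == "female")
  out <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  for (b in unique(raw$batch)) {
    i <- raw$batch == b
    L <- log(V[i, , drop = FALSE])
    sds0 <- apply(L, 2, stats::sd)
    if (any(sds0 == 0))
      stop("constant marker within batch ", b, ": ",
           colnames(V)[which(sds0 == 0)[1]])
    R <- residualize(L, cbind(age = age[i], sex_female = sexf[i]))
    sds <- apply(R, 2, stats::sd)
    if (any(sds < .Machine$double.eps))
      stop("degenerate marker (zero residual variance) within batch ", b,
           ": ", colnames(V)[which(sds < .Machine$double.eps)[1]])
    out[i, ] <- scale(R, center = TRUE, scale = sds)
  }
  marker_matrix(out, "protein", batch = raw$batch)
}

#' Align scores, covariates and markers into the analysis table
#'
#' Applies the exclusion cascade in the reporting order: participants with
#' an invalid or absent dietary record are dropped first, then participants
#' with any missing covariate; the remainder is the analyzed sample
#' (`eligible - excluded_diet - excluded_covariates = analyzed`).
#' Eligibility is defined by presence in the marker matrix.
#'
#' @param scores data.frame with `participant_id` and index totals; rows
#'   present only for participants with a valid dietary record (pre-filter
#'   with [validate_ffq()], or pass `valid`).
#' @param covariates data.frame with `participant_id` and model covariates.
#' @param markers a [marker_matrix()].
#' @param valid optional logical vector aligned to `scores` rows marking
#'   FFQ validity (default: all score rows valid).
#' @param covariate_cols covariate columns checked for missingness.
#' @return list with `data` (joined data.frame), `markers` (row-subset
#'   `marker_matrix`) and `report` (eligible / excluded_diet /
#'   excluded_covariates / analyzed counts).
#' @export
align_tables <- function(scores, covariates, markers, valid = NULL,
                         covariate_cols = c("age", "sex", "energy_kcal",
                                            "smoker", "physical_activity",
                                            "lipid_med", "htn_med", "bmi")) {
  stopifnot(inherits(markers, "marker_matrix"))
  eligible_ids <- rownames(markers$values)
  if (is.null(valid)) valid <- rep(TRUE, nrow(scores))
  good_diet <- scores$participant_id[valid]
  keep1 <- eligible_ids[eligible_ids %in% good_diet]
  excluded_diet <- length(eligible_ids) - length(keep1)

  cc <- covariates[match(keep1, covariates$participant_id),
                   c("participant_id", covariate_cols)]
  has_cov <- !is.na(cc$participant_id) & stats::complete.cases(cc)
  keep2 <- keep1[has_cov]
  excluded_cov <- length(keep1) - length(keep2)
  if (!length(keep2)) stop("no participants remain after exclusions")

  dat <- merge(scores[match(keep2, scores$participant_id), , drop = FALSE],
               covariates[match(keep2, covariates$participant_id), ,
                          drop = FALSE],
               by = "participant_id", sort = FALSE)
  mm <- marker_matrix(markers$values[keep2, , drop = FALSE],
                      markers$platform,
                      batch = if (!is.null(markers$batch))
                        markers$batch[match(keep2, eligible_ids)])
  list(data = dat, markers = mm,
       report = list(eligible = length(eligible_ids),
                     excluded_diet = excluded_diet,
                     excluded_covariates = excluded_cov,
                     analyzed = length(keep2)))
}
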