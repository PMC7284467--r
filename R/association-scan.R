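#' @title Diet-index / marker association scan
#' @description Per-(index, marker) multivariable linear models with the
#'   eight standard covariates, Benjamini-Hochberg FDR and Bonferroni
#'   multiplicity control, and cross-index overlap summaries.
#' @name association-scan
NULL

#' Fit one marker ~ index + covariates linear model
#'
#' Ordinary least squares; the reported coefficient is the change in marker
#' per SD-unit increase of the standardized index. Two-sided p-value from
#' the t distribution with `n - p` degrees of freedom (p includes the
#' intercept).
#'
#' @param y numeric marker vector (no missing values).
#' @param index_std standardized index vector.
#' @param covariates optional numeric data.frame/matrix of adjustment
#'   covariates.
#' @return list with `beta`, `se`, `t`, `p`, `df`.
#' @export
fit_marker_model <- function(y, index_std, covariates = NULL) {
  n <- length(y)
  stopifnot(length(index_std) == n)
  if (anyNA(y) || anyNA(index_std)) stop("missing values in model inputs")
  X <- cbind(`(Intercept)` = 1, index = index_std)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (n <= ncol(X)) stop("too few observations for the design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  if (stats::sd(y) == 0) stop("degenerate: constant marker")
  cf <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  beta <- cf[["index"]]
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in input
#' order.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(m * p_values[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# multi-response OLS for one index: shared design, per-marker stats
scan_one_index <- function(Y, index_std, covars) {
  X <- cbind(`(Intercept)` = 1, index = index_std, covars)
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix in scan")
  df <- n - ncol(X)
  cf <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  sigma2 <- colSums(res^2) / df
  xtxinv22 <- chol2inv(qr.R(qrX))[2, 2]
  beta <- cf["index", ]
  se <- sqrt(sigma2 * xtxinv22)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  degenerate <- col_sds(Y) == 0
  status <- ifelse(degenerate, "degenerate", "ok")
  beta[degenerate] <- NA; se[degenerate] <- NA
  tval[degenerate] <- NA; p[degenerate] <- NA
  data.frame(marker = colnames(Y), beta = beta, se = se, t = tval, p = p,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}

col_sds <- function(Y) apply(Y, 2, stats::sd)

#' Scan every (index, marker) pair
#'
#' Fits a separate multivariable model per index and marker. FDR is applied
#' within each (index, platform) family by default, matching the per-platform
#' Bonferroni denominators; set `fdr_family = "pooled"` to pool the three
#' indices of a platform into one family.
#'
#' @param scores_std data.frame with `participant_id` and one standardized
#'   column per index (e.g. `AHEI`, `DASH`, `MDS`), aligned to the marker
#'   rows.
#' @param markers a [marker_matrix()] (already preprocessed for proteins).
#' @param covariates data.frame aligned to the marker rows with `age`,
#'   `sex`, `energy_kcal`, `smoker`, `physical_activity`, `lipid_med`,
#'   `htn_med`, `bmi`.
#' @param indices index columns of `scores_std` to scan.
#' @param alpha FDR threshold (default 0.05).
#' @param fdr_family `"per_index"` (default) or `"pooled"`.
#' @param bonferroni_m family size for the Bonferroni threshold; defaults
#'   to the platform marker count.
#' @param covariate_cols covariates entering the model.
#' @return data.frame of association records: `index`, `marker`,
#'   `platform`, `beta`, `se`, `t`, `p`, `q`, `fdr_sig`, `bonferroni_sig`,
#'   `status`.
#' @export
run_scan <- function(scores_std, markers, covariates,
                     indices = c("AHEI", "DASH", "MDS"), alpha = 0.05,
                     fdr_family = c("per_index", "pooled"),
                     bonferroni_m = NULL,
                     covariate_cols = c("age", "sex", "energy_kcal",
                                        "smoker", "physical_activity",
                                        "lipid_med", "htn_med", "bmi")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(markers, "marker_matrix"),
            all(indices %in% names(scores_std)))
  ids <- rownames(markers$values)
  ord <- match(ids, scores_std$participant_id)
  if (anyNA(ord)) stop("scores missing for some marker participants")
  cv <- covariates[match(ids, covariates$participant_id), covariate_cols,
                   drop = FALSE]
  if (anyNA(cv)) stop("missing covariates in the analysis sample")
  if ("sex" %in% names(cv))
    cv$sex <- as.numeric(as.character(cv$sex) == "female")
  covars <- as.matrix(cv)
  m <- ncol(markers$values)
  if (is.null(bonferroni_m)) bonferroni_m <- m

  recs <- lapply(indices, function(ix) {
    r <- scan_one_index(markers$values, scores_std[[ix]][ord], covars)
    r$index <- ix
    r
  })
  rec <- do.call(rbind, recs)
  rec$platform <- markers$platform
  rec$q <- NA_real_
  if (fdr_family == "per_index") {
    for (ix in indices) {
      i <- rec$index == ix & rec$status == "ok"
      rec$q[i] <- bh_fdr(rec$p[i])
    }
  } else {
    i <- rec$status == "ok"
    rec$q[i] <- bh_fdr(rec$p[i])
  }
  rec$fdr_sig <- !is.na(rec$q) & rec$q <= alpha
  rec$bonferroni_sig <- !is.na(rec$p) & rec$p <= alpha / bonferroni_m
  rec[, c("index", "marker", "platform", "beta", "se", "t", "p", "q",
          "fdr_sig", "bonferroni_sig", "status")]
}

#' Summarize cross-index overlap of significant markers
#'
#' Set algebra on the FDR-significant markers of each index: per-index
#' counts, all pairwise and triple intersections, and the union, suitable
#' for a three-set Venn diagram.
#'
#' @param records output of [run_scan()].
#' @param flag significance column to use (default `"fdr_sig"`).
#' @return list with `sets` (per-index marker id vectors) and `counts`
#'   (named intersection/union sizes).
#' @export
overlap_sets <- function(records, flag = "fdr_sig") {
  stopifnot(flag %in% names(records))
  idx <- unique(records$index)
  sets <- lapply(idx, function(ix)
    sort(unique(records$marker[records$index == ix & records[[flag]]])))
  names(sets) <- idx
  counts <- list()
  for (ix in idx) counts[[ix]] <- length(sets[[ix]])
  if (length(idx) >= 2) {
    prs <- utils::combn(idx, 2, simplify = FALSE)
    for (p in prs)
      counts[[paste(p, collapse = "&")]] <-
        length(intersect(sets[[p[1]]], sets[[p[2]]]))
  }
  if (length(idx) >= 3) {
    tri <- utils::combn(idx, 3, simplify = FALSE)
    for (p in tri)
      counts[[paste(p, collapse = "&")]] <-
        length(Reduce(intersect, sets[p]))
  }
  counts[["union"]] <- length(unique(unlist(sets)))
  list(sets = sets, counts = counts)
}
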