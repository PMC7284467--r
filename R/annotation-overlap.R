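#' @title QTL / GWAS overlap reports
#' @description Local-table joins of significant markers against
#'   user-supplied QTL and GWAS-trait tables; no network access, exact
#'   string variant matching.
#' @name annotation-overlap
NULL

#' Join significant markers to QTL variants and GWAS traits
#'
#' Inner join of significant markers to their QTL variants, then left join
#' of those variants to GWAS trait rows: markers with a QTL but no catalog
#' trait are retained with empty trait fields. With `collapse = TRUE`
#' (default) multiple trait rows per (marker, variant) are comma-joined
#' into one row, matching the published table layout; with
#' `collapse = FALSE` one row per trait row is emitted.
#'
#' @param significant_markers character vector of marker identifiers.
#' @param qtl data.frame with `marker_id`, `variant_id`, `nearest_gene`
#'   (unique (marker_id, variant_id) pairs).
#' @param gwas data.frame with `variant_id`, `trait`, `accession`; may be
#'   empty.
#' @param collapse collapse multiple traits per variant into one row.
#' @return data.frame: `marker_id`, `variant_id`, `nearest_gene`,
#'   `gwas_traits`, `gwas_accessions`.
#' @export
overlap_report <- function(significant_markers, qtl, gwas = NULL,
                           collapse = TRUE) {
  req <- c("marker_id", "variant_id", "nearest_gene")
  if (!all(req %in% names(qtl)))
    stop("QTL table lacks required columns: ",
         paste(setdiff(req, names(qtl)), collapse = ", "))
  if (anyDuplicated(qtl[, c("marker_id", "variant_id")]))
    stop("QTL (marker_id, variant_id) pairs must be unique")
  if (is.null(gwas))
    gwas <- data.frame(variant_id = character(), trait = character(),
                       accession = character(), stringsAsFactors = FALSE)
  reqg <- c("variant_id", "trait", "accession")
  if (!all(reqg %in% names(gwas)))
    stop("GWAS table lacks required columns: ",
         paste(setdiff(reqg, names(gwas)), collapse = ", "))

  hit <- qtl[qtl$marker_id %in% significant_markers, req, drop = FALSE]
  if (!nrow(hit))
    return(data.frame(marker_id = character(), variant_id = character(),
                      nearest_gene = character(), gwas_traits = character(),
                      gwas_accessions = character(), stringsAsFactors = FALSE))
  joined <- merge(hit, gwas, by = "variant_id", all.x = TRUE, sort = FALSE)
  joined$trait[is.na(joined$trait)] <- ""
  joined$accession[is.na(joined$accession)] <- ""
  if (collapse) {
    key <- paste(joined$marker_id, joined$variant_id, sep = "\r")
    agg <- function(v) vapply(split(v, key), function(x)
      paste(x[nzchar(x)], collapse = ", "), "")
    first <- !duplicated(key)
    out <- data.frame(marker_id = joined$marker_id[first],
                      variant_id = joined$variant_id[first],
                      nearest_gene = joined$nearest_gene[first],
                      stringsAsFactors = FALSE)
    tr <- agg(joined$trait); ac <- agg(joined$accession)
    k <- paste(out$marker_id, out$variant_id, sep = "\r")
    out$gwas_traits <- unname(tr[k])
    out$gwas_accessions <- unname(ac[k])
  } else {
    out <- data.frame(marker_id = joined$marker_id,
                      variant_id = joined$variant_id,
                      nearest_gene = joined$nearest_gene,
                      gwas_traits = joined$trait,
                      gwas_accessions = joined$accession,
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$marker_id, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
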