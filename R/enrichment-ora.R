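#' @title Pathway over-representation analysis
#' @description GMT-backed gene-set collections, pathway-size filtering,
#'   upper-tail hypergeometric enrichment with enrichment ratios and
#'   BH-FDR, plus descriptive metabolite annotation.
#' @name enrichment-ora
NULL

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member identifiers. Duplicate members within a set are
#' deduplicated with a warning. The background universe defaults to the
#' union of all members unless an explicit universe is supplied.
#'
#' @param path GMT file path.
#' @param universe optional character vector overriding the background.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of member vectors) and `background`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    if (f[1] %in% names(sets)) stop("duplicated set name: ", f[1])
    sets[[f[1]]] <- members
  }
  gene_set_collection(sets, universe)
}

#' Build a gene-set collection
#' @param sets named list of member identifier vectors.
#' @param universe optional explicit background; defaults to the union of
#'   all set members. Members outside the universe are dropped.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  background <- if (is.null(universe)) sort(unique(unlist(sets)))
                else sort(unique(universe))
  sets <- lapply(sets, function(m) intersect(unique(m), background))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Filter pathways by size
#'
#' Sizes are computed after restriction to the background; sets with
#' `min_size <= size <= max_size` are retained (so sizes 4 and 2001 are
#' excluded and 5 retained at the defaults).
#'
#' @param collection a `gene_set_collection`.
#' @param min_size,max_size inclusive size bounds (defaults 5 and 2000).
#' @return the filtered collection (background unchanged).
#' @export
filter_pathways <- function(collection, min_size = 5L, max_size = 2000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_size > max_size) stop("min_size must be <= max_size")
  sz <- lengths(collection$sets)
  collection$sets <- collection$sets[sz >= min_size & sz <= max_size]
  collection
}

#' Hypergeometric over-representation test
#'
#' For each pathway with background size N, pathway size K, selection size
#' n and overlap k: upper-tail hypergeometric `p = P(X >= k)` and
#' enrichment ratio `(k/n) / (K/N)`; BH-FDR across the tested pathways.
#' Selected identifiers outside the background are reported and dropped
#' with a warning.
#'
#' @param selected character vector of selected marker identifiers.
#' @param collection a (filtered) `gene_set_collection`.
#' @return data.frame sorted by p: `pathway`, `set_size`, `n_selected`,
#'   `overlap`, `enrichment_ratio`, `p`, `q`, `matched`. Attributes
#'   `n_mapped` / `n_unmapped` record how many selected ids were in the
#'   background.
#' @export
ora_test <- function(selected, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  selected <- unique(selected)
  unmapped <- setdiff(selected, collection$background)
  if (length(unmapped)) {
    warning(length(unmapped), " selected ids outside the background dropped: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
    selected <- setdiff(selected, unmapped)
  }
  N <- length(collection$background)
  n <- length(selected)
  if (n == 0L || !length(collection$sets)) {
    out <- data.frame(pathway = character(), set_size = integer(),
                      n_selected = integer(), overlap = integer(),
                      enrichment_ratio = numeric(), p = numeric(),
                      q = numeric(), matched = character(),
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(names(collection$sets), function(nm) {
      mem <- collection$sets[[nm]]
      K <- length(mem)
      hit <- intersect(selected, mem)
      k <- length(hit)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      data.frame(pathway = nm, set_size = K, n_selected = n, overlap = k,
                 enrichment_ratio = (k / n) / (K / N), p = p,
                 matched = paste(sort(hit), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    out <- out[order(out$p, out$pathway), c("pathway", "set_size",
                                            "n_selected", "overlap",
                                            "enrichment_ratio", "p", "q",
                                            "matched")]
    rownames(out) <- NULL
  }
  attr(out, "n_mapped") <- n
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Descriptive pathway annotation (no test)
#'
#' Maps selected markers to the pathways that contain them, mirroring the
#' descriptive treatment of metabolite sets: no enrichment statistic is
#' computed.
#'
#' @param selected character vector of marker identifiers.
#' @param collection a `gene_set_collection`.
#' @return data.frame: `pathway`, `matched`, `n_matched`.
#' @export
annotate_members <- function(selected, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection$sets), function(nm) {
    hit <- intersect(selected, collection$sets[[nm]])
    if (!length(hit)) return(NULL)
    data.frame(pathway = nm, matched = paste(sort(hit), collapse = ","),
               n_matched = length(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), matched = character(),
                      n_matched = integer(), stringsAsFactors = FALSE)
  out[order(-out$n_matched, out$pathway), , drop = FALSE]
}
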