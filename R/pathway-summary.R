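## Pathway-level DE summaries, annotation coverage percentages, and a
## generic hypergeometric over-representation test on user-supplied
## term -> gene maps.

#' Pathway differential-expression summary table
#'
#' For each pathway, counts the distinct differentially expressed lncRNAs
#' (DELs) and mRNAs (DEMs) annotated to it and reports them as ratios of
#' the study-wide DEL/DEM totals, rounded to 8 decimal places.
#'
#' @param del_ids,dem_ids Character vectors of DE lncRNA / DE mRNA ids.
#' @param pathway_map Data frame `pathway_id, pathway_name, gene_id`.
#' @param total_dels,total_dems Study-wide totals used as ratio
#'   denominators; default to the number of distinct supplied ids.
#' @return Data frame `pathway_id, pathway_name, del_count, del_ratio,
#'   dem_count, dem_ratio`, one row per pathway in map order.
#' @export
pathway_de_table <- function(del_ids, dem_ids, pathway_map,
                             total_dels = length(unique(del_ids)),
                             total_dems = length(unique(dem_ids))) {
  if (total_dels <= 0 || total_dems <= 0)
    stop("totals must be positive (ratio undefined)", call. = FALSE)
  del_ids <- unique(del_ids); dem_ids <- unique(dem_ids)
  paths <- unique(pathway_map[, c("pathway_id", "pathway_name")])
  del_count <- dem_count <- integer(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    genes <- unique(pathway_map$gene_id[
      pathway_map$pathway_id == paths$pathway_id[i]])
    del_count[i] <- sum(del_ids %in% genes)
    dem_count[i] <- sum(dem_ids %in% genes)
  }
  if (any(del_count > total_dels) || any(dem_count > total_dems))
    stop("per-pathway count exceeds supplied total", call. = FALSE)
  data.frame(paths, del_count = del_count,
             del_ratio = round(del_count / total_dels, 8),
             dem_count = dem_count,
             dem_ratio = round(dem_count / total_dems, 8),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotation coverage percentages
#'
#' Percentage of a universe annotated per database, and by the union,
#' rounded to 2 decimal places.
#'
#' @param annotated Named list of character vectors (one per database) or a
#'   named numeric vector of counts.
#' @param universe_size Size of the annotation universe.
#' @return Data frame `database, count, percent`, with a final `union` row
#'   when id sets (not bare counts) were supplied.
#' @export
annotation_coverage <- function(annotated, universe_size) {
  if (universe_size <= 0) stop("universe size must be positive", call. = FALSE)
  if (is.numeric(annotated)) {
    counts <- annotated
    union_n <- NA_integer_
  } else {
    counts <- vapply(annotated, function(s) length(unique(s)), integer(1))
    union_n <- length(unique(unlist(annotated)))
  }
  if (any(counts > universe_size) ||
      (!is.na(union_n) && union_n > universe_size))
    stop("annotated set larger than universe", call. = FALSE)
  out <- data.frame(database = names(counts), count = as.integer(counts),
                    percent = round(100 * counts / universe_size, 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.na(union_n))
    out <- rbind(out, data.frame(
      database = "union", count = union_n,
      percent = round(100 * union_n / universe_size, 2)))
  out
}

#' Hypergeometric over-representation test
#'
#' For every term, the one-sided upper-tail probability of observing at
#' least the seen number of study genes annotated to the term, under
#' sampling without replacement from the universe.
#'
#' @param study Character vector of study gene ids (must lie in `universe`).
#' @param term_map Data frame `term_id, gene_id` (term genes outside the
#'   universe are clipped with a warning).
#' @param universe Character vector: the gene universe.
#' @param alpha Significance threshold on the raw p-value (default 0.01,
#'   strict); Benjamini-Hochberg adjustment available via `adjust = "BH"`.
#' @param adjust Passed to [stats::p.adjust()]; default `"none"`.
#' @return Data frame `term_id, k (study hits), m (term size), n (study
#'   size), N (universe size), p, enriched`.
#' @export
hypergeometric_enrichment <- function(study, term_map, universe,
                                      alpha = 0.01, adjust = "none") {
  study <- unique(study); universe <- unique(universe)
  if (!all(study %in% universe))
    stop("study set must be a subset of the universe", call. = FALSE)
  N <- length(universe); n <- length(study)
  terms <- unique(term_map$term_id)
  k <- m <- integer(length(terms)); p <- numeric(length(terms))
  clipped <- FALSE
  for (i in seq_along(terms)) {
    genes <- unique(term_map$gene_id[term_map$term_id == terms[i]])
    if (!all(genes %in% universe)) {
      clipped <- TRUE
      genes <- intersect(genes, universe)
    }
    m[i] <- length(genes)
    k[i] <- length(intersect(genes, study))
    p[i] <- stats::phyper(k[i] - 1, m[i], N - m[i], n, lower.tail = FALSE)
  }
  if (clipped) warning("term genes outside the universe were clipped",
                       call. = FALSE)
  padj <- stats::p.adjust(p, method = adjust)
  data.frame(term_id = terms, k = k, m = m, n = n, N = N, p = padj,
             enriched = padj < alpha, stringsAsFactors = FALSE)
}
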