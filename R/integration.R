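## Microbiota-gene integration: Pearson correlation of pathway gene
## expression against genus relative abundances, with star annotation.

#' Significance stars for p-values
#'
#' `***` for p < 0.001, `**` for 0.001 <= p < 0.01, `*` for
#' 0.01 <= p < 0.05, empty otherwise. The three cut points partition
#' (0, 1] exactly.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "")))
}

#' Gene x genus correlation grid
#'
#' Pearson correlation (with two-sided t-approximation p-value) of every
#' gene expression profile against every genus abundance profile over the
#' shared samples, annotated with significance stars.
#'
#' @param gene_expr Numeric matrix, genes x samples (rownames = gene ids).
#' @param abundance Numeric matrix, genera x samples (rownames = genus
#'   names); columns must match `gene_expr`'s samples.
#' @return Long-format data frame `gene_id, genus, r, p, stars`, row-major
#'   over genes then genera. Zero-variance profiles give NA r/p and an
#'   `NA`-star flag.
#' @export
gene_microbe_matrix <- function(gene_expr, abundance) {
  if (is.null(colnames(gene_expr)) || is.null(colnames(abundance))) {
    if (ncol(gene_expr) != ncol(abundance))
      stop("sample mismatch between expression and abundance", call. = FALSE)
  } else {
    miss <- c(setdiff(colnames(gene_expr), colnames(abundance)),
              setdiff(colnames(abundance), colnames(gene_expr)))
    if (length(miss) > 0)
      stop("sample mismatch; missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    abundance <- abundance[, colnames(gene_expr), drop = FALSE]
  }
  if (ncol(gene_expr) < 3L) stop("need n >= 3 samples", call. = FALSE)
  out <- expand.grid(genus = rownames(abundance),
                     gene_id = rownames(gene_expr),
                     stringsAsFactors = FALSE)[, 2:1]
  cells <- mapply(function(g, b) {
    x <- as.numeric(gene_expr[g, ]); y <- as.numeric(abundance[b, ])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    cc <- correlation_with_p(x, y)
    c(cc$r, cc$p)
  }, out$gene_id, out$genus)
  out$r <- cells[1, ]
  out$p <- cells[2, ]
  out$stars <- ifelse(is.na(out$p), NA_character_, p_stars(out$p))
  if (anyNA(out$r))
    warning("zero-variance profile(s): correlation undefined there",
            call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Select pathway DE genes and most-changed genera
#'
#' Restricts genes to the differentially expressed members of a pathway
#' gene set, and genera to the `top_k` with the largest absolute change in
#' group-mean relative abundance between the two groups.
#'
#' @param de Data frame with `transcript_id` and `direction` columns.
#' @param pathway_ids Character vector of pathway member ids.
#' @param abundance Genera x samples abundance matrix.
#' @param groups Group label per abundance sample.
#' @param top_k Number of genera to keep (must not exceed the number of
#'   genera).
#' @param treatment,control Group labels (defaults `"A"`, `"C"`).
#' @return List with `genes` (character vector) and `genera` (abundance
#'   matrix restricted to the selected genera, ranked by change).
#' @export
select_features <- function(de, pathway_ids, abundance, groups, top_k,
                            treatment = "A", control = "C") {
  if (top_k > nrow(abundance))
    stop("top_k exceeds the number of genera", call. = FALSE)
  genes <- intersect(
    de$transcript_id[de$direction %in% c("up", "down")], pathway_ids)
  if (length(genes) == 0L)
    warning("no differentially expressed pathway genes selected",
            call. = FALSE)
  change <- abs(rowMeans(abundance[, groups == treatment, drop = FALSE]) -
                rowMeans(abundance[, groups == control, drop = FALSE]))
  keep <- order(change, decreasing = TRUE)[seq_len(top_k)]
  list(genes = genes, genera = abundance[keep, , drop = FALSE])
}
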