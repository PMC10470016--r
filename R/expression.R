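## Normalization, low-expression filtering, two-group differential
## expression, sample diagnostics, DE summary arithmetic and 2^-ddCt.
##
## An expression matrix is a list with:
##   counts  - numeric matrix, transcripts x samples (rownames = ids)
##   lengths - effective transcript lengths in bp (named or row-ordered)
##   groups  - character vector per sample, two levels (default "A"/"C")

expr_matrix <- function(counts, lengths, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (length(lengths) != nrow(counts))
    stop("one length per transcript required", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (length(groups) != ncol(counts))
    stop("one group label per sample required", call. = FALSE)
  structure(list(counts = counts, lengths = as.numeric(lengths),
                 groups = as.character(groups)),
            class = "expr_matrix")
}

#' Transcripts-per-million normalization
#'
#' Per sample, `rate_i = count_i / length_i` and
#' `TPM_i = 1e6 * rate_i / sum(rate)`, so every column sums to one million.
#'
#' @param x An expression matrix (list with `counts`, `lengths`, `groups`)
#'   or a plain counts matrix with `lengths` supplied.
#' @param lengths Effective lengths in bp when `x` is a plain matrix.
#' @return Numeric matrix of TPM values, same dimnames as the counts.
#' @export
compute_tpm <- function(x, lengths = NULL) {
  m <- normalize_inputs(x, lengths)
  rate <- m$counts / m$lengths
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero sample column: TPM undefined, returning NaN")
  sweep(rate, 2, tot, "/") * 1e6
}

#' FPKM normalization
#'
#' `FPKM_i = count_i * 1e9 / (length_i * library_size)` with library size
#' the per-sample count total.
#'
#' @inheritParams compute_tpm
#' @return Numeric matrix of FPKM values.
#' @export
compute_fpkm <- function(x, lengths = NULL) {
  m <- normalize_inputs(x, lengths)
  lib <- colSums(m$counts)
  if (any(lib == 0)) warning("zero library size: FPKM undefined, returning NaN")
  sweep(m$counts / m$lengths, 2, lib, "/") * 1e9
}

normalize_inputs <- function(x, lengths) {
  if (inherits(x, "expr_matrix")) return(x)
  if (is.null(lengths)) stop("lengths required for a plain counts matrix",
                             call. = FALSE)
  counts <- as.matrix(x)
  if (length(lengths) != nrow(counts))
    stop("one length per transcript required", call. = FALSE)
  list(counts = counts, lengths = as.numeric(lengths))
}

#' Drop transcripts never reaching an FPKM of 1
#'
#' A transcript is retained iff its FPKM is >= `threshold` in at least one
#' sample; transcripts below threshold in every sample are filtered out.
#'
#' @param fpkm FPKM matrix (transcripts x samples, rownames = ids).
#' @param threshold Retention threshold (default 1).
#' @return Character vector of retained transcript ids.
#' @export
filter_low_expression <- function(fpkm, threshold = 1) {
  keep <- apply(fpkm >= threshold, 1, any)
  rownames(fpkm)[keep]
}

#' Two-group differential expression on FPKM
#'
#' Fold change is computed on group-mean FPKM with a pseudo-count of 1:
#' `log2fc = log2((mean_A + 1) / (mean_C + 1))`. The p-value comes from a
#' Welch two-sample t-test on `log2(FPKM + 1)`. A transcript is called
#' `up` when `log2fc > lfc_cut` and `p < p_cut`, `down` when
#' `log2fc < -lfc_cut` and `p < p_cut`, otherwise `ns` (both comparisons
#' strict). At the study's n = 3 per group the t-test has few degrees of
#' freedom; calls should be validated against planted truth (see the
#' methods vignette).
#'
#' @param fpkm FPKM matrix, transcripts x samples.
#' @param groups Character vector of sample group labels (two levels).
#' @param treatment,control The two group labels; fold change is
#'   treatment over control. Defaults `"A"` over `"C"`.
#' @param lfc_cut,p_cut Call thresholds (defaults 1 and 0.001, both strict).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values are thresholded); `"BH"` available.
#' @return Data frame `transcript_id, log2fc, p, direction`.
#' @export
differential_expression <- function(fpkm, groups, treatment = "A",
                                    control = "C", lfc_cut = 1,
                                    p_cut = 0.001, adjust = "none") {
  a <- groups == treatment
  c_ <- groups == control
  if (sum(a) < 2L || sum(c_) < 2L)
    stop("at least 2 samples per group are required", call. = FALSE)
  la <- log2(fpkm[, a, drop = FALSE] + 1)
  lc <- log2(fpkm[, c_, drop = FALSE] + 1)
  welch <- row_welch(la, lc)
  lfc <- log2((rowMeans(fpkm[, a, drop = FALSE]) + 1) /
              (rowMeans(fpkm[, c_, drop = FALSE]) + 1))
  p <- stats::p.adjust(welch$p, method = adjust)
  direction <- ifelse(lfc > lfc_cut & p < p_cut, "up",
               ifelse(lfc < -lfc_cut & p < p_cut, "down", "ns"))
  data.frame(transcript_id = rownames(fpkm), log2fc = unname(lfc),
             p = unname(p), direction = unname(direction),
             stringsAsFactors = FALSE)
}

## Vectorized Welch t-test across rows of two matrices.
## Rows with zero variance in both groups get p = 1 (test undefined).
row_welch <- function(xa, xc) {
  na <- ncol(xa); nc <- ncol(xc)
  ma <- rowMeans(xa); mc <- rowMeans(xc)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vc <- rowSums((xc - mc)^2) / (nc - 1)
  se2 <- va / na + vc / nc
  degenerate <- se2 == 0
  if (any(degenerate))
    warning("zero within-group variance in both groups for ",
            sum(degenerate), " transcript(s): p set to 1", call. = FALSE)
  tstat <- (ma - mc) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vc / nc)^2 / (nc - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[degenerate] <- 1
  list(t = tstat, df = df, p = p)
}

#' Pairwise sample correlations and PCA on log2(FPKM + 1)
#'
#' @param fpkm FPKM matrix, transcripts x samples.
#' @return List with `r` and `r2` sample-by-sample Pearson matrices, and
#'   `pca`: scores (samples x PCs) plus `variance_share` per component.
#' @export
sample_diagnostics <- function(fpkm) {
  if (ncol(fpkm) < 2L) stop("at least 2 samples required", call. = FALSE)
  lf <- log2(fpkm + 1)
  sds <- apply(lf, 2, stats::sd)
  if (any(sds == 0))
    warning("constant sample column(s): correlation undefined there",
            call. = FALSE)
  r <- suppressWarnings(stats::cor(lf))
  pc <- stats::prcomp(t(lf), center = TRUE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  list(r = r, r2 = r^2,
       pca = list(scores = pc$x, variance_share = share))
}

#' Summarize differential-expression calls by class and novelty
#'
#' @param de Data frame with a `direction` column (`up`/`down`/`ns`).
#' @param class Optional biotype per row (e.g. `"lncRNA"`/`"mRNA"`).
#' @param status Optional `"known"`/`"novel"` flag per row.
#' @return Data frame with one row per (class, status) stratum plus the
#'   per-class and grand totals; columns `up`, `down`, `total` with
#'   `total = up + down`.
#' @export
summarize_de <- function(de, class = NULL, status = NULL) {
  dir <- de$direction
  class <- class %||% rep("all", length(dir))
  status <- status %||% rep("all", length(dir))
  strata <- interaction(class, status, drop = TRUE, sep = "|")
  count <- function(mask) {
    data.frame(up = sum(dir == "up" & mask), down = sum(dir == "down" & mask))
  }
  rows <- lapply(levels(strata), function(s) {
    cbind(data.frame(class = sub("\\|.*", "", s),
                     status = sub(".*\\|", "", s)), count(strata == s))
  })
  out <- do.call(rbind, rows)
  per_class <- lapply(unique(out$class), function(cl) {
    cbind(data.frame(class = cl, status = "all"), count(class == cl))
  })
  grand <- cbind(data.frame(class = "all", status = "all"),
                 count(rep(TRUE, length(dir))))
  out <- rbind(out, do.call(rbind, per_class), grand)
  out$total <- out$up + out$down
  out <- out[!duplicated(out[, c("class", "status")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = dCt - mean(dCt over control samples)`; the relative expression
#' is `2^-ddCt` (control-group mean is 1 by construction on the log scale).
#'
#' @param ct Numeric matrix of Ct values, genes x samples, with the
#'   reference gene as one row.
#' @param reference_gene Row name of the internal-control gene.
#' @param groups Group label per sample.
#' @param control_group Label of the calibrator group (default `"C"`).
#' @return Matrix of relative expression for all non-reference genes.
#' @export
ddct <- function(ct, reference_gene, groups, control_group = "C") {
  if (!reference_gene %in% rownames(ct))
    stop("reference gene '", reference_gene, "' not present", call. = FALSE)
  ref <- ct[reference_gene, ]
  if (anyNA(ref)) stop("missing reference Ct", call. = FALSE)
  targets <- setdiff(rownames(ct), reference_gene)
  dct <- sweep(ct[targets, , drop = FALSE], 2, ref, "-")
  ctrl <- groups == control_group
  if (!any(ctrl)) stop("no samples in control group", call. = FALSE)
  ddct_ <- sweep(dct, 1, rowMeans(dct[, ctrl, drop = FALSE]), "-")
  2^(-ddct_)
}
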