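## lncRNA target prediction: cis genomic windows, trans duplex energy,
## dual-correlation coexpression, and overlap classification.

#' Cis target genes of lncRNAs by genomic windows
#'
#' A gene is a cis target of a lncRNA when its genomic span intersects the
#' window from `up_window` bp upstream of the lncRNA to `down_window` bp
#' downstream of it, with upstream/downstream taken in the lncRNA's strand
#' orientation (for a minus-strand lncRNA the upstream window extends to
#' higher coordinates). Overlapping genes are included with distance 0;
#' otherwise the signed distance is negative upstream and positive
#' downstream of the lncRNA.
#'
#' @param lncrnas,genes Data frames with columns `transcript_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (1-based inclusive).
#' @param up_window,down_window Window sizes in bp (defaults 10000 upstream,
#'   20000 downstream).
#' @return Data frame `lncrna_id, gene_id, distance` (one row per pair).
#' @export
cis_targets <- function(lncrnas, genes, up_window = 10000, down_window = 20000) {
  check_records(lncrnas); check_records(genes)
  if (nrow(lncrnas) == 0L || nrow(genes) == 0L)
    return(empty_pairs(c("lncrna_id", "gene_id", "distance")))
  minus <- lncrnas$strand == "-"
  win_start <- ifelse(minus, lncrnas$start - down_window,
                      lncrnas$start - up_window)
  win_end <- ifelse(minus, lncrnas$end + up_window,
                    lncrnas$end + down_window)
  win <- GenomicRanges::GRanges(
    lncrnas$chrom,
    IRanges::IRanges(pmax(1, win_start), win_end)
  )
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(win, g, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (length(i) == 0L)
    return(empty_pairs(c("lncrna_id", "gene_id", "distance")))
  dist <- signed_distance(lncrnas$start[i], lncrnas$end[i], minus[i],
                          genes$start[j], genes$end[j])
  out <- data.frame(lncrna_id = lncrnas$transcript_id[i],
                    gene_id = genes$transcript_id[j],
                    distance = dist, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Signed gap between a gene span and a lncRNA span, oriented by the
## lncRNA strand: negative = gene on the lncRNA's 5' (upstream) side,
## positive = 3' (downstream), 0 = overlapping.
signed_distance <- function(l_start, l_end, l_minus, g_start, g_end) {
  left_gap <- l_start - g_end    # gene entirely left of lncRNA when > 0
  right_gap <- g_start - l_end   # gene entirely right of lncRNA when > 0
  d <- numeric(length(l_start))
  left <- left_gap > 0; right <- right_gap > 0
  d[left] <- ifelse(l_minus[left], left_gap[left], -left_gap[left])
  d[right] <- ifelse(l_minus[right], -right_gap[right], right_gap[right])
  d
}

check_records <- function(x) {
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(x)))
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(x) > 0 && !all(x$strand %in% c("+", "-")))
    stop("unknown strand (must be '+' or '-')", call. = FALSE)
  invisible(x)
}

empty_pairs <- function(cols) {
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  for (nm in intersect(cols, c("distance", "energy", "r_pearson", "r_spearman")))
    out[[nm]] <- numeric(0)
  out
}

## Nearest-neighbor Watson-Crick stack free energies (kcal/mol, 37 C),
## Turner-style values. Keyed by the top-strand 5'->3' dinucleotide; the
## bottom strand is the antiparallel Watson-Crick complement. The table is
## self-consistent under reading the duplex from the other strand:
## E(XY) = E(revcomp(XY)).
STACK_ENERGY <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  CU = -2.08, AG = -2.08,
  CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)

#' Minimum hybridization free energy of two RNAs
#'
#' Scans all antiparallel Watson-Crick duplex windows formed by contiguous
#' complementary stretches of the two sequences and returns the most
#' negative sum of nearest-neighbor stack energies (kcal/mol). Loops,
#' bulges and G-U wobbles are not modeled: this is a deliberate
#' contiguous-helix simplification, and externally computed energies can be
#' supplied to [trans_targets()] instead.
#'
#' @param seq_a,seq_b RNA sequences (character scalars; `T` is accepted and
#'   read as `U`).
#' @return Free energy in kcal/mol; 0 when no two adjacent complementary
#'   base pairs exist.
#' @export
duplex_energy <- function(seq_a, seq_b) {
  a <- rna_ints(seq_a); b <- rna_ints(seq_b)
  if (length(a) < 2L || length(b) < 2L) return(0)
  ## Antiparallel pairing: a[i] with b[j], the next stacked pair is
  ## (a[i+1], b[j-1]), so a helix lives on one antidiagonal i + j = const.
  ## On each antidiagonal the problem reduces to the minimum-sum contiguous
  ## run over pairable positions.
  comp <- c(4L, 3L, 2L, 1L)  # A<->U, C<->G as integers 1..4 (A C G U)
  best <- 0
  nb <- length(b)
  for (d in 2L:(length(a) + nb)) {
    i <- max(1L, d - nb):min(length(a), d - 1L)
    if (length(i) < 2L) next
    j <- d - i
    ok <- a[i] == comp[b[j]]
    if (sum(ok) < 2L) next
    ## stack between consecutive pairable positions i, i+1 on the diagonal
    step_ok <- ok[-length(ok)] & ok[-1]
    if (!any(step_ok)) next
    key <- (a[i[-length(i)]] - 1L) * 4L + a[i[-1]]
    e <- STACK_ENERGY_MAT[key]
    e[!step_ok] <- NA_real_
    best <- min(best, min_run_sum(e))
  }
  best
}

## Minimum over contiguous runs (NA breaks a run) of cumulative sums.
min_run_sum <- function(e) {
  best <- 0; acc <- 0
  for (v in e) {
    if (is.na(v)) { acc <- 0 } else { acc <- min(v, acc + v); best <- min(best, acc) }
  }
  best
}

STACK_ENERGY_MAT <- {
  bases <- c("A", "C", "G", "U")
  m <- numeric(16)
  for (x in 1:4) for (y in 1:4)
    m[(x - 1) * 4 + y] <- STACK_ENERGY[paste0(bases[x], bases[y])]
  m
}

rna_ints <- function(seq) {
  s <- chartr("acgutT", "ACGUUU", as.character(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(v, c("A", "C", "G", "U"))
  if (anyNA(code))
    stop("non-nucleotide character in sequence: ",
         paste(unique(v[is.na(code)]), collapse = ","), call. = FALSE)
  code
}

#' Trans target genes of lncRNAs by duplex energy
#'
#' A gene is a trans target of a lncRNA when their duplex energy is
#' strictly below `threshold` kcal/mol AND the gene lies outside the
#' lncRNA's cis window (cis and trans are mutually exclusive).
#'
#' @inheritParams cis_targets
#' @param sequences Named character vector of transcript sequences, used
#'   when `energies` is not supplied.
#' @param energies Optional precomputed energy table
#'   (`lncrna_id, gene_id, energy`), e.g. from a full secondary-structure
#'   tool; rows absent from the table are treated as non-binding.
#' @param threshold Energy threshold, default -30 kcal/mol (strict `<`).
#' @return Data frame `lncrna_id, gene_id, energy`.
#' @export
trans_targets <- function(lncrnas, genes, sequences = NULL, energies = NULL,
                          threshold = -30, up_window = 10000,
                          down_window = 20000) {
  check_records(lncrnas); check_records(genes)
  cis <- cis_targets(lncrnas, genes, up_window, down_window)
  cis_key <- paste(cis$lncrna_id, cis$gene_id)
  out <- empty_pairs(c("lncrna_id", "gene_id", "energy"))
  for (li in seq_len(nrow(lncrnas))) {
    for (gi in seq_len(nrow(genes))) {
      lid <- lncrnas$transcript_id[li]; gid <- genes$transcript_id[gi]
      if (paste(lid, gid) %in% cis_key) next
      e <- if (!is.null(energies)) {
        hit <- energies$lncrna_id == lid & energies$gene_id == gid
        if (any(hit)) energies$energy[hit][1] else 0
      } else {
        if (is.null(sequences) || !all(c(lid, gid) %in% names(sequences)))
          stop("missing sequence for ", lid, " or ", gid,
               " and no precomputed energy", call. = FALSE)
        duplex_energy(sequences[[lid]], sequences[[gid]])
      }
      if (e < threshold)
        out <- rbind(out, data.frame(lncrna_id = lid, gene_id = gid,
                                     energy = e, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Coexpressed target genes by dual correlation thresholds
#'
#' A (lncRNA, gene) pair is a coexpression target when signed Pearson
#' r >= `r_min` AND signed Spearman rho >= `r_min` across samples (average
#' ranks for ties). With `unsigned = TRUE` the thresholds apply to |r|.
#'
#' @param lnc_expr,gene_expr Numeric matrices (features x samples) with the
#'   same sample columns.
#' @param r_min Threshold for both coefficients (default 0.6, inclusive).
#' @param unsigned Apply thresholds to absolute values (default FALSE).
#' @return Data frame `lncrna_id, gene_id, r_pearson, r_spearman`.
#' @export
coexpression_targets <- function(lnc_expr, gene_expr, r_min = 0.6,
                                 unsigned = FALSE) {
  if (ncol(lnc_expr) != ncol(gene_expr))
    stop("matrices must share samples", call. = FALSE)
  if (ncol(lnc_expr) < 3L) stop("need n >= 3 samples", call. = FALSE)
  const_l <- apply(lnc_expr, 1, function(x) stats::sd(x) == 0)
  const_g <- apply(gene_expr, 1, function(x) stats::sd(x) == 0)
  if (any(const_l) || any(const_g))
    warning("zero-variance profile(s) skipped", call. = FALSE)
  lm_ <- lnc_expr[!const_l, , drop = FALSE]
  gm <- gene_expr[!const_g, , drop = FALSE]
  if (nrow(lm_) == 0L || nrow(gm) == 0L)
    return(empty_pairs(c("lncrna_id", "gene_id", "r_pearson", "r_spearman")))
  rp <- stats::cor(t(lm_), t(gm), method = "pearson")
  rs <- stats::cor(t(lm_), t(gm), method = "spearman")
  score_p <- if (unsigned) abs(rp) else rp
  score_s <- if (unsigned) abs(rs) else rs
  hit <- which(score_p >= r_min & score_s >= r_min, arr.ind = TRUE)
  out <- data.frame(lncrna_id = rownames(lm_)[hit[, 1]],
                    gene_id = rownames(gm)[hit[, 2]],
                    r_pearson = rp[hit], r_spearman = rs[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the genomic overlap of a lncRNA and a gene
#'
#' For spans on the same chromosome that intersect: same strand with one
#' span fully containing the other is `overlap`; opposite strand with
#' containment is `anti-overlap`; same strand with a partial intersection
#' is `incomplete`; opposite strand partial is `anti-incomplete`.
#' Non-intersecting spans (or different chromosomes) are `none`.
#'
#' @param lnc,gene Single-row data frames (or lists) with `chrom`,
#'   `strand`, `start`, `end`.
#' @return One of `"none"`, `"overlap"`, `"anti-overlap"`, `"incomplete"`,
#'   `"anti-incomplete"`.
#' @export
classify_overlap <- function(lnc, gene) {
  if (lnc$chrom != gene$chrom) return("none")
  if (lnc$end < gene$start || gene$end < lnc$start) return("none")
  same <- lnc$strand == gene$strand
  contained <- (lnc$start >= gene$start && lnc$end <= gene$end) ||
    (gene$start >= lnc$start && gene$end <= lnc$end)
  if (contained) {
    if (same) "overlap" else "anti-overlap"
  } else {
    if (same) "incomplete" else "anti-incomplete"
  }
}
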