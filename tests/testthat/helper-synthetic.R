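# Shared fixtures, built in code.

# Small two-group study used by several modules.
small_study <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_mrna = 40, n_lncrna = 30, n_mirna = 10,
         de_fraction = 0.5, lfc_location = 3, nb_dispersion = 0.01,
         n_planted_triads = 4),
    list(...))
  cfg <- do.call(simulation_config, args)
  ann <- generate_annotation(cfg)
  cc <- generate_counts(ann, cfg)
  list(cfg = cfg, ann = ann, counts = cc)
}

# Conditions under which the pipeline recovers planted truth exactly:
# no classifier noise, strong planted effect, near-deterministic counts,
# exact planted anti-correlation, and 5 replicates per group (the Welch
# test's df collapses at n = 3; see the methods vignette).
closure_config <- function(seed) {
  simulation_config(seed = seed, n_mrna = 120, n_lncrna = 80, n_mirna = 8,
                    n_samples_per_group = 5, de_fraction = 0.3,
                    lfc_location = 6, nb_dispersion = 5e-4,
                    n_planted_triads = 3, triad_r = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent O(n^2) interval scan used as the cis-window oracle.
brute_cis <- function(lncrnas, genes, up = 10000, down = 20000) {
  hits <- list()
  for (i in seq_len(nrow(lncrnas))) for (j in seq_len(nrow(genes))) {
    l <- lncrnas[i, ]; g <- genes[j, ]
    if (l$chrom != g$chrom) next
    ws <- if (l$strand == "+") l$start - up else l$start - down
    we <- if (l$strand == "+") l$end + down else l$end + up
    if (g$end >= max(ws, 1) && g$start <= we)
      hits[[length(hits) + 1L]] <- paste(l$transcript_id, g$transcript_id)
  }
  unlist(hits) %||% character(0)
}

# A transcript record row for interval tests.
rec <- function(id, start, end, strand = "+", chrom = "chr1") {
  data.frame(transcript_id = id, chrom = chrom, strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)
}

# Random Watson-Crick RNA sequence.
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

revcomp_rna <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Vectors with an exact sample Pearson correlation r (orthonormal
# construction), for closed-form p-value checks.
pair_with_r <- function(r, n, seed = 1) {
  set.seed(seed)
  z <- scale(stats::rnorm(n))[, 1]
  e <- stats::rnorm(n)
  e <- scale(e - z * sum(e * z) / sum(z * z))[, 1]
  list(x = z, y = r * z + sqrt(1 - r^2) * e)
}
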