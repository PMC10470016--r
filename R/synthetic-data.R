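## Synthetic-data generator. Emulates the statistical structure the
## analysis assumes -- a two-group (antibiotic "A" vs control "C") design
## with three biological replicates, negative-binomially dispersed counts
## with a planted differentially expressed fraction, classifier scores
## correlated with a planted biotype, a miRNA layer with planted
## sign-consistent ceRNA triads, and genus abundances with planted
## gene-genus correlations -- and returns ground-truth labels so every
## downstream stage has a parameter-recovery test.

#' Simulation configuration
#'
#' Validated parameter bundle for all generators. The same configuration
#' (including `seed`) always yields byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_mrna,n_lncrna,n_mirna Feature counts.
#' @param n_samples_per_group Replicates per group (default 3, the usual
#'   bulk RNA-seq design); values below 2 leave the DE test undefined.
#' @param de_fraction Probability that a transcript is planted as
#'   differentially expressed, in [0, 1].
#' @param lfc_location Planted group-mean shift in log2 units (applied as
#'   +/- `lfc_location` to group A).
#' @param nb_dispersion Negative-binomial dispersion (> 0); the NB size
#'   parameter is its reciprocal.
#' @param n_genera Number of microbiota genera.
#' @param n_planted_triads Number of planted ceRNA triads.
#' @param genome_length Genome size in bp; `NULL` auto-sizes to fit all
#'   loci without mandatory overlap.
#' @param cis_fraction,overlap_fraction Fractions of lncRNAs placed within
#'   the cis window of an mRNA, resp. overlapping one; the remainder are
#'   isolated (> 30 kb from every mRNA).
#' @param triad_r Target anti-correlation magnitude for planted triads.
#' @param sf_sigma Log-normal sigma of per-sample library size factors.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_mrna = 120L, n_lncrna = 80L,
                              n_mirna = 20L, n_samples_per_group = 3L,
                              de_fraction = 0.4, lfc_location = 2,
                              nb_dispersion = 0.1, n_genera = 12L,
                              n_planted_triads = 5L, genome_length = NULL,
                              cis_fraction = 0.3, overlap_fraction = 0.2,
                              triad_r = 0.9, sf_sigma = 0.2) {
  cfg <- list(seed = as.integer(seed), n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
              n_samples_per_group = as.integer(n_samples_per_group),
              de_fraction = de_fraction, lfc_location = lfc_location,
              nb_dispersion = nb_dispersion, n_genera = as.integer(n_genera),
              n_planted_triads = as.integer(n_planted_triads),
              genome_length = genome_length, cis_fraction = cis_fraction,
              overlap_fraction = overlap_fraction, triad_r = triad_r,
              sf_sigma = sf_sigma)
  counts <- c("n_mrna", "n_lncrna", "n_mirna", "n_genera",
              "n_planted_triads", "n_samples_per_group")
  for (nm in counts)
    if (cfg[[nm]] < 0L) stop(nm, " must be nonnegative", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (cis_fraction + overlap_fraction > 1)
    stop("cis_fraction + overlap_fraction must not exceed 1", call. = FALSE)
  if (triad_r <= 0 || triad_r > 1)
    stop("triad_r must lie in (0, 1]", call. = FALSE)
  slot <- 80000
  required <- (cfg$n_mrna + cfg$n_lncrna + 1L) * slot
  if (is.null(genome_length)) cfg$genome_length <- required
  else if (genome_length < required)
    stop("genome_length ", genome_length, " too small to place all loci (need ",
         required, " bp)", call. = FALSE)
  cfg$slot <- slot
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a transcript annotation with controlled lncRNA placement
#'
#' Places `n_mrna` multi-exon mRNA loci in non-overlapping slots, then
#' places lncRNAs in three strata: a `cis_fraction` within the 10 kb
#' upstream / 20 kb downstream cis window of some mRNA, an
#' `overlap_fraction` overlapping an mRNA (cycling through contained /
#' partial on the same / opposite strand), and the rest isolated. Every
#' lncRNA gets >= 2 exons and spliced length > 200 bp so it survives the
#' candidate filter; mRNAs get 2-8 exons.
#'
#' @param config A [simulation_config()].
#' @return List with data frames `transcripts` (`transcript_id, chrom,
#'   strand, start, end, biotype, status, placement`) and `exons`
#'   (`transcript_id, start, end`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    n_m <- config$n_mrna; n_l <- config$n_lncrna
    tx <- list(); ex <- list()
    add <- function(id, strand, start, exon_widths, intron_widths, biotype,
                    status, placement) {
      starts <- start +
        cumsum(c(0, exon_widths[-length(exon_widths)] + intron_widths))
      ends <- starts + exon_widths - 1
      tx[[length(tx) + 1L]] <<- data.frame(
        transcript_id = id, chrom = "chr1", strand = strand,
        start = starts[1], end = ends[length(ends)], biotype = biotype,
        status = status, placement = placement, stringsAsFactors = FALSE)
      ex[[length(ex) + 1L]] <<- data.frame(
        transcript_id = id, start = starts, end = ends,
        stringsAsFactors = FALSE)
      invisible(NULL)
    }
    slot <- config$slot
    mrna_anchor <- integer(n_m)
    mrna_end <- integer(n_m)
    for (i in seq_len(n_m)) {
      start <- (i - 1L) * slot + 25000L
      n_exon <- sample(2:8, 1)
      widths <- sample(150:600, n_exon, replace = TRUE)
      introns <- sample(100:800, max(n_exon - 1, 1), replace = TRUE)[
        seq_len(n_exon - 1)]
      strand <- sample(c("+", "-"), 1)
      add(sprintf("MRNA_%04d", i), strand, start, widths, introns, "mRNA",
          sample(c("known", "novel"), 1, prob = c(0.67, 0.33)), "slot")
      mrna_anchor[i] <- start
      mrna_end[i] <- start + sum(widths) + sum(introns) - 1L
    }
    n_cis <- round(config$cis_fraction * n_l)
    n_ov <- round(config$overlap_fraction * n_l)
    n_iso <- n_l - n_cis - n_ov
    if (n_l > 0 && (n_cis + n_ov) > 0 && n_m == 0)
      stop("cannot place cis/overlapping lncRNAs without mRNAs",
           call. = FALSE)
    ov_modes <- c("contained_same", "contained_opp",
                  "partial_same", "partial_opp")
    li <- 0L
    lnc_exons <- function() {
      n_exon <- sample(2:4, 1)
      widths <- sample(120:500, n_exon, replace = TRUE)
      if (sum(widths) <= 200) widths[1] <- widths[1] + 200L
      introns <- sample(80:400, max(n_exon - 1, 1), replace = TRUE)[
        seq_len(n_exon - 1)]
      list(widths = widths, introns = introns)
    }
    place_lnc <- function(placement, start, strand) {
      li <<- li + 1L
      e <- lnc_exons()
      add(sprintf("LNC_%04d", li), strand, start, e$widths, e$introns,
          "lncRNA", sample(c("known", "novel"), 1), placement)
    }
    for (k in seq_len(n_cis)) {
      host <- sample.int(max(n_m, 1L), 1)
      ## lncRNA on + strand just downstream of the host mRNA: the host
      ## falls in the lncRNA's 0-10 kb upstream window.
      start <- mrna_end[host] + sample(500:8000, 1)
      place_lnc("cis", start, "+")
    }
    for (k in seq_len(n_ov)) {
      host <- sample.int(max(n_m, 1L), 1)
      mode <- ov_modes[(k - 1L) %% 4L + 1L]
      host_strand <- tx[[host]]$strand
      strand <- if (grepl("same", mode)) host_strand
      else setdiff(c("+", "-"), host_strand)
      start <- if (grepl("contained", mode)) mrna_anchor[host] + 50L
      else mrna_anchor[host] - sample(200:600, 1)
      place_lnc(paste0("overlap_", mode), start, strand)
    }
    for (k in seq_len(n_iso)) {
      start <- (n_m + k - 1L) * slot + 55000L
      if (start + 5000 > config$genome_length)
        stop("genome too small to place isolated lncRNA loci", call. = FALSE)
      place_lnc("isolated", start, sample(c("+", "-"), 1))
    }
    transcripts <- if (length(tx)) do.call(rbind, tx) else
      data.frame(transcript_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 biotype = character(0), status = character(0),
                 placement = character(0), stringsAsFactors = FALSE)
    exons <- if (length(ex)) do.call(rbind, ex) else
      data.frame(transcript_id = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
    rownames(transcripts) <- rownames(exons) <- NULL
    list(transcripts = transcripts, exons = exons)
  })
}

#' Write an annotation as GFF3
#'
#' @param annotation From [generate_annotation()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  if (nrow(tx) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  tgr <- GenomicRanges::GRanges(tx$chrom,
                                IRanges::IRanges(tx$start, tx$end),
                                strand = tx$strand)
  S4Vectors::mcols(tgr) <- S4Vectors::DataFrame(
    source = "ceRNAnet", type = "transcript", ID = tx$transcript_id,
    biotype = tx$biotype, status = tx$status)
  m <- match(ex$transcript_id, tx$transcript_id)
  egr <- GenomicRanges::GRanges(tx$chrom[m],
                                IRanges::IRanges(ex$start, ex$end),
                                strand = tx$strand[m])
  S4Vectors::mcols(egr) <- S4Vectors::DataFrame(
    source = "ceRNAnet", type = "exon",
    Parent = ex$transcript_id)
  rtracklayer::export(c(tgr, egr), path, format = "gff3")
  ## drop run-dependent header lines so equal inputs give equal bytes
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}

#' Random transcript sequences matching spliced lengths
#'
#' @param annotation From [generate_annotation()].
#' @param config The matching [simulation_config()].
#' @return A [Biostrings::DNAStringSet] named by transcript id.
#' @export
generate_sequences <- function(annotation, config) {
  tx <- as_transcript_df(annotation)
  with_seed(config$seed + 107L, {
    seqs <- vapply(tx$spliced_length, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, tx$transcript_id))
  })
}

#' Write sequences as 60-column-wrapped FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Generate negative-binomial counts with planted differential expression
#'
#' Each transcript is planted as differentially expressed with probability
#' `de_fraction`; planted transcripts get a +/- `lfc_location` log2 shift
#' of the group-A mean (sign chosen uniformly; `up` means higher in A).
#' Counts are drawn NB(mean, size = 1/dispersion) after scaling by
#' per-sample log-normal library size factors.
#'
#' @param annotation From [generate_annotation()].
#' @param config A [simulation_config()].
#' @return List with `expr` (an expression matrix: `counts`, `lengths`,
#'   `groups`) and `truth` (`transcript_id, biotype, de, direction,
#'   base_mean`).
#' @export
generate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_per_group < 2L)
    stop("need >= 2 samples per group: the DE test is undefined below that",
         call. = FALSE)
  tx <- as_transcript_df(annotation)
  if (nrow(tx) == 0L) stop("empty annotation", call. = FALSE)
  with_seed(config$seed + 211L, {
    n <- nrow(tx); ns <- config$n_samples_per_group
    samples <- c(paste0("A", seq_len(ns)), paste0("C", seq_len(ns)))
    groups <- rep(c("A", "C"), each = ns)
    base <- 2^stats::runif(n, 6, 10)
    de <- stats::runif(n) < config$de_fraction
    ## Planted directions are balanced (half up, half down, matched base
    ## means): FPKM is a relative measure, so unbalanced planted read mass
    ## would shift the apparent fold change of every unperturbed
    ## transcript (library-composition bias).
    direction <- rep("ns", n)
    de_idx <- sample(which(de))
    n_up <- floor(length(de_idx) / 2)
    direction[de_idx[seq_len(n_up)]] <- "up"
    direction[de_idx[setdiff(seq_along(de_idx), seq_len(n_up))]] <- "down"
    fold <- 2^config$lfc_location
    mu_a <- base * ifelse(direction == "up", fold, 1)
    mu_c <- base * ifelse(direction == "down", fold, 1)
    mu <- cbind(matrix(mu_a, n, ns), matrix(mu_c, n, ns))
    sf <- exp(stats::rnorm(2 * ns, 0, config$sf_sigma))
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(stats::rnbinom(n * 2 * ns, mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     n, 2 * ns, dimnames = list(tx$transcript_id, samples))
    truth <- data.frame(transcript_id = tx$transcript_id,
                        biotype = tx$biotype, de = de, direction = direction,
                        base_mean = base, stringsAsFactors = FALSE)
    list(expr = expr_matrix(counts, tx$spliced_length, groups),
         truth = truth)
  })
}

#' Generate classifier score evidence correlated with the true biotype
#'
#' Each of the four classifiers independently votes on the correct side of
#' its threshold with probability `1 - noise_rate`; scores are drawn
#' uniformly on the chosen side (only the side matters to the vote).
#'
#' @param annotation From [generate_annotation()].
#' @param config A [simulation_config()].
#' @param noise_rate Per-classifier wrong-side probability, in [0, 1).
#' @return Score data frame for [vote_biotype()].
#' @export
generate_coding_scores <- function(annotation, config, noise_rate = 0) {
  if (noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must lie in [0, 1)", call. = FALSE)
  tx <- as_transcript_df(annotation)
  with_seed(config$seed + 307L, {
    n <- nrow(tx)
    coding <- tx$biotype == "mRNA"
    side <- function() xor(coding, stats::runif(n) < noise_rate)
    draw <- function(on, lo_c, hi_c, lo_n, hi_n)
      ifelse(on, stats::runif(n, lo_c, hi_c), stats::runif(n, lo_n, hi_n))
    data.frame(
      transcript_id = tx$transcript_id,
      cnci = draw(side(), 0.1, 5, -5, -0.1),
      cpc = draw(side(), 0.1, 5, -5, -0.1),
      txcds = draw(side(), 501, 1500, 0, 499),
      pfam_hit = side(),
      stringsAsFactors = FALSE)
  })
}

#' Generate a miRNA layer with planted ceRNA triads
#'
#' Plants `n_planted_triads` triads on distinct differentially expressed
#' lncRNA/mRNA pairs sharing a direction: the miRNA profile is built
#' anti-correlated (target magnitude `triad_r`) with the standardized mean
#' of the two partner log2 profiles, which also gives it the opposite DE
#' direction. Decoy triads violating exactly one rule (a same-direction
#' miRNA, or an uncorrelated miRNA) are added to the maps with truth
#' labels so rule-forced exclusion is testable.
#'
#' @param annotation From [generate_annotation()].
#' @param counts From [generate_counts()] on the same annotation.
#' @param config A [simulation_config()].
#' @return List: `mir_counts` (matrix, miRNAs x samples), `mir_lengths`,
#'   `mir_mrna_map`, `mir_lnc_map`, `planted` (triad truth table) and
#'   `decoys` (with a `violation` column).
#' @export
generate_mirna_layer <- function(annotation, counts, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- counts$truth
  expr <- counts$expr
  with_seed(config$seed + 401L, {
    ns2 <- ncol(expr$counts)
    de_l <- truth$transcript_id[truth$de & truth$biotype == "lncRNA"]
    de_m <- truth$transcript_id[truth$de & truth$biotype == "mRNA"]
    k <- config$n_planted_triads
    ## anti-correlate against log2 FPKM so per-sample library-size factors
    ## (shared by all transcripts) do not leak into the miRNA profiles
    lodd <- log2(compute_fpkm(expr) + 1)
    pick_pairs <- function(k) {
      ## distinct lncRNA and mRNA per triad, directions matched
      dirs <- stats::setNames(truth$direction, truth$transcript_id)
      pairs <- list()
      used_l <- used_m <- character(0)
      for (d in c("up", "down")) {
        ls <- setdiff(de_l[dirs[de_l] == d], used_l)
        ms <- setdiff(de_m[dirs[de_m] == d], used_m)
        n_d <- min(length(ls), length(ms))
        if (n_d == 0) next
        take <- seq_len(n_d)
        pairs[[d]] <- data.frame(lncrna_id = ls[take], mrna_id = ms[take],
                                 direction = d, stringsAsFactors = FALSE)
        used_l <- c(used_l, ls[take]); used_m <- c(used_m, ms[take])
      }
      got <- do.call(rbind, pairs)
      if (is.null(got) || nrow(got) < k)
        stop("insufficient DE lncRNA/mRNA pairs to plant ", k, " triads",
             call. = FALSE)
      got[sample.int(nrow(got), k), , drop = FALSE]
    }
    planted <- if (k > 0) pick_pairs(k) else
      data.frame(lncrna_id = character(0), mrna_id = character(0),
                 direction = character(0), mirna_id = character(0),
                 stringsAsFactors = FALSE)
    n_mir <- max(config$n_mirna, k)
    mir_ids <- sprintf("MIR_%03d", seq_len(n_mir))
    mir_log2 <- matrix(stats::runif(n_mir, 7, 10), n_mir, ns2)
    rownames(mir_log2) <- mir_ids
    anti_profile <- function(lnc, mrna) {
      z <- scale(c(lodd[lnc, ]))[, 1] / 2 + scale(c(lodd[mrna, ]))[, 1] / 2
      w <- scale(z)[, 1]
      ## noise orthogonalized against the signal in-sample, so the planted
      ## anti-correlation magnitude is hit exactly, not just in expectation
      eps <- stats::rnorm(ns2)
      eps <- eps - w * sum(eps * w) / sum(w * w)
      eps <- scale(eps)[, 1]
      -(config$triad_r * w + sqrt(1 - config$triad_r^2) * eps)
    }
    if (k > 0) {
      planted$mirna_id <- mir_ids[seq_len(k)]
      for (i in seq_len(k))
        mir_log2[i, ] <- mir_log2[i, 1] +
          2 * anti_profile(planted$lncrna_id[i], planted$mrna_id[i])
    }
    ## decoys: one same-direction miRNA, one uncorrelated miRNA
    decoys <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                         mrna_id = character(0), violation = character(0),
                         stringsAsFactors = FALSE)
    free <- setdiff(seq_len(n_mir), seq_len(k))
    if (k > 0 && length(free) >= 2) {
      d1 <- free[1]; d2 <- free[2]
      ## same trend as the pair: correlated, not anti-correlated
      mir_log2[d1, ] <- mir_log2[d1, 1] -
        2 * anti_profile(planted$lncrna_id[1], planted$mrna_id[1])
      decoys <- rbind(decoys, data.frame(
        lncrna_id = planted$lncrna_id[1], mirna_id = mir_ids[d1],
        mrna_id = planted$mrna_id[1], violation = "same_direction",
        stringsAsFactors = FALSE))
      mir_log2[d2, ] <- mir_log2[d2, 1] + stats::rnorm(ns2, 0, 0.1)
      decoys <- rbind(decoys, data.frame(
        lncrna_id = planted$lncrna_id[1], mirna_id = mir_ids[d2],
        mrna_id = planted$mrna_id[1], violation = "uncorrelated",
        stringsAsFactors = FALSE))
    }
    mir_counts <- matrix(
      stats::rnbinom(length(mir_log2), mu = as.vector(2^mir_log2),
                     size = 1 / max(config$nb_dispersion, 1e-8)),
      n_mir, ns2, dimnames = list(mir_ids, colnames(expr$counts)))
    mir_mrna_map <- rbind(planted[, c("mirna_id", "mrna_id")],
                          decoys[, c("mirna_id", "mrna_id")])
    mir_lnc_map <- rbind(planted[, c("mirna_id", "lncrna_id")],
                         decoys[, c("mirna_id", "lncrna_id")])
    rownames(mir_mrna_map) <- rownames(mir_lnc_map) <- NULL
    opposite <- c(up = "down", down = "up")
    mir_truth <- data.frame(transcript_id = mir_ids,
                            direction = "ns", stringsAsFactors = FALSE)
    if (k > 0) {
      mir_truth$direction[seq_len(k)] <- opposite[planted$direction]
      if (nrow(decoys) > 0) {
        d1 <- match(decoys$mirna_id[decoys$violation == "same_direction"],
                    mir_ids)
        mir_truth$direction[d1] <- planted$direction[1]
      }
    }
    list(mir_counts = mir_counts,
         mir_truth = mir_truth,
         mir_lengths = rep(22, n_mir),
         mir_mrna_map = mir_mrna_map,
         mir_lnc_map = mir_lnc_map,
         planted = planted, decoys = decoys)
  })
}

#' Generate genus abundances with planted gene correlations
#'
#' Each planted (gene, genus) pair gets an abundance profile built as
#' `r * z_gene + sqrt(1 - r^2) * noise` on the log scale (so the
#' correlation with the gene profile has expected sign and magnitude `r`);
#' unplanted genera are independent log-normal noise.
#'
#' @param config A [simulation_config()].
#' @param gene_profiles Numeric matrix, genes x samples (e.g. log2 FPKM).
#' @param planted Optional data frame `gene_id, genus, r` (|r| <= 1); by
#'   default no pairs are planted.
#' @return List with `abundance` (genera x samples) and `planted`.
#' @export
generate_microbiota <- function(config, gene_profiles, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 503L, {
    ns2 <- ncol(gene_profiles)
    genera <- paste0("Genus_", seq_len(config$n_genera))
    log_ab <- matrix(stats::rnorm(config$n_genera * ns2, 4, 1),
                     config$n_genera, ns2,
                     dimnames = list(genera, colnames(gene_profiles)))
    abundance <- exp(log_ab)
    if (!is.null(planted) && nrow(planted) > 0) {
      if (!all(planted$genus %in% genera))
        stop("planted genus not in table", call. = FALSE)
      if (!all(planted$gene_id %in% rownames(gene_profiles)))
        stop("planted gene not in gene_profiles", call. = FALSE)
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene_id[i]; b <- planted$genus[i]; r <- planted$r[i]
        z <- scale(as.numeric(gene_profiles[g, ]))[, 1]
        eps <- stats::rnorm(ns2)
        ## orthogonalize the noise so the sample correlation equals r
        eps <- eps - z * sum(eps * z) / sum(z * z)
        eps <- scale(eps)[, 1]
        abundance[b, ] <- 50 + 10 * (r * z + sqrt(1 - r^2) * eps)
      }
    }
    list(abundance = abundance,
         planted = planted %||% data.frame(gene_id = character(0),
                                           genus = character(0),
                                           r = numeric(0)))
  })
}

#' Write a matrix as a TSV with a `transcript_id` id column
#'
#' @param m Matrix with rownames.
#' @param path Output file.
#' @param id_name Name of the id column (default `"transcript_id"`).
#' @export
write_tsv_matrix <- function(m, path, id_name = "transcript_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
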