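## Characterization of Toll/Imd pathway proteins: ORF translation,
## molecular weight, isoelectric point, and domain-architecture
## validation / Toll subfamily assignment.

#' Translate a complete ORF to its protein sequence
#'
#' Validates that the cDNA is a complete ORF (length divisible by 3,
#' starts with ATG, ends with a stop codon, no internal stops) and
#' translates it with the standard genetic code. A complete ORF of
#' `L` bp encodes `L/3 - 1` amino acids (the stop is not translated).
#'
#' @param cdna Character scalar, DNA alphabet (U accepted as T).
#' @return Character scalar: the protein sequence (no stop symbol).
#' @export
translate_orf <- function(cdna) {
  s <- toupper(chartr("u", "t", as.character(cdna)))
  if (nchar(s) %% 3 != 0)
    stop("ORF length ", nchar(s), " is not divisible by 3", call. = FALSE)
  if (nchar(s) < 6) stop("ORF must hold at least a start and a stop codon",
                         call. = FALSE)
  if (substr(s, 1, 3) != "ATG")
    stop("ORF does not start with ATG (position 1)", call. = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  n <- nchar(aa)
  if (substr(aa, n, n) != "*")
    stop("ORF does not end in a stop codon (position ", nchar(s) - 2, ")",
         call. = FALSE)
  body <- substr(aa, 1, n - 1)
  internal <- regexpr("*", body, fixed = TRUE)
  if (internal > 0)
    stop("internal stop codon at codon ", internal, call. = FALSE)
  body
}

#' Amino-acid length implied by a complete ORF length
#'
#' @param orf_bp ORF length(s) in bp, including the stop codon.
#' @return `orf_bp / 3 - 1`.
#' @export
aa_length_from_orf <- function(orf_bp) {
  if (any(orf_bp %% 3 != 0)) stop("ORF length not divisible by 3",
                                  call. = FALSE)
  orf_bp / 3 - 1
}

#' Protein molecular weight in kDa
#'
#' Sum of average residue masses plus one water, using the constants in
#' `AA_RESIDUE_MASS` / `WATER_MASS`.
#'
#' @param protein Character scalar over the 20 standard amino acids.
#' @return Molecular weight in kDa (unrounded; round to 2 decimals for
#'   reporting).
#' @export
molecular_weight <- function(protein) {
  aa <- strsplit(toupper(as.character(protein)), "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty protein", call. = FALSE)
  mass <- AA_RESIDUE_MASS[aa]
  if (anyNA(mass))
    stop("unknown residue: ", paste(unique(aa[is.na(mass)]), collapse = ","),
         call. = FALSE)
  (sum(mass) + WATER_MASS) / 1000
}

## Net charge of a protein at a given pH under the Henderson-Hasselbalch
## model; monotone decreasing in pH.
protein_net_charge <- function(protein, ph) {
  aa <- strsplit(toupper(as.character(protein)), "", fixed = TRUE)[[1]]
  counts <- table(factor(aa, levels = names(AA_RESIDUE_MASS)))
  pos <- c(nterm = 1, counts[c("K", "R", "H")])
  pos_pka <- PKA[c("nterm", "K", "R", "H")]
  neg <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
  neg_pka <- PKA[c("cterm", "D", "E", "C", "Y")]
  vapply(ph, function(p) {
    sum(pos / (1 + 10^(p - pos_pka))) - sum(neg / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the protein is
#' zero, found by bisection on [0, 14] to a tolerance of 0.01 pH units.
#' The pKa set lives in `PKA`.
#'
#' @param protein Character scalar over the 20 standard amino acids.
#' @param tol Bisection tolerance in pH units (default 0.01).
#' @return The pI.
#' @export
isoelectric_point <- function(protein, tol = 0.01) {
  if (nchar(protein) == 0L) stop("empty protein", call. = FALSE)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Validate a Toll receptor domain architecture and assign a subfamily
#'
#' A valid Toll architecture has at least one leucine-rich repeat (LRR),
#' exactly one transmembrane (TM) span, exactly one Toll/IL-1 receptor
#' (TIR) domain, and the TIR strictly after the TM (extracellular LRRs,
#' intracellular TIR). Overlapping TM/TIR spans are an error.
#'
#' The subfamily rule is a documented heuristic (the field's P/sP/sPP
#' nomenclature is descriptive, not operational): a valid receptor with at
#' least `lrr_min_p` LRRs and at least `len_min_p` residues is `P`; with
#' that many LRRs but a shorter chain it is `sPP` (same arrangement,
#' shorter); with fewer LRRs it is `sP`; invalid architectures are
#' `unclassified`.
#'
#' @param lrr Matrix/data frame of LRR spans (`start`, `end`, aa) or a
#'   2-column matrix; one row per repeat.
#' @param tm,tir Spans (vectors `c(start, end)` or 1-row data frames); a
#'   multi-row input means multiple spans and invalidates the
#'   architecture.
#' @param aa_length Protein length in residues.
#' @param signal Optional signal-peptide span (unused by validity).
#' @param lrr_min_p,len_min_p Subfamily thresholds (defaults 15 repeats,
#'   1100 aa).
#' @return List with `valid` (logical), `subfamily` in
#'   `c("P", "sP", "sPP", "unclassified")`, and `reason` when invalid.
#' @export
validate_toll <- function(lrr, tm, tir, aa_length, signal = NULL,
                          lrr_min_p = 15L, len_min_p = 1100L) {
  spans <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), ncol = 2))
    if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
    if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
    x
  }
  lrr <- spans(lrr); tm <- spans(tm); tir <- spans(tir)
  fail <- function(reason) list(valid = FALSE, subfamily = "unclassified",
                                reason = reason)
  if (nrow(tm) == 1L && nrow(tir) == 1L &&
      tm[1, 1] <= tir[1, 2] && tir[1, 1] <= tm[1, 2])
    stop("TM and TIR spans overlap", call. = FALSE)
  if (nrow(lrr) < 1L) return(fail("no LRR motif"))
  if (nrow(tm) != 1L) return(fail("need exactly one transmembrane span"))
  if (nrow(tir) != 1L) return(fail("need exactly one TIR domain"))
  if (tir[1, 1] <= tm[1, 2]) return(fail("TIR must follow the TM span"))
  all_spans <- rbind(lrr, tm, tir, spans(signal))
  if (any(all_spans < 1) || any(all_spans > aa_length))
    return(fail("domain span outside [1, protein length]"))
  subfamily <- if (nrow(lrr) >= lrr_min_p) {
    if (aa_length >= len_min_p) "P" else "sPP"
  } else "sP"
  list(valid = TRUE, subfamily = subfamily, reason = NA_character_)
}

#' Check printed (ORF bp, aa) pairs against the complete-ORF rule
#'
#' @param table Data frame with columns `orf_bp` and `aa_length`.
#' @return The table with `expected_aa = orf_bp/3 - 1` and logical
#'   `consistent` columns appended.
#' @export
orf_aa_consistency <- function(table) {
  table$expected_aa <- aa_length_from_orf(table$orf_bp)
  table$consistent <- table$expected_aa == table$aa_length
  table
}

#' Published Toll/Imd pathway gene characterization table
#'
#' The printed cDNA/protein characterization of the 25 Toll/Imd signaling
#' pathway genes of the leaf beetle *Altica viridicyanea* (GenBank
#' OQ819300-OQ819306 and OQ834300-OQ834318): ORF length, amino-acid
#' length, molecular weight, theoretical pI, and domain spans. Shipped as
#' plain TSV in `extdata`. Note: the Imd row as published (ORF 621 bp,
#' 207 aa) is internally inconsistent with the complete-ORF rule
#' `aa = orf/3 - 1`; [orf_aa_consistency()] flags it.
#'
#' @return Data frame, one row per gene.
#' @export
toll_imd_gene_table <- function() {
  path <- system.file("extdata", "aviridicyanea_toll_imd_genes.tsv",
                      package = "ceRNAnet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Characterize proteins from complete ORF sequences
#'
#' Runs translate -> molecular weight -> pI for each sequence.
#'
#' @param orfs Named character vector of complete ORF cDNA sequences.
#' @return Data frame `gene, orf_bp, aa_length, mw_kda (2 dp), pi (2 dp)`.
#' @export
characterize_proteins <- function(orfs) {
  rows <- lapply(names(orfs), function(nm) {
    prot <- translate_orf(orfs[[nm]])
    data.frame(gene = nm, orf_bp = nchar(orfs[[nm]]),
               aa_length = nchar(prot),
               mw_kda = round(molecular_weight(prot), 2),
               pi = round(isoelectric_point(prot), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
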