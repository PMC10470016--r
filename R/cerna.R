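## ceRNA (lncRNA-miRNA-mRNA) triad assembly under the sponge rules:
## lncRNA and mRNA share a differential-expression direction, the miRNA
## moves the opposite way, and both miRNA-facing expression correlations
## are strong (anti-correlated under the sponge model) and significant.

#' Pearson correlation with a t-approximation p-value
#'
#' `r` is the Pearson coefficient of the two profiles and the two-sided
#' p-value uses `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. For |r| = 1 the p-value is 0.
#'
#' @param x,y Numeric profiles of equal length, n >= 3.
#' @return List with `r` and `p`.
#' @export
correlation_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must match", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

#' Assemble ceRNA triads
#'
#' Emits every (lncRNA, miRNA, mRNA) triple such that: the miRNA targets
#' both the mRNA (via `mir_mrna_map`) and the lncRNA (via `mir_lnc_map`);
#' the lncRNA and mRNA have the same differential-expression direction
#' (`up` or `down`) and the miRNA the opposite one; and both miRNA-facing
#' expression correlations satisfy the correlation rule with p < `p_max`.
#' Under the sponge model (default) the rule is r <= -`r_min` for both
#' miRNA-lncRNA and miRNA-mRNA pairs; with `unsigned = TRUE` it is
#' |r| >= `r_min`.
#'
#' @param de_lnc,de_mirna,de_mrna Data frames with `transcript_id` and
#'   `direction` (from [differential_expression()]); only `up`/`down` rows
#'   participate.
#' @param expr Named list of expression matrices (features x samples) or a
#'   single matrix covering all ids; profiles are looked up by id.
#' @param mir_mrna_map Data frame `mirna_id, mrna_id`.
#' @param mir_lnc_map Data frame `mirna_id, lncrna_id`.
#' @param r_min Correlation magnitude threshold (default 0.6, inclusive).
#' @param p_max Correlation p-value threshold (default 0.05, strict).
#' @param unsigned Use |r| >= r_min instead of r <= -r_min.
#' @return Data frame, one row per triad, with the pair correlations,
#'   p-values and the three directions.
#' @export
build_triads <- function(de_lnc, de_mirna, de_mrna, expr, mir_mrna_map,
                         mir_lnc_map, r_min = 0.6, p_max = 0.05,
                         unsigned = FALSE) {
  dirs <- function(de) {
    d <- de$direction[de$direction %in% c("up", "down")]
    stats::setNames(d, de$transcript_id[de$direction %in% c("up", "down")])
  }
  dl <- dirs(de_lnc); dmi <- dirs(de_mirna); dm <- dirs(de_mrna)
  profile <- make_profile_lookup(expr)
  out <- list()
  for (k in seq_len(nrow(mir_mrna_map))) {
    mir <- mir_mrna_map$mirna_id[k]; mrna <- mir_mrna_map$mrna_id[k]
    if (is.na(dmi[mir]) || is.na(dm[mrna])) next
    if (dmi[mir] == dm[mrna]) next
    lncs <- mir_lnc_map$lncrna_id[mir_lnc_map$mirna_id == mir]
    for (lnc in lncs) {
      if (is.na(dl[lnc])) next
      if (dl[lnc] != dm[mrna]) next
      pm <- profile(mir); pl <- profile(lnc); pg <- profile(mrna)
      if (is.null(pm) || is.null(pl) || is.null(pg)) {
        warning("expression profile missing for a mapped id; triad skipped",
                call. = FALSE)
        next
      }
      c1 <- correlation_with_p(pl, pm)  # lncRNA - miRNA
      c2 <- correlation_with_p(pm, pg)  # miRNA - mRNA
      if (anyNA(c(c1$r, c2$r))) next
      pass_r <- if (unsigned) abs(c1$r) >= r_min && abs(c2$r) >= r_min
      else c1$r <= -r_min && c2$r <= -r_min
      if (!pass_r || c1$p >= p_max || c2$p >= p_max) next
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = lnc, mirna_id = mir, mrna_id = mrna,
        r_lnc_mir = c1$r, p_lnc_mir = c1$p,
        r_mir_mrna = c2$r, p_mir_mrna = c2$p,
        dir_lnc = unname(dl[lnc]), dir_mir = unname(dmi[mir]),
        dir_mrna = unname(dm[mrna]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), r_lnc_mir = numeric(0),
                      p_lnc_mir = numeric(0), r_mir_mrna = numeric(0),
                      p_mir_mrna = numeric(0), dir_lnc = character(0),
                      dir_mir = character(0), dir_mrna = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("lncrna_id", "mirna_id", "mrna_id")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

make_profile_lookup <- function(expr) {
  mats <- if (is.list(expr) && !is.data.frame(expr)) expr else list(expr)
  mats <- lapply(mats, as.matrix)
  function(id) {
    for (m in mats) if (id %in% rownames(m)) return(as.numeric(m[id, ]))
    NULL
  }
}

#' Distinct-entity counts of a ceRNA network
#'
#' @param triads Triad table from [build_triads()].
#' @return List: `mir_mrna_pairs`, `lnc_mir_pairs`, `lncrnas`, `mirnas`,
#'   `mrnas` (all distinct counts).
#' @export
network_summary <- function(triads) {
  list(
    mir_mrna_pairs = nrow(unique(triads[, c("mirna_id", "mrna_id")])),
    lnc_mir_pairs = nrow(unique(triads[, c("lncrna_id", "mirna_id")])),
    lncrnas = length(unique(triads$lncrna_id)),
    mirnas = length(unique(triads$mirna_id)),
    mrnas = length(unique(triads$mrna_id))
  )
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes an edge table (`source, target, interaction`), a node attribute
#' table (`id, type, direction`) and optionally a SIF file, all loadable
#' through Cytoscape's table import.
#'
#' @param triads Triad table from [build_triads()].
#' @param path Output prefix; writes `<path>_edges.tsv`,
#'   `<path>_nodes.tsv` and optionally `<path>.sif`.
#' @param sif Also write the SIF variant (default TRUE).
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(triads, path, sif = TRUE) {
  edges <- unique(rbind(
    data.frame(source = triads$lncrna_id, target = triads$mirna_id,
               interaction = "lncRNA-miRNA", stringsAsFactors = FALSE),
    data.frame(source = triads$mirna_id, target = triads$mrna_id,
               interaction = "miRNA-mRNA", stringsAsFactors = FALSE)))
  nodes <- unique(rbind(
    data.frame(id = triads$lncrna_id, type = "lncRNA",
               direction = triads$dir_lnc, stringsAsFactors = FALSE),
    data.frame(id = triads$mirna_id, type = "miRNA",
               direction = triads$dir_mir, stringsAsFactors = FALSE),
    data.frame(id = triads$mrna_id, type = "mRNA",
               direction = triads$dir_mrna, stringsAsFactors = FALSE)))
  files <- c(edges = paste0(path, "_edges.tsv"),
             nodes = paste0(path, "_nodes.tsv"))
  utils::write.table(edges, files["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, files["nodes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sif) {
    files <- c(files, sif = paste0(path, ".sif"))
    writeLines(paste(edges$source, edges$interaction, edges$target,
                     sep = "\t"), files["sif"])
  }
  invisible(files)
}
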