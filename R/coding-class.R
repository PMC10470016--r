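## Consensus coding-potential classification.
##
## Four independent lines of evidence are reduced to votes:
##   CNCI score  > 0    -> coding
##   CPC score   > 0    -> coding
##   txCdsPredict > 500 -> coding
##   Pfam domain hit    -> coding
## A transcript is called mRNA when at least 3 of the 4 votes are coding,
## lncRNA when at least 3 are noncoding, and ambiguous on a 2-2 split.
## Scores exactly at a threshold count as noncoding votes (the coding call
## requires a strict ">").

#' Filter transcripts to lncRNA/mRNA candidates
#'
#' Retains transcripts with at least `min_exons` exons and spliced length
#' strictly greater than `min_length` bp, the standard candidate filter
#' applied before coding-potential classification. Spliced length is the sum
#' of exon widths.
#'
#' @param transcripts A transcript annotation as returned by
#'   [generate_annotation()]: a list with data frames `transcripts` and
#'   `exons`, or just the `transcripts` data frame if it carries a
#'   `spliced_length` and `n_exons` column.
#' @param min_exons Minimum exon count (default 2).
#' @param min_length Spliced length must exceed this many bp (default 200;
#'   the comparison is strict, a 200-bp transcript is removed).
#' @return The `transcripts` data frame restricted to candidates, original
#'   order preserved.
#' @export
filter_candidates <- function(transcripts, min_exons = 2L, min_length = 200L) {
  tx <- as_transcript_df(transcripts)
  if (any(tx$spliced_length < 0))
    stop("negative spliced length: malformed exon intervals", call. = FALSE)
  keep <- tx$n_exons >= min_exons & tx$spliced_length > min_length
  tx[keep, , drop = FALSE]
}

as_transcript_df <- function(transcripts) {
  if (is.list(transcripts) && !is.data.frame(transcripts) &&
      all(c("transcripts", "exons") %in% names(transcripts))) {
    tx <- transcripts$transcripts
    ex <- transcripts$exons
    if (any(ex$end < ex$start))
      stop("negative-length exon interval", call. = FALSE)
    w <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
    n <- tapply(ex$transcript_id, ex$transcript_id, length)
    tx$spliced_length <- as.integer(w[tx$transcript_id])
    tx$n_exons <- as.integer(n[tx$transcript_id])
    tx$spliced_length[is.na(tx$spliced_length)] <- 0L
    tx$n_exons[is.na(tx$n_exons)] <- 0L
    return(tx)
  }
  if (!all(c("spliced_length", "n_exons") %in% names(transcripts)))
    stop("transcripts must carry spliced_length and n_exons (or supply exons)",
         call. = FALSE)
  transcripts
}

#' Consensus biotype vote for a table of classifier scores
#'
#' @param scores Data frame with columns `transcript_id`, `cnci`, `cpc`,
#'   `txcds` (numeric scores) and `pfam_hit` (logical or 0/1).
#' @return Data frame with `transcript_id`, `votes_coding`,
#'   `votes_noncoding` and `label` in `c("mRNA", "lncRNA", "ambiguous")`.
#' @details Votes: `cnci > 0`, `cpc > 0`, `txcds > 500`, `pfam_hit`. At
#'   least 3 coding votes gives mRNA, at least 3 noncoding gives lncRNA,
#'   a 2-2 split is ambiguous. Missing scores are an error, never imputed.
#' @export
vote_biotype <- function(scores) {
  need <- c("transcript_id", "cnci", "cpc", "txcds", "pfam_hit")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sc <- scores[, c("cnci", "cpc", "txcds")]
  if (anyNA(sc) || anyNA(scores$pfam_hit) || !all(vapply(sc, is.numeric, TRUE)))
    stop("missing or non-numeric classifier score; no imputation is done",
         call. = FALSE)
  if (!all(is.finite(as.matrix(sc))))
    stop("non-finite classifier score", call. = FALSE)
  votes <- (scores$cnci > 0) + (scores$cpc > 0) + (scores$txcds > 500) +
    as.logical(scores$pfam_hit)
  label <- ifelse(votes >= 3L, "mRNA", ifelse(votes <= 1L, "lncRNA", "ambiguous"))
  data.frame(
    transcript_id = scores$transcript_id,
    votes_coding = as.integer(votes),
    votes_noncoding = 4L - as.integer(votes),
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Partition candidate transcripts into mRNA / lncRNA / ambiguous
#'
#' @param scores Classifier score table (see [vote_biotype()]).
#' @param candidates Candidate transcript ids (e.g. from
#'   [filter_candidates()]); a data frame with a `transcript_id` column is
#'   also accepted.
#' @return List with character vectors `mrna`, `lncrna`, `ambiguous`, the
#'   vote audit data frame `votes`, and `missing`: candidate ids without a
#'   score row (reported, never silently dropped).
#' @export
classify_transcripts <- function(scores, candidates) {
  ids <- if (is.data.frame(candidates)) candidates$transcript_id else candidates
  ids <- as.character(ids)
  votes <- vote_biotype(scores)
  votes <- votes[match(ids, votes$transcript_id), , drop = FALSE]
  missing <- ids[is.na(votes$votes_coding)]
  votes <- votes[!is.na(votes$votes_coding), , drop = FALSE]
  rownames(votes) <- NULL
  list(
    mrna = votes$transcript_id[votes$label == "mRNA"],
    lncrna = votes$transcript_id[votes$label == "lncRNA"],
    ambiguous = votes$transcript_id[votes$label == "ambiguous"],
    votes = votes,
    missing = missing
  )
}
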