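## Published summary tables for the A. viridicyanea gut study, shipped as
## plain TSV under extdata. These are the worked-example inputs for the
## summary arithmetic (pathway ratios, DE count closure, annotation
## coverage); the full sequencing data (SRA PRJNA946198) are not required.

read_extdata <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "ceRNAnet",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published immune-pathway DE summary for the beetle gut study
#'
#' Differentially expressed lncRNA (DEL) and mRNA (DEM) counts and ratios
#' for 13 immune-related KEGG pathways, as published. Ratios are per the
#' study-wide totals of 8,539 DELs and 13,263 DEMs.
#'
#' @return Data frame `pathway_id, pathway_name, del_count, del_ratio,
#'   dem_count, dem_ratio`.
#' @export
immune_pathway_table <- function() read_extdata("aviridicyanea_immune_pathways.tsv")

#' Published DE direction counts by class and novelty
#'
#' @return Data frame `class, status, up, down`.
#' @export
de_count_table <- function() read_extdata("aviridicyanea_de_counts.tsv")

#' Published transcript classification counts
#'
#' @return Data frame `class, status, count`.
#' @export
transcript_count_table <- function() read_extdata("aviridicyanea_transcript_counts.tsv")

#' Published annotation coverage counts
#'
#' Per-database annotated mRNA counts (universe: 26,361 assembled mRNAs)
#' with the published percentages for cross-checking.
#'
#' @return Data frame `database, count, percent_published`.
#' @export
annotation_count_table <- function() read_extdata("aviridicyanea_annotation_counts.tsv")
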