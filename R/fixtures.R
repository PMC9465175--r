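# Published-table fixtures for the Phasmatidae mitogenome the package's
# reports mirror. Shipped as plain TSV under extdata and parsed with the
# package's own readers, so they double as I/O round-trip material.

#' Published gene-arrangement table
#'
#' The 38-row arrangement table (37 genes plus the A+T-rich region) of a
#' 16,060 bp stick-insect mitogenome, with the printed Location, Size and
#' Intergenic Nucleotides columns retained verbatim. Note that several
#' printed sizes and IGN values disagree with the printed coordinates;
#' computed values are always available alongside via
#' [build_arrangement()].
#'
#' @return an [annotation_table()] with `ign` and `size_printed` filled.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_arrangement.tsv",
                      package = "mitoprofile", mustWork = TRUE)
  read_feature_table(path, genome_length = 16060L,
                     genome_id = "stick_insect_mitogenome",
                     dialect = "table2")
}

#' Published codon-usage counts
#'
#' The 64 printed codon counts of the mitogenome's 13 protein-coding
#' genes.
#'
#' @return named integer vector (RNA codon -> count).
#' @export
table4_fixture <- function() {
  d <- table4_df()
  stats::setNames(as.integer(d$count), d$codon)
}

table4_df <- function() {
  path <- system.file("extdata", "table4_codon_usage.tsv",
                      package = "mitoprofile", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published RSCU column
#'
#' The printed RSCU values accompanying [table4_fixture()], for
#' column-level comparison against [rscu()].
#'
#' @return named numeric vector (RNA codon -> printed RSCU).
#' @export
table4_printed_rscu <- function() {
  d <- table4_df()
  stats::setNames(as.numeric(d$rscu_printed), d$codon)
}

#' Published composition table
#'
#' Printed per-class base percentages and skews (Whole genome, PCG, rRNA,
#' tRNA, A+T region).
#'
#' @return data frame with columns `label`, `pct_a`, `pct_c`, `pct_g`,
#'   `pct_t`, `pct_at`, `at_skew`, `gc_skew`.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_composition.tsv",
                      package = "mitoprofile", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  num <- function(x) as.numeric(gsub("−", "-", x))
  data.frame(label = d$Feature,
             pct_a = num(d$`A%`), pct_c = num(d$`C%`), pct_g = num(d$`G%`),
             pct_t = num(d$`T%`), pct_at = num(d$`A+T%`),
             at_skew = num(d$`A+T skew`), gc_skew = num(d$`G+C skew`),
             stringsAsFactors = FALSE)
}

#' Control-region long-repeat segments
#'
#' The four >30 bp direct-repeat segments reported for the A+T-rich region
#' of the same mitogenome; the synthetic generator plants a subset of
#' these.
#'
#' @format character vector of length 4.
#' @export
CR_LONG_REPEATS <- c(
  "AAAAATTATATTTAATAAATTAATATTTATAAA",
  "ATAATATATAATTATTTAAAAAATAATATAAAATTA",
  "TAATTCAATAATAATAATTAATAAATTAATAAT",
  "AAAATTTTTAAAATAATTTTATTAAAATTATTCTT")
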