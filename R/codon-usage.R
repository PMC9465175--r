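# Codon extraction, counting, RSCU and codons-per-thousand under a
# configurable genetic-code family partition.
#
# RSCU(c) = count(c) * degeneracy(family) / sum of counts over the family:
# the observed count divided by the expected count under uniform synonymous
# use. Codons are keyed as RNA triplets (UUA not TTA); DNA input is
# transcribed transparently.

BASES_RNA <- c("U", "C", "A", "G")

all_codons <- function() {
  g <- expand.grid(b3 = BASES_RNA, b2 = BASES_RNA, b1 = BASES_RNA,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

standard_aa <- function() {
  # standard genetic code, RNA codons -> one-letter amino acid ("*" = stop)
  tab <- Biostrings::GENETIC_CODE
  stats::setNames(unname(tab), dna_to_rna(names(tab)))
}

#' Genetic-code family partition
#'
#' Partition of the 64 codons into synonymous families, used by [rscu()].
#' `"standard"` is the standard nuclear code (Leu/Ser/Arg six-fold, Ile
#' three-fold, stop family `{UAA, UAG, UGA}`). `"invertebrate_mito"` moves
#' `AUA` to Met, `UGA` to Trp and `AGA`/`AGG` to Ser (eight-fold), leaving a
#' two-codon stop family.
#'
#' @param code_name `"standard"` or `"invertebrate_mito"`.
#' @return object of class `GeneticCodePartition`: list with `code_name`,
#'   `family_of` (codon -> family id), `degeneracy` (family id -> size),
#'   `aa_of` (codon -> amino-acid label), `stop_family`, `start_codons`.
#' @export
genetic_code_partition <- function(code_name = c("standard",
                                                 "invertebrate_mito")) {
  code_name <- match.arg(code_name)
  aa <- standard_aa()
  if (code_name == "invertebrate_mito") {
    aa[c("AUA", "UGA", "AGA", "AGG")] <- c("M", "W", "S", "S")
  }
  fam <- aa  # family id = amino-acid letter ("*" for stops)
  deg <- table(fam)
  structure(list(
    code_name = code_name,
    family_of = fam,
    degeneracy = stats::setNames(as.integer(deg), names(deg)),
    aa_of = aa,
    stop_family = "*",
    start_codons = if (code_name == "standard") c("AUG")
                   else c("AUU", "AUC", "AUA", "AUG", "GUG", "UUG")),
    class = "GeneticCodePartition")
}

#' Split a CDS into codons
#'
#' Consecutive non-overlapping triplets from position 1 of the reading
#' strand. A trailing 1–2 nt remainder (an incomplete stop codon completed
#' by polyadenylation) is recorded, not counted; codons containing `N` are
#' excluded with a tally.
#'
#' @param cds nucleotide string (DNA or RNA), length >= 3.
#' @return list with `codons` (RNA triplets), `trailing` (remainder string,
#'   possibly empty) and `n_excluded` (N-containing codons dropped).
#' @export
extract_codons <- function(cds) {
  cds <- dna_to_rna(toupper(cds))
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon (", n, " nt)")
  k <- n %/% 3L
  starts <- seq(1L, by = 3L, length.out = k)
  codons <- substring(cds, starts, starts + 2L)
  trailing <- if (n %% 3L) substr(cds, 3L * k + 1L, n) else ""
  has_n <- grepl("N", codons, fixed = TRUE)
  list(codons = codons[!has_n], trailing = trailing,
       n_excluded = sum(has_n))
}

#' Count codons over a set of CDS
#'
#' @param cds_list character vector (or list) of CDS sequences in reading
#'   orientation.
#' @return object of class `CodonUsageTable`: list with `counts` (named
#'   integer over all 64 RNA codons), `total`, `n_excluded` and `trailing`
#'   (per-CDS remainders).
#' @export
count_codons <- function(cds_list) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  if (length(cds_list) == 0L) stop("no CDS supplied")
  parts <- lapply(cds_list, extract_codons)
  codons <- unlist(lapply(parts, `[[`, "codons"))
  counts <- stats::setNames(integer(64), all_codons())
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, total = sum(counts),
                 n_excluded = sum(vapply(parts, `[[`, integer(1), "n_excluded")),
                 trailing = vapply(parts, `[[`, character(1), "trailing")),
            class = "CodonUsageTable")
}

normalize_counts <- function(counts) {
  if (inherits(counts, "CodonUsageTable")) counts <- counts$counts
  names(counts) <- dna_to_rna(toupper(names(counts)))
  full <- stats::setNames(numeric(64), all_codons())
  full[names(counts)] <- counts
  full
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * degeneracy(f) / sum(counts over family f)`.
#' Families with zero total get `NA` for all their codons.
#'
#' @param counts named codon counts (RNA or DNA names; absent = 0) or a
#'   [count_codons()] table.
#' @param partition a [genetic_code_partition()].
#' @param rounded round to 2 decimals half-up (report edge)?
#' @return named numeric vector over all 64 codons.
#' @export
rscu <- function(counts, partition = genetic_code_partition("standard"),
                 rounded = FALSE) {
  cnt <- normalize_counts(counts)
  fam <- partition$family_of[names(cnt)]
  fam_tot <- tapply(cnt, fam, sum)
  deg <- partition$degeneracy[fam]
  out <- ifelse(fam_tot[fam] > 0, cnt * deg / fam_tot[fam], NA_real_)
  out <- stats::setNames(as.numeric(out), names(cnt))
  if (rounded) round_half_up(out, 2) else out
}

# named two-fold splits of the six/eight-fold families, as used in codon
# distribution plots: Leu2 = UUR, Leu1 = CUN, Ser2 = UCN, Ser1 = AGN,
# Arg1 = CGN, Arg2 = AGR
CODON_GROUPS <- list(
  Leu2 = c("UUA", "UUG"),
  Leu1 = c("CUU", "CUC", "CUA", "CUG"),
  Ser2 = c("UCU", "UCC", "UCA", "UCG"),
  Ser1 = c("AGU", "AGC"),
  Arg1 = c("CGU", "CGC", "CGA", "CGG"),
  Arg2 = c("AGA", "AGG"))

#' Codons per thousand codons (CDspT)
#'
#' `1000 * group count / total count`. Grouping is per codon, per
#' synonymous family of a partition, or per named group (the two-fold
#' leucine/serine/arginine splits `Leu1`, `Leu2`, `Ser1`, `Ser2`, `Arg1`,
#' `Arg2`).
#'
#' @param counts named codon counts or a [count_codons()] table.
#' @param grouping `"codon"`, `"family"` or `"named"`.
#' @param partition partition used when `grouping = "family"`.
#' @param rounded round to 1 decimal half-up (report edge)?
#' @return named numeric vector of per-thousand values.
#' @export
cdspt <- function(counts, grouping = c("codon", "family", "named"),
                  partition = genetic_code_partition("standard"),
                  rounded = FALSE) {
  grouping <- match.arg(grouping)
  cnt <- normalize_counts(counts)
  total <- sum(cnt)
  if (total == 0) stop("total codon count is zero")
  g <- switch(grouping,
    codon = cnt,
    family = tapply(cnt, partition$family_of[names(cnt)], sum),
    named = vapply(CODON_GROUPS, function(cs) sum(cnt[cs]), numeric(1)))
  out <- stats::setNames(1000 * as.numeric(g) / total, names(g))
  if (rounded) round_half_up(out, 1) else out
}

#' Classify start and stop codons of CDS
#'
#' The start codon is the first triplet (flagged `is_ATN` when it matches
#' `AUN`); the stop is the final complete `UAA`/`UAG`, or the partial
#' `T`/`TA` remainder left by an incomplete stop codon completed by
#' polyadenylation.
#'
#' @param cds_list named character vector of CDS sequences (including any
#'   trailing partial codon).
#' @param partition a [genetic_code_partition()] (reserved for
#'   code-dependent stop sets).
#' @return data frame with columns `gene`, `start_codon`, `is_ATN`,
#'   `stop_codon`, `complete` (DNA-letter codons).
#' @export
classify_terminals <- function(cds_list,
                               partition = genetic_code_partition("invertebrate_mito")) {
  cds_list <- unlist(cds_list)
  genes <- names(cds_list) %||% paste0("cds", seq_along(cds_list))
  rows <- lapply(seq_along(cds_list), function(i) {
    p <- extract_codons(cds_list[[i]])
    start <- rna_to_dna(p$codons[1])
    if (nzchar(p$trailing)) {
      stop_codon <- rna_to_dna(p$trailing)
      complete <- FALSE
    } else {
      last <- rna_to_dna(p$codons[length(p$codons)])
      stop_codon <- last
      complete <- last %in% c("TAA", "TAG")
    }
    data.frame(gene = genes[i], start_codon = start,
               is_ATN = grepl("^AT", start),
               stop_codon = stop_codon, complete = complete,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format codon usage report
#'
#' @param counts named codon counts or a [count_codons()] table.
#' @param partition a [genetic_code_partition()]; amino-acid labels follow
#'   the selected partition.
#' @return data frame `codon`, `aa`, `count`, `rscu` (2 dp), `cdspt`
#'   (1 dp).
#' @export
codon_usage_report <- function(counts,
                               partition = genetic_code_partition("standard")) {
  cnt <- normalize_counts(counts)
  data.frame(codon = names(cnt),
             aa = unname(partition$aa_of[names(cnt)]),
             count = as.integer(cnt),
             rscu = unname(rscu(cnt, partition, rounded = TRUE)),
             cdspt = unname(cdspt(cnt, "codon", rounded = TRUE)),
             stringsAsFactors = FALSE)
}
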