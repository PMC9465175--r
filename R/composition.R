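# Base composition, A+T content and strand-skew statistics.
#
# Skews are the classical strand-asymmetry measures
#   AT skew = (A - T) / (A + T),   GC skew = (G - C) / (G + C),
# computed identically from counts or from percentages (the denominator
# cancels). N never counts toward the A/C/G/T denominator, so composition
# stays well-defined on draft sequences.

base_counts <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"), T = sum(b == "T"))
}

#' Base composition of a sequence
#'
#' Percentages of A/C/G/T over the non-N positions, plus A+T content.
#' Values are unrounded; reports round at the edge (2 decimals).
#'
#' @param seq nucleotide string.
#' @return named numeric vector `pct_a`, `pct_c`, `pct_g`, `pct_t`,
#'   `pct_at`.
#' @export
base_composition <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  n <- base_counts(seq)
  tot <- sum(n)
  if (tot == 0L) stop("sequence contains no A/C/G/T (all N?)")
  p <- 100 * n / tot
  c(pct_a = unname(p["A"]), pct_c = unname(p["C"]),
    pct_g = unname(p["G"]), pct_t = unname(p["T"]),
    pct_at = unname(p["A"] + p["T"]))
}

#' AT skew
#'
#' `(a - t) / (a + t)`; inputs may be counts or percentages.
#'
#' @param a,t counts or percentages of A and T.
#' @return dimensionless skew in `[-1, 1]`, or `NA` when `a + t == 0`.
#' @export
at_skew <- function(a, t) {
  if (a + t == 0) return(NA_real_)
  (a - t) / (a + t)
}

#' GC skew
#'
#' `(g - c) / (g + c)` under the default `g_minus_c` orientation. The
#' `c_minus_g` orientation, `(c - g) / (c + g)`, is the convention some
#' published composition tables use for their "G+C skew" column and is the
#' preset for reproducing such tables.
#'
#' @param g,c counts or percentages of G and C.
#' @param orientation `"g_minus_c"` (default) or `"c_minus_g"`.
#' @return dimensionless skew in `[-1, 1]`, or `NA` when `g + c == 0`.
#' @export
gc_skew <- function(g, c, orientation = c("g_minus_c", "c_minus_g")) {
  orientation <- match.arg(orientation)
  if (g + c == 0) return(NA_real_)
  s <- (g - c) / (g + c)
  if (orientation == "c_minus_g") -s else s
}

#' Composition report over a genome and its feature classes
#'
#' One row for the whole genome (plus strand) and one per requested gene
#' class, each class computed over the concatenation of strand-oriented
#' (reading-strand) feature sequences — skew is strand-dependent, so class
#' rows use the strand the genes are read from.
#'
#' @param genome a [genome_record()].
#' @param table an [annotation_table()].
#' @param class_spec named character vector mapping report labels to gene
#'   classes; default mirrors a published composition table.
#' @param gc_orientation passed to [gc_skew()].
#' @param rounded round percentages to 2 and skews to 3 decimals (half-up)?
#' @return data frame with columns `label`, `pct_a`, `pct_c`, `pct_g`,
#'   `pct_t`, `pct_at`, `at_skew`, `gc_skew`.
#' @export
composition_report <- function(genome, table,
                               class_spec = c("PCG" = "PCG", "rRNA" = "rRNA",
                                              "tRNA" = "tRNA",
                                              "A+T region" = "control_region"),
                               gc_orientation = "g_minus_c",
                               rounded = TRUE) {
  seq_of_class <- function(cls) {
    fs <- Filter(function(f) f$gene_class == cls, table$features)
    if (length(fs) == 0L) return(NULL)
    paste(vapply(fs, function(f) extract_feature_sequence(genome, f),
                 character(1)), collapse = "")
  }
  labels <- c("Whole genome", names(class_spec))
  seqs <- c(list(genome$seq),
            lapply(unname(class_spec), seq_of_class))
  keep <- !vapply(seqs, is.null, logical(1))
  if (!all(keep))
    warning("empty class, row(s) dropped: ",
            paste(labels[!keep], collapse = ", "))
  labels <- labels[keep]; seqs <- seqs[keep]
  rows <- lapply(seqs, function(s) {
    n <- base_counts(s)
    p <- base_composition(s)
    c(p, at_skew = at_skew(n["A"], n["T"]),
      gc_skew = gc_skew(n["G"], n["C"], gc_orientation))
  })
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("pct_a", "pct_c", "pct_g", "pct_t", "pct_at",
                "at_skew", "gc_skew")
  if (rounded) {
    d[1:5] <- lapply(d[1:5], round_half_up, digits = 2)
    d[6:7] <- lapply(d[6:7], round_half_up, digits = 3)
  }
  cbind(data.frame(label = labels, stringsAsFactors = FALSE), d)
}

#' Write a composition report as TSV
#'
#' Header mirrors the published table: Feature, A%, C%, G%, T%, A+T%,
#' A+T skew, G+C skew.
#'
#' @param report output of [composition_report()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_composition_report <- function(report, path) {
  out <- report
  names(out) <- c("Feature", "A%", "C%", "G%", "T%", "A+T%",
                  "A+T skew", "G+C skew")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
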