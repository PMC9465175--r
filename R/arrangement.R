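# Gene-arrangement accounting: feature sizes, intergenic nucleotides,
# per-class totals and a canonical gene-order signature.

#' Feature length on a circular genome
#'
#' Non-wrapped features have length `end - start + 1`; a feature wrapping
#' the origin (`start > end`) has length
#' `(genome_length - start + 1) + end`.
#'
#' @param f a [feature_annotation()] (or list with `start`/`end`).
#' @param genome_length genome length in bp (required for wrapped features).
#' @return length in bp.
#' @export
feature_length <- function(f, genome_length = NULL) {
  if (f$start <= f$end) return(f$end - f$start + 1L)
  if (is.null(genome_length))
    stop("genome_length required for a feature wrapping the origin")
  (as.integer(genome_length) - f$start + 1L) + f$end
}

#' Signed intergenic gap between consecutive features
#'
#' Defined strictly as `next.start - prev.end - 1` on the circle: 0 means
#' abutting, a negative value is the negated overlap length.
#'
#' @param prev,nxt consecutive features in circular order.
#' @param genome_length genome length in bp.
#' @param wrap does the adjacency cross the origin (last feature back to the
#'   first)?
#' @return signed gap in bp.
#' @export
intergenic_gap <- function(prev, nxt, genome_length, wrap = FALSE) {
  if (identical(prev, nxt)) stop("intergenic_gap of a feature with itself")
  prev_end <- prev$end
  nxt_start <- nxt$start
  if (wrap && !feature_wraps(prev)) {
    # adjacency crosses the origin: measure past position genome_length
    (as.integer(genome_length) - prev_end) + nxt_start - 1L
  } else {
    nxt_start - prev_end - 1L
  }
}

#' Tabulate a circular gene arrangement
#'
#' One row per feature in circular order with its computed size and the
#' signed gap to the next feature (the last row wraps to the first). When
#' the table carries printed size/IGN columns they are reported alongside.
#'
#' @param table an [annotation_table()].
#' @return data frame with columns `name`, `gene_class`, `strand`, `start`,
#'   `end`, `size`, `ign_next`, plus `size_printed`/`ign_printed` when
#'   available, and a `degenerate` attribute for a single-feature circle.
#' @export
build_arrangement <- function(table) {
  feats <- table$features
  n <- length(feats)
  L <- table$genome_length
  size <- vapply(feats, feature_length, integer(1), genome_length = L)
  ign <- integer(n)
  degenerate <- FALSE
  if (n == 1L) {
    ign[1] <- L - size[1]
    degenerate <- TRUE
  } else {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ign[i] <- intergenic_gap(feats[[i]], feats[[j]], L, wrap = (i == n))
    }
  }
  spans <- paste(vapply(feats, `[[`, integer(1), "start"),
                 vapply(feats, `[[`, integer(1), "end"))
  if (anyDuplicated(spans))
    warning("features with identical spans present")
  d <- data.frame(
    name = vapply(feats, `[[`, character(1), "name"),
    gene_class = vapply(feats, `[[`, character(1), "gene_class"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    start = vapply(feats, `[[`, integer(1), "start"),
    end = vapply(feats, `[[`, integer(1), "end"),
    size = size, ign_next = ign, stringsAsFactors = FALSE)
  if (!is.null(table$size_printed)) d$size_printed <- table$size_printed
  if (!is.null(table$ign)) d$ign_printed <- table$ign
  attr(d, "degenerate") <- degenerate
  d
}

#' Summarize a gene arrangement
#'
#' Counts and total lengths per gene class, spacer/overlap statistics over
#' the signed intergenic-nucleotide values, and the protein-coding fraction
#' of the genome. `ign_source`/`size_source` select between values computed
#' from coordinates and a printed column retained from a published table.
#'
#' @param rows output of [build_arrangement()].
#' @param genome_length genome length in bp.
#' @param ign_source `"computed"` or `"printed"`.
#' @param size_source class totals from `"computed"` or `"printed"` sizes.
#' @return list with `class_counts`, `class_totals`, `spacer_count`,
#'   `spacer_total`, `spacer_max`, `overlap_count`, `overlap_max`,
#'   `pcg_fraction_of_genome` (percent, 2 decimals).
#' @export
summarize_arrangement <- function(rows, genome_length,
                                  ign_source = c("computed", "printed"),
                                  size_source = c("computed", "printed")) {
  ign_source <- match.arg(ign_source)
  size_source <- match.arg(size_source)
  ign <- if (ign_source == "printed") {
    if (is.null(rows$ign_printed))
      stop("printed IGN requested but table has no printed IGN column")
    rows$ign_printed
  } else rows$ign_next
  sizes <- if (size_source == "printed") {
    if (is.null(rows$size_printed))
      stop("printed sizes requested but table has no printed size column")
    rows$size_printed
  } else rows$size
  ign <- ign[!is.na(ign)]
  pos <- ign[ign > 0L]; neg <- ign[ign < 0L]
  cls <- rows$gene_class
  class_counts <- table(cls)
  class_totals <- tapply(sizes, cls, function(x) sum(x, na.rm = TRUE))
  pcg_total <- sum(rows$size[cls == "PCG"])
  list(
    class_counts = c(class_counts),
    class_totals = c(class_totals),
    spacer_count = length(pos),
    spacer_total = sum(pos),
    spacer_max = if (length(pos)) max(pos) else 0L,
    overlap_count = length(neg),
    overlap_max = if (length(neg)) max(-neg) else 0L,
    pcg_fraction_of_genome =
      round_half_up(100 * pcg_total / genome_length, 2))
}

#' Canonical gene-order signature
#'
#' The ordered, stranded gene list as `name(strand)` tokens, rotated so the
#' anchor gene comes first (default `trnI`); two genomes share an
#' arrangement iff their signatures are equal. When the anchor is absent
#' the lexicographically minimal rotation is used.
#'
#' @param table an [annotation_table()].
#' @param anchor anchor gene name.
#' @return single string, tokens separated by spaces.
#' @export
gene_order_signature <- function(table, anchor = "trnI") {
  feats <- table$features
  tok <- vapply(feats, function(f) sprintf("%s(%s)", f$name, f$strand),
                character(1))
  n <- length(tok)
  rot <- function(k) paste(tok[c(k:n, if (k > 1) 1:(k - 1))], collapse = " ")
  nm <- vapply(feats, `[[`, character(1), "name")
  k <- match(anchor, nm)
  if (!is.na(k)) return(rot(k))
  min(vapply(seq_len(n), rot, character(1)))
}
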