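# Fixed windows around named gene junctions and conserved-motif reporting.

#' Extract a junction window
#'
#' The window spans the last `flank_a` bases of `gene_a` through the first
#' `flank_b` bases of `gene_b`, extracted once from the genome (an overlap
#' between the genes is handled by coordinate arithmetic, never by
#' duplicating shared sequence) and returned on the reading strand of
#' `gene_a`: for a minus-strand `gene_a` the plus-strand extraction is
#' reverse-complemented.
#'
#' @param genome a [genome_record()].
#' @param table an [annotation_table()].
#' @param gene_a,gene_b names of the two annotated genes, in circular
#'   order.
#' @param flank_a,flank_b flank widths in bp (defaults 15/15).
#' @param max_separation maximum allowed gap between the genes (default
#'   50 bp).
#' @return object of class `JunctionWindow`: list with `genome_id`,
#'   `gene_a`, `gene_b`, `seq`, `offset_of_junction` (= `flank_a`) and
#'   `gap`.
#' @export
junction_window <- function(genome, table, gene_a, gene_b,
                            flank_a = 15L, flank_b = 15L,
                            max_separation = 50L) {
  fa <- get_feature(table, gene_a)
  fb <- get_feature(table, gene_b)
  L <- genome$length
  gap <- fb$start - fa$end - 1L
  if (gap < -L / 2) gap <- gap + L  # adjacency across the origin
  if (gap > max_separation)
    stop("genes '", gene_a, "' and '", gene_b, "' are ", gap,
         " bp apart (max_separation = ", max_separation, ")")
  w_start <- fa$end - flank_a + 1L
  w_end <- fb$start + flank_b - 1L
  span <- list(name = paste0(gene_a, "/", gene_b), strand = "+",
               start = ((w_start - 1L) %% L) + 1L,
               end = ((w_end - 1L) %% L) + 1L)
  seq <- extract_feature_sequence(genome, span)
  if (fa$strand == "-") seq <- revcomp(seq)
  structure(list(genome_id = genome$id, gene_a = gene_a, gene_b = gene_b,
                 seq = seq, offset_of_junction = as.integer(flank_a),
                 gap = gap),
            class = "JunctionWindow")
}

#' Scan junction windows for a motif
#'
#' Exact matching at `max_mismatch = 0` (equivalent to naive substring
#' search); otherwise every window position with at most `max_mismatch`
#' substitutions is reported.
#'
#' @param windows list of [junction_window()] objects.
#' @param motif nucleotide motif.
#' @param max_mismatch maximum substitutions per hit (default 0).
#' @return data frame `genome_id`, `gene_a`, `gene_b`, `position`
#'   (1-based within window), `mismatches`; zero rows where nothing hits.
#' @export
motif_scan <- function(windows, motif, max_mismatch = 0L) {
  stopifnot(nzchar(motif))
  motif <- toupper(motif)
  m <- nchar(motif)
  mb <- strsplit(motif, "", fixed = TRUE)[[1]]
  rows <- list()
  for (w in windows) {
    if (m > nchar(w$seq)) {
      warning("motif longer than window for ", w$gene_a, "/", w$gene_b,
              " in ", w$genome_id)
      next
    }
    sb <- strsplit(w$seq, "", fixed = TRUE)[[1]]
    for (p in seq_len(length(sb) - m + 1L)) {
      mm <- sum(sb[p:(p + m - 1L)] != mb)
      if (mm <= max_mismatch)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = w$genome_id, gene_a = w$gene_a, gene_b = w$gene_b,
          position = p, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(0), gene_a = character(0),
                      gene_b = character(0), position = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-column consensus of junction windows
#'
#' Windows of unequal length are trimmed to the shortest with a warning.
#' The consensus takes the modal base per column (ties broken `A < C < G <
#' T`) and reports the modal base's frequency as the conservation fraction.
#'
#' @param windows list of [junction_window()] objects (or plain character
#'   sequences).
#' @return list with `consensus` (string) and `conservation` (numeric
#'   vector in `(0, 1]`, one entry per column).
#' @export
consensus_window <- function(windows) {
  if (length(windows) == 0L) stop("no windows supplied")
  seqs <- vapply(windows, function(w)
    if (is.character(w)) w else w$seq, character(1))
  n <- nchar(seqs)
  if (length(unique(n)) > 1L) {
    warning("windows of unequal length; trimming to ", min(n), " bp")
    seqs <- substr(seqs, 1L, min(n))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cols <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    best <- names(tab)[which.max(tab)]   # which.max: first max, A<C<G<T order
    c(base = best, frac = max(tab) / length(col))
  })
  list(consensus = paste(cols["base", ], collapse = ""),
       conservation = as.numeric(cols["frac", ]))
}

#' Write junction windows as multi-FASTA
#'
#' @param windows list of [junction_window()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(windows, path) {
  recs <- lapply(windows, function(w)
    genome_record(sprintf("%s|%s-%s", w$genome_id, w$gene_a, w$gene_b),
                  w$seq, circular = FALSE))
  write_fasta(recs, path)
}
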