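# Detection of control-region features: homopolymer stretches,
# dinucleotide (and general short-unit) microsatellites, and long direct
# repeats. Coordinates are region-relative, 1-based. All detectors report
# maximal features only.

repeat_feature <- function(kind, start, length, unit, copies = NA_integer_,
                           mate_start = NA_integer_, occurrences = NULL) {
  structure(list(kind = kind, start = as.integer(start),
                 length = as.integer(length), unit = unit,
                 copies = as.integer(copies),
                 mate_start = as.integer(mate_start),
                 occurrences = occurrences),
            class = "RepeatFeature")
}

repeat_df <- function(features) {
  if (length(features) == 0L)
    return(data.frame(kind = character(0), start = integer(0),
                      length = integer(0), unit = character(0),
                      copies = integer(0), mate_start = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(features, function(f)
    data.frame(kind = f$kind, start = f$start, length = f$length,
               unit = f$unit, copies = f$copies, mate_start = f$mate_start,
               stringsAsFactors = FALSE)))
}

#' Maximal homopolymer runs
#'
#' @param seq nucleotide string.
#' @param min_len minimum run length (>= 2).
#' @return data frame of runs (`kind = "homopolymer"`), left to right.
#' @export
homopolymer_runs <- function(seq, min_len = 10L) {
  stopifnot(min_len >= 2L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  repeat_df(lapply(which(keep), function(i)
    repeat_feature("homopolymer", starts[i], r$lengths[i], r$values[i],
                   copies = r$lengths[i])))
}

least_rotation <- function(x) {
  n <- nchar(x)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
  min(rots)
}

#' Maximal short-unit tandem arrays (microsatellites)
#'
#' Finds maximal tandem arrays of a `unit_len`-bp unit with at least
#' `min_copies` full copies. Arrays whose unit is a single repeated base
#' are excluded when `unit_len > 1` (a `(TT)n` is a homopolymer, not a
#' microsatellite). The reported `unit` is as read at the array start; the
#' canonical unit (lexicographically least rotation) is reported alongside.
#'
#' @param seq nucleotide string.
#' @param unit_len repeat-unit length (>= 1).
#' @param min_copies minimum number of full copies (>= 2).
#' @return data frame of arrays with an extra `unit_canonical` column.
#' @export
microsatellites <- function(seq, unit_len = 2L, min_copies = 5L) {
  stopifnot(unit_len >= 1L, min_copies >= 2L)
  n <- nchar(seq)
  u <- as.integer(unit_len)
  if (n < u * min_copies) return(cbind(repeat_df(list()),
                                       unit_canonical = character(0)))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  # positions where s[i] == s[i+u]: maximal period-u regions
  eq <- b[seq_len(n - u)] == b[(u + 1L):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  feats <- list()
  for (i in which(r$values)) {
    region_len <- r$lengths[i] + u        # matched span in bases
    copies <- region_len %/% u
    if (copies < min_copies) next
    start <- starts[i]
    unit <- substr(seq, start, start + u - 1L)
    if (u > 1L && length(unique(strsplit(unit, "")[[1]])) == 1L) next
    feats[[length(feats) + 1L]] <- c(
      list(repeat_feature("microsatellite", start, copies * u, unit,
                          copies = copies)),
      canonical = least_rotation(unit))
  }
  d <- repeat_df(lapply(feats, `[[`, 1L))
  d$unit_canonical <- vapply(feats, `[[`, character(1), "canonical")
  d
}

#' Long direct repeats
#'
#' Maximal substrings of length >= `min_len` occurring at two or more
#' distinct positions (same strand). Each distinct repeated substring is
#' reported once with all its occurrence starts; substrings wholly
#' contained (content and occurrences) in a longer reported repeat are
#' suppressed. The search enumerates all substrings per length, longest
#' first, with explicit string comparison — collision-free by construction
#' and fast enough for control-region scale (a few kb).
#'
#' @param seq nucleotide string.
#' @param min_len minimum repeat length (>= 8).
#' @return data frame: `kind = "direct_repeat"`, `start` (first
#'   occurrence), `mate_start` (second occurrence), `copies` (number of
#'   occurrences), `unit` (the repeated segment).
#' @export
long_direct_repeats <- function(seq, min_len = 30L) {
  stopifnot(min_len >= 8L)
  n <- nchar(seq)
  if (n < 2L * min_len && n < min_len + 1L) return(repeat_df(list()))
  kept <- list()  # each: unit, occ (integer starts), length
  covered_by_kept <- function(unit, occ) {
    for (k in kept) {
      off <- as.integer(gregexpr(unit, k$unit, fixed = TRUE)[[1]])
      off <- off[off > 0L]
      if (length(off) == 0L) next
      ok <- vapply(occ, function(s)
        any(vapply(k$occ, function(ks)
          any(s - ks + 1L == off), logical(1))), logical(1))
      if (all(ok)) return(TRUE)
    }
    FALSE
  }
  # longest repeated substring length via diagonal self-comparison: caps
  # the enumeration so typical regions cost O(n) substring passes
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  max_len <- 0L
  for (d in seq_len(n - 1L)) {
    eq <- b[seq_len(n - d)] == b[(d + 1L):n]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs)) max_len <- max(max_len, max(runs))
  }
  if (max_len < min_len) return(repeat_df(list()))
  for (len in seq(max_len, min_len)) {
    starts <- seq_len(n - len + 1L)
    subs <- substring(seq, starts, starts + len - 1L)
    grp <- split(starts, subs)
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp) == 0L) next
    for (unit in sort(names(grp))) {
      occ <- grp[[unit]]
      if (!covered_by_kept(unit, occ))
        kept[[length(kept) + 1L]] <- list(unit = unit, occ = occ, length = len)
    }
  }
  kept <- kept[order(vapply(kept, function(k) k$occ[1], integer(1)))]
  repeat_df(lapply(kept, function(k)
    repeat_feature("direct_repeat", k$occ[1], k$length, k$unit,
                   copies = length(k$occ), mate_start = k$occ[2],
                   occurrences = k$occ)))
}

#' Control-region feature report
#'
#' Extracts the control region, computes its composition row and runs the
#' three detectors with the configured minima. Detector coordinates are
#' region-relative (1-based); a genome-absolute start column is added.
#'
#' @param genome a [genome_record()].
#' @param table an [annotation_table()] containing a `control_region`
#'   feature.
#' @param min_homopolymer minimum homopolymer run (default 10).
#' @param microsat_unit microsatellite unit length (default 2).
#' @param microsat_min_copies minimum copies (default 5).
#' @param min_repeat minimum direct-repeat length (default 30).
#' @return list with `composition` (one-row data frame) and `features`
#'   (data frame over all three detectors with `genome_start` column).
#' @export
region_report <- function(genome, table, min_homopolymer = 10L,
                          microsat_unit = 2L, microsat_min_copies = 5L,
                          min_repeat = 30L) {
  cr <- Filter(function(f) f$gene_class == "control_region", table$features)
  if (length(cr) == 0L) stop("no control_region feature annotated")
  cr <- cr[[1L]]
  seq <- extract_feature_sequence(genome, cr)
  n <- base_counts(seq)
  comp <- data.frame(label = cr$name, t(round_half_up(base_composition(seq), 2)),
                     at_skew = round_half_up(at_skew(n["A"], n["T"]), 3),
                     gc_skew = round_half_up(gc_skew(n["G"], n["C"]), 3),
                     row.names = NULL, stringsAsFactors = FALSE)
  h <- homopolymer_runs(seq, min_homopolymer)
  m <- microsatellites(seq, microsat_unit, microsat_min_copies)
  m$unit_canonical <- NULL
  r <- long_direct_repeats(seq, min_repeat)
  feats <- rbind(h, m, r)
  # region-relative -> genome-absolute (control region on its own strand)
  feats$genome_start <- if (cr$strand == "+") {
    cr$start + feats$start - 1L
  } else {
    cr$end - (feats$start + feats$length - 1L) + 1L
  }
  list(composition = comp, features = feats)
}
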