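# Heuristic cloverleaf folding of annotated mitochondrial tRNA genes.
#
# The search is anchored on the anticodon arm rather than free-energy
# minimization: mitochondrial tRNA claims of interest are arm presence and
# the inventory of Watson-Crick / G-U wobble / mismatched stem pairs, and
# an anchored search is auditable and needs no thermodynamic tables.
#
# Procedure: (1) enumerate candidate anticodon arms (stem 4-5 pairs around
# a 7-nt loop, the expected anticodon required at loop positions 3-5 when
# given); (2) fix the acceptor stem as the best 7-pair register of
# positions 1-7 against the 3' end (with or without a discriminator base,
# at most 2 non-pairs); (3) search the DHU arm (stem 3-4, loop 4-12)
# between acceptor and anticodon arm and the T-arm (stem 4-5, loop 3-9)
# between anticodon arm and the acceptor 3' side; (4) score
# 3*WC + 2*GU - 1*mismatch over all stems and keep the highest-scoring
# non-crossing assembly (ties: leftmost start, then longest stem, then
# shortest loop).

#' Folding thresholds and scoring weights
#'
#' @param anticodon_stem,dhu_stem,tpsic_stem integer ranges of allowed stem
#'   lengths (pairs).
#' @param anticodon_loop anticodon loop length (fixed, nt).
#' @param dhu_loop,tpsic_loop allowed loop length ranges (nt).
#' @param acceptor_pairs acceptor stem length (pairs).
#' @param acceptor_max_nonpairs maximum non-WC/GU pairs tolerated in the
#'   acceptor stem.
#' @param stem_max_mismatch maximum mismatches tolerated in a candidate
#'   arm stem.
#' @param w_wc,w_gu,w_mm scoring weights.
#' @return list of folding parameters.
#' @export
trna_fold_config <- function(anticodon_stem = 4:5, anticodon_loop = 7L,
                             dhu_stem = 3:4, dhu_loop = 4:12,
                             tpsic_stem = 4:5, tpsic_loop = 3:9,
                             acceptor_pairs = 7L, acceptor_max_nonpairs = 2L,
                             stem_max_mismatch = 1L,
                             w_wc = 3, w_gu = 2, w_mm = -1) {
  list(anticodon_stem = sort(anticodon_stem, decreasing = TRUE),
       anticodon_loop = as.integer(anticodon_loop),
       dhu_stem = sort(dhu_stem, decreasing = TRUE),
       dhu_loop = sort(dhu_loop),
       tpsic_stem = sort(tpsic_stem, decreasing = TRUE),
       tpsic_loop = sort(tpsic_loop),
       acceptor_pairs = as.integer(acceptor_pairs),
       acceptor_max_nonpairs = as.integer(acceptor_max_nonpairs),
       stem_max_mismatch = as.integer(stem_max_mismatch),
       w_wc = w_wc, w_gu = w_gu, w_mm = w_mm)
}

pair_class <- function(b5, b3) {
  p <- paste0(b5, b3)
  ifelse(p %in% c("AT", "TA", "GC", "CG"), "watson_crick",
         ifelse(p %in% c("GT", "TG"), "gu_wobble", "mismatch"))
}

stem_eval <- function(b, p5, p3, cfg) {
  cls <- pair_class(b[p5], b[p3])
  score <- sum((cls == "watson_crick") * cfg$w_wc +
               (cls == "gu_wobble") * cfg$w_gu +
               (cls == "mismatch") * cfg$w_mm)
  list(cls = cls, score = score, n_mismatch = sum(cls == "mismatch"))
}

make_arm <- function(present, pairs = NULL, loop = NULL, score = 0) {
  list(present = present, pairs = pairs, loop = loop, score = score)
}

# best hairpin (stem k around loop l) with stem start in [from, to_start],
# whole arm within [from, to_end]; enumeration order d asc, k desc, l asc
best_hairpin <- function(b, from, to_end, stems, loops, cfg) {
  best <- NULL
  if (from < 1L || to_end > length(b) || from > to_end) return(NULL)
  for (d in from:to_end) {
    for (k in stems) {
      for (l in loops) {
        arm_end <- d + 2L * k + l - 1L
        if (arm_end > to_end) next
        p5 <- d:(d + k - 1L)
        p3 <- arm_end:(arm_end - k + 1L)
        ev <- stem_eval(b, p5, p3, cfg)
        if (ev$n_mismatch > cfg$stem_max_mismatch) next
        if (is.null(best) || ev$score > best$score) {
          best <- make_arm(TRUE, pairs = cbind(p5 = p5, p3 = p3),
                           loop = c(d + k, arm_end - k), score = ev$score)
        }
      }
    }
  }
  best
}

#' Fold a tRNA sequence into a cloverleaf
#'
#' @param seq tRNA gene sequence (reading strand, DNA letters); lengths
#'   outside 55-95 nt trigger a warning.
#' @param expected_anticodon optional anticodon triplet (DNA letters)
#'   required at positions 3-5 of the anticodon loop.
#' @param config a [trna_fold_config()].
#' @return object of class `CloverleafStructure`: list with arms
#'   `acceptor`, `dhu`, `anticodon_arm`, `tpsic` (each with `present`,
#'   `pairs` matrix, `loop` span, `score`), plus `anticodon`,
#'   `anticodon_span`, `variable_loop`, `score`, `n`, `diagnostic`.
#' @export
fold_cloverleaf <- function(seq, expected_anticodon = NULL,
                            config = trna_fold_config()) {
  seq <- rna_to_dna(toupper(seq))
  n <- nchar(seq)
  if (n < 55L || n > 95L)
    warning("tRNA length ", n, " nt outside the typical 55-95 range")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  cfg <- config
  ap <- cfg$acceptor_pairs

  # acceptor stem: 5' 1..7 against the 3' end, with (e = n-1, canonical
  # discriminator) preferred over (e = n) on ties
  acceptor <- make_arm(FALSE)
  acc_e <- NA_integer_
  for (e in c(n - 1L, n)) {
    p5 <- 1L:ap
    p3 <- e - p5 + 1L
    if (min(p3) <= ap) next
    ev <- stem_eval(b, p5, p3, cfg)
    if (ev$n_mismatch > cfg$acceptor_max_nonpairs) next
    if (!acceptor$present || ev$score > acceptor$score) {
      acceptor <- make_arm(TRUE, pairs = cbind(p5 = p5, p3 = p3),
                           loop = NULL, score = ev$score)
      acc_e <- e
    }
  }
  acc3_start <- if (!is.na(acc_e)) acc_e - ap + 1L else n - ap

  # candidate anticodon arms
  candidates <- list()
  loop_l <- cfg$anticodon_loop
  for (d in if (ap + 1L <= n - ap) (ap + 1L):(n - ap) else integer(0)) {
    for (k in cfg$anticodon_stem) {
      arm_end <- d + 2L * k + loop_l - 1L
      if (arm_end > n - ap) next
      loop_start <- d + k
      if (!is.null(expected_anticodon)) {
        got <- substr(seq, loop_start + 2L, loop_start + 4L)
        if (got != toupper(expected_anticodon)) next
      }
      p5 <- d:(d + k - 1L)
      p3 <- arm_end:(arm_end - k + 1L)
      ev <- stem_eval(b, p5, p3, cfg)
      if (ev$n_mismatch > cfg$stem_max_mismatch) next
      candidates[[length(candidates) + 1L]] <-
        make_arm(TRUE, pairs = cbind(p5 = p5, p3 = p3),
                 loop = c(loop_start, arm_end - k), score = ev$score)
    }
  }

  empty <- make_arm(FALSE)
  best <- NULL
  for (cand in candidates) {
    ac_start <- cand$pairs[1, "p5"]
    ac_end <- max(cand$pairs[, "p3"])
    dhu <- best_hairpin(b, ap + 1L, ac_start - 1L,
                        cfg$dhu_stem, cfg$dhu_loop, cfg)
    tpsic <- best_hairpin(b, ac_end + 1L, acc3_start - 1L,
                          cfg$tpsic_stem, cfg$tpsic_loop, cfg)
    total <- acceptor$score + cand$score +
      (if (is.null(dhu)) 0 else dhu$score) +
      (if (is.null(tpsic)) 0 else tpsic$score)
    if (is.null(best) || total > best$total) {
      best <- list(ac = cand, dhu = dhu %||% empty,
                   tpsic = tpsic %||% empty, total = total)
    }
  }

  if (is.null(best)) {
    st <- list(acceptor = acceptor, dhu = empty, anticodon_arm = empty,
               tpsic = empty, anticodon = NA_character_,
               anticodon_span = NULL, variable_loop = NULL,
               score = acceptor$score, n = n,
               diagnostic = "no anticodon arm candidate")
  } else {
    ac <- best$ac
    anticodon_span <- c(ac$loop[1] + 2L, ac$loop[1] + 4L)
    ac_end <- max(ac$pairs[, "p3"])
    var_start <- ac_end + 1L
    var_end <- if (best$tpsic$present) best$tpsic$pairs[1, "p5"] - 1L
               else acc3_start - 1L
    st <- list(acceptor = acceptor, dhu = best$dhu, anticodon_arm = ac,
               tpsic = best$tpsic,
               anticodon = substr(seq, anticodon_span[1], anticodon_span[2]),
               anticodon_span = anticodon_span,
               variable_loop = if (var_end >= var_start) c(var_start, var_end)
                               else NULL,
               score = best$total, n = n, diagnostic = NA_character_)
  }
  st$seq <- seq
  class(st) <- "CloverleafStructure"
  st
}

structure_pairs <- function(st) {
  arms <- list(acceptor = st$acceptor, dhu = st$dhu,
               anticodon_arm = st$anticodon_arm, tpsic = st$tpsic)
  do.call(rbind, lapply(names(arms), function(a) {
    arm <- arms[[a]]
    if (!isTRUE(arm$present) || is.null(arm$pairs)) return(NULL)
    data.frame(arm = a, p5 = arm$pairs[, "p5"], p3 = arm$pairs[, "p3"],
               stringsAsFactors = FALSE)
  }))
}

#' Classify the base pairs of a folded structure
#'
#' Each stem pair is Watson-Crick (`AU`, `UA`, `GC`, `CG`), a G-U wobble
#' (`GU`, `UG`) or a mismatch; mismatches are listed with positions and
#' bases (RNA letters).
#'
#' @param structure a [fold_cloverleaf()] result.
#' @param seq optional sequence (defaults to the one stored in the
#'   structure).
#' @return list with `counts` (named: watson_crick, gu_wobble, mismatch)
#'   and `mismatch_list` (data frame `arm`, `pos5`, `pos3`, `bases`).
#' @export
classify_pairs <- function(structure, seq = structure$seq) {
  seq <- rna_to_dna(toupper(seq))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  pr <- structure_pairs(structure)
  if (is.null(pr) || nrow(pr) == 0L) {
    return(list(counts = c(watson_crick = 0L, gu_wobble = 0L, mismatch = 0L),
                mismatch_list = data.frame(arm = character(0),
                                           pos5 = integer(0),
                                           pos3 = integer(0),
                                           bases = character(0))))
  }
  cls <- pair_class(b[pr$p5], b[pr$p3])
  counts <- c(watson_crick = sum(cls == "watson_crick"),
              gu_wobble = sum(cls == "gu_wobble"),
              mismatch = sum(cls == "mismatch"))
  mm <- pr[cls == "mismatch", , drop = FALSE]
  mismatch_list <- data.frame(
    arm = mm$arm, pos5 = mm$p5, pos3 = mm$p3,
    bases = if (nrow(mm)) paste0(dna_to_rna(b[mm$p5]), "-",
                                 dna_to_rna(b[mm$p3])) else character(0),
    stringsAsFactors = FALSE)
  list(counts = counts, mismatch_list = mismatch_list)
}

#' Dot-bracket string for a folded structure
#'
#' @param structure a [fold_cloverleaf()] result.
#' @return string of `(`, `)` and `.` of the sequence's length.
#' @export
dot_bracket <- function(structure) {
  db <- rep(".", structure$n)
  pr <- structure_pairs(structure)
  if (!is.null(pr) && nrow(pr)) {
    db[pr$p5] <- "("
    db[pr$p3] <- ")"
  }
  paste(db, collapse = "")
}

#' Fold all annotated tRNAs of a genome
#'
#' Extracts each tRNA strand-aware, folds it (using the annotated
#' anticodon as the expected anticodon when present) and summarizes arm
#' presence and pair classes.
#'
#' @param genome a [genome_record()].
#' @param table an [annotation_table()] with tRNA features.
#' @param config a [trna_fold_config()].
#' @return list with `structures` (named list of `CloverleafStructure`),
#'   `report` (data frame: gene, length, arm presence flags, anticodon,
#'   pair-class counts, dot-bracket) and `missing_arm_counts`.
#' @export
fold_all <- function(genome, table, config = trna_fold_config()) {
  trnas <- Filter(function(f) f$gene_class == "tRNA", table$features)
  if (length(trnas) == 0L) stop("no tRNA features annotated")
  structures <- list()
  rows <- list()
  for (f in trnas) {
    seq <- extract_feature_sequence(genome, f)
    exp_ac <- if (!is.na(f$anticodon)) f$anticodon else NULL
    st <- fold_cloverleaf(seq, expected_anticodon = exp_ac, config = config)
    cp <- classify_pairs(st)
    structures[[f$name]] <- st
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f$name, length = st$n,
      acceptor = st$acceptor$present, dhu = st$dhu$present,
      anticodon_arm = st$anticodon_arm$present, tpsic = st$tpsic$present,
      anticodon = st$anticodon,
      watson_crick = cp$counts["watson_crick"],
      gu_wobble = cp$counts["gu_wobble"],
      mismatch = cp$counts["mismatch"],
      dot_bracket = dot_bracket(st),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  report <- do.call(rbind, rows)
  list(structures = structures, report = report,
       missing_arm_counts = c(
         acceptor = sum(!report$acceptor), dhu = sum(!report$dhu),
         anticodon_arm = sum(!report$anticodon_arm),
         tpsic = sum(!report$tpsic)))
}
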