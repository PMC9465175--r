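# Seeded generator of circular 37-gene insect mitogenomes with a
# ground-truth manifest. The annotation skeleton is laid out first and the
# sequence is generated into it, so every manifest quantity (coordinates,
# gaps, planted features, tRNA arms, codon counts) is exact rather than
# estimated. The generator verifies its own manifest by running the
# analysis modules on the emitted genome; random filler is resampled
# (deterministically, bounded) until recovery is exact.

# ancestral insect gene order; sizes for tRNAs are derived from the arm
# layout, PCG/rRNA/control-region sizes are typical stick-insect values
# adjusted to codon frame
ancestral_template <- function() {
  d <- data.frame(
    name = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY",
             "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
             "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
             "trnE", "trnF", "nad5", "trnH", "nad4", "nad4L", "trnT",
             "trnP", "nad6", "cob", "trnS2", "nad1", "trnL1", "rrnL",
             "trnV", "rrnS", "AT_rich"),
    strand = c("+", "-", "+", "+", "+", "-", "-",
               "+", "+", "+", "+", "+", "+", "+",
               "+", "+", "+", "+", "+", "+", "+",
               "+", "-", "-", "-", "-", "-", "+",
               "-", "+", "+", "+", "-", "-", "-",
               "-", "-", "+"),
    stringsAsFactors = FALSE)
  d$gene_class <- vapply(d$name, function(n) {
    if (grepl("^trn", n)) "tRNA"
    else if (grepl("^rrn", n)) "rRNA"
    else if (n == "AT_rich") "control_region" else "PCG"
  }, character(1))
  sizes <- c(nad2 = 1006L, cox1 = 1534L, cox2 = 670L, atp8 = 159L,
             atp6 = 681L, cox3 = 789L, nad3 = 352L, nad5 = 1723L,
             nad4 = 1332L, nad4L = 291L, nad6 = 480L, cob = 1132L,
             nad1 = 963L, rrnL = 1291L, rrnS = 769L, AT_rich = 1465L)
  d$size <- unname(sizes[d$name])   # NA for tRNAs, filled later
  gaps <- stats::setNames(integer(nrow(d)), d$name)  # gap to next feature
  gaps[c("trnW", "trnN")] <- -1L
  gaps["trnY"] <- 1L
  gaps["cox2"] <- 9L
  gaps["atp8"] <- -7L
  gaps[c("cox3", "nad5")] <- 2L
  gaps["nad3"] <- 6L
  gaps["nad6"] <- 5L
  gaps["trnS2"] <- 7L
  gaps["nad1"] <- 4L
  d$gap_next <- unname(gaps)
  d
}

default_anticodons <- function() c(
  trnI = "GAT", trnQ = "TTG", trnM = "CAT", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

default_pcg_spec <- function() list(
  nad2  = list(start = "ATC", stop = "T"),
  cox1  = list(start = "ATG", stop = "T"),
  cox2  = list(start = "ATA", stop = "T"),
  atp8  = list(start = "ATC", stop = "TAA"),
  atp6  = list(start = "ATG", stop = "TAA"),
  cox3  = list(start = "ATG", stop = "TAA"),
  nad3  = list(start = "ATT", stop = "T"),
  nad5  = list(start = "ATA", stop = "T"),
  nad4  = list(start = "TTA", stop = "TAA"),
  nad4L = list(start = "TTA", stop = "TAA"),
  nad6  = list(start = "ATA", stop = "TAA"),
  cob   = list(start = "ATG", stop = "T"),
  nad1  = list(start = "ATA", stop = "TAA"))

default_codon_weights <- function() {
  w <- as.numeric(table4_fixture())
  names(w) <- names(table4_fixture())
  w[c("UAA", "UAG")] <- 0  # no internal stops
  w
}

#' Simulation configuration
#'
#' Defaults emulate a stick-insect mitogenome: ancestral insect gene order
#' (13 PCGs, 22 tRNAs, 2 rRNAs, one control region), an A+T-rich control
#' region of 1,465 bp at 87% A+T carrying a 19 bp poly-T stretch, a
#' (TA)10 microsatellite, a terminal 12 bp poly-A and two >30 bp segments
#' each planted twice; codon usage drawn from the published codon-count
#' table; ATGATAA planted across the atp8/atp6 overlap (-7 bp) and
#' TTAACTA in a 7 bp trnS2/nad1 spacer; trnH, trnM and trnF built without
#' T-arms.
#'
#' @param seed integer seed; the generator is deterministic given the
#'   whole configuration.
#' @param template gene-order template data frame (`name`, `strand`,
#'   `gene_class`, `size`, `gap_next`).
#' @param pcg per-PCG start/stop specification.
#' @param anticodons named anticodon triplets (DNA) per tRNA.
#' @param tpsic_absent tRNAs built without a T-arm.
#' @param dhu_absent tRNAs built without a DHU arm.
#' @param codon_weights sampling weights over the 64 codons (RNA names).
#' @param target_at per-class A+T percentage targets for random filler.
#' @param control_region_plants list: `poly_t`, `ta_copies`, `poly_a`,
#'   `repeats` (character vector, each planted twice).
#' @param junction_plants list of `list(gene_a, gene_b, motif, mode)`,
#'   mode `"overlap"` (motif realized structurally across a negative gap)
#'   or `"spacer"` (motif written into a positive gap of the motif's
#'   length).
#' @param max_retries bound on deterministic resampling passes.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              template = ancestral_template(),
                              pcg = default_pcg_spec(),
                              anticodons = default_anticodons(),
                              tpsic_absent = c("trnH", "trnM", "trnF"),
                              dhu_absent = character(0),
                              codon_weights = default_codon_weights(),
                              target_at = list(trna = 77, rrna = 81.7,
                                               control_region = 87,
                                               spacer = 80),
                              control_region_plants = list(
                                poly_t = 19L, ta_copies = 10L, poly_a = 12L,
                                repeats = CR_LONG_REPEATS[c(1, 3)]),
                              junction_plants = list(
                                list(gene_a = "atp8", gene_b = "atp6",
                                     motif = "ATGATAA", mode = "overlap"),
                                list(gene_a = "trnS2", gene_b = "nad1",
                                     motif = "TTAACTA", mode = "spacer")),
                              max_retries = 60L) {
  cfg <- structure(list(seed = as.integer(seed), template = template,
                        pcg = pcg, anticodons = anticodons,
                        tpsic_absent = tpsic_absent, dhu_absent = dhu_absent,
                        codon_weights = codon_weights, target_at = target_at,
                        control_region_plants = control_region_plants,
                        junction_plants = junction_plants,
                        max_retries = as.integer(max_retries)),
                   class = "SimulationConfig")
  validate_simulation_config(cfg)
  cfg
}

trna_length_for <- function(name, cfg) {
  n <- 72L
  if (name %in% cfg$tpsic_absent) n <- n - 11L  # T-arm + var loop -> 10-nt loop
  if (name %in% cfg$dhu_absent) n <- n - 10L    # DHU arm -> 6-nt replacement
  n
}

validate_simulation_config <- function(cfg) {
  d <- cfg$template
  stopifnot(is.data.frame(d), nrow(d) >= 2L)
  sizes <- d$size
  trna <- d$gene_class == "tRNA"
  sizes[trna] <- vapply(d$name[trna], trna_length_for, integer(1), cfg = cfg)
  if (any(is.na(sizes) | sizes < 1L))
    stop("template sizes must be positive (missing size for a non-tRNA?)")
  for (i in seq_len(nrow(d))) {
    g <- d$gap_next[i]
    j <- if (i == nrow(d)) 1L else i + 1L
    if (g < 0 && -g >= min(sizes[i], sizes[j]))
      stop("overlap of ", -g, " bp between ", d$name[i], " and ", d$name[j],
           " exceeds a gene size")
  }
  if (any(cfg$codon_weights < 0) || sum(cfg$codon_weights) <= 0)
    stop("codon_weights must be non-negative with positive sum")
  for (jp in cfg$junction_plants) {
    g <- d$gap_next[match(jp$gene_a, d$name)]
    m <- nchar(jp$motif)
    if (jp$mode == "overlap" && g != -m)
      stop("overlap-mode junction plant ", jp$gene_a, "/", jp$gene_b,
           " requires gap ", -m, ", template has ", g)
    if (jp$mode == "spacer" && g != m)
      stop("spacer-mode junction plant ", jp$gene_a, "/", jp$gene_b,
           " requires gap ", m, ", template has ", g)
    if (jp$mode == "overlap" && jp$gene_a %in% names(cfg$pcg)) {
      # the downstream gene owns the shared sequence, so the motif tail
      # must realize the upstream gene's stop codon
      sp <- cfg$pcg[[jp$gene_a]]
      stop_str <- if (sp$stop == "TAA") "TAA" else sp$stop
      tail <- substr(toupper(jp$motif), m - nchar(stop_str) + 1L, m)
      if (tail != stop_str)
        stop("overlap motif ", jp$motif, " is inconsistent with the ",
             jp$gene_a, " stop codon ", stop_str)
    }
  }
  invisible(cfg)
}

# random filler with capped homopolymer runs (<= 6) and capped period-2
# arrays (<= 8 nt), so planted control-region features stay uniquely
# maximal
rand_filler <- function(n, at_pct) {
  if (n <= 0L) return(character(0))
  p <- c(A = at_pct / 2, C = (100 - at_pct) / 2,
         G = (100 - at_pct) / 2, T = at_pct / 2) / 100
  bases <- names(p)
  v <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:12) {
      c0 <- sample(bases, 1L, prob = p)
      if (filler_ok(v, i, c0)) break
      c0 <- NA_character_
    }
    if (is.na(c0)) c0 <- setdiff(c("C", "G"), v[i - 1L])[1L]
    v[i] <- c0
  }
  v
}

filler_ok <- function(v, i, c0) {
  if (i > 6L && all(v[(i - 6L):(i - 1L)] == c0)) return(FALSE)
  cnt <- 0L
  j <- i - 2L
  prev <- c0
  while (j >= 1L && v[j] == prev) {
    cnt <- cnt + 1L
    prev <- v[j]
    j <- j - 1L
  }
  cnt < 7L
}

sample_codons_dna <- function(n, weights_rna, prefix_base = NULL) {
  w <- weights_rna
  w[c("UAA", "UAG")] <- 0
  codons <- rna_to_dna(names(w))
  if (!is.null(prefix_base)) {
    keep <- startsWith(codons, prefix_base)
    codons <- codons[keep]; w <- w[keep]
  }
  if (sum(w) <= 0) stop("no codons available under the given constraint")
  sample(codons, n, replace = TRUE, prob = w)
}

build_cds <- function(size, start_codon, stop_mode, weights_rna,
                      prefix = NULL) {
  stop_len <- c(TAA = 3L, TA = 2L, T = 1L)[[stop_mode]]
  n_internal <- (size - 3L - stop_len) / 3L
  if (n_internal != floor(n_internal) || n_internal < 1L)
    stop("CDS size ", size, " incompatible with stop '", stop_mode, "'")
  n_internal <- as.integer(n_internal)
  body <- sample_codons_dna(n_internal, weights_rna)
  cds <- paste0(start_codon, paste(body, collapse = ""),
                if (stop_mode == "TAA") "TAA" else stop_mode)
  if (!is.null(prefix)) {
    m <- nchar(prefix)
    if (substr(prefix, 1L, 3L) != start_codon)
      stop("junction prefix conflicts with start codon")
    k_full <- m %/% 3L
    rem <- m %% 3L
    if (rem > 0L) {
      # resample the straddling codon constrained to the prefix remainder
      base <- substr(prefix, 3L * k_full + 1L, m)
      cod <- sample_codons_dna(1L, weights_rna, prefix_base = base)
      prefix_full <- paste0(prefix, substr(cod, rem + 1L, 3L))
    } else prefix_full <- prefix
    cds <- paste0(prefix_full, substr(cds, nchar(prefix_full) + 1L, size))
  }
  stopifnot(nchar(cds) == size)
  cds
}

# ---- tRNA construction ------------------------------------------------------

arms_from_layout <- function(layout) {
  lapply(layout, function(a) {
    if (!a$present) return(list(present = FALSE))
    list(present = TRUE, pairs = a$pairs, loop = a$loop)
  })
}

build_trna <- function(anticodon, tpsic = TRUE, dhu = TRUE, at = 77,
                       max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    acc5 <- rand_filler(7L, at)
    link1 <- rand_filler(2L, at)
    pieces <- list(acc5, link1)
    pos <- 10L
    if (dhu) {
      dstem <- rand_filler(4L, at)
      dloop <- rand_filler(8L, at)
      dhu_arm <- list(present = TRUE,
                      pairs = cbind(p5 = pos:(pos + 3L),
                                    p3 = (pos + 15L):(pos + 12L)),
                      loop = c(pos + 4L, pos + 11L))
      pieces <- c(pieces, list(dstem, dloop, rev(chartr("ACGT", "TGCA", dstem))))
      pos <- pos + 16L
      link2 <- rand_filler(1L, at)
      pieces <- c(pieces, list(link2))
      pos <- pos + 1L
    } else {
      repl <- rand_filler(6L, at)   # 9-nt region 8..16: too short for any DHU arm
      dhu_arm <- list(present = FALSE)
      pieces <- c(pieces, list(repl, rand_filler(1L, at)))
      pos <- pos + 7L
    }
    ac_start <- pos
    astem <- rand_filler(5L, at)
    aloop <- c(rand_filler(2L, at), strsplit(anticodon, "")[[1]],
               rand_filler(2L, at))
    ac_arm <- list(present = TRUE,
                   pairs = cbind(p5 = ac_start:(ac_start + 4L),
                                 p3 = (ac_start + 16L):(ac_start + 12L)),
                   loop = c(ac_start + 5L, ac_start + 11L))
    pieces <- c(pieces, list(astem, aloop, rev(chartr("ACGT", "TGCA", astem))))
    pos <- pos + 17L
    if (tpsic) {
      var <- rand_filler(4L, at)
      tstem <- rand_filler(5L, at)
      tloop <- rand_filler(7L, at)
      t_start <- pos + 4L
      t_arm <- list(present = TRUE,
                    pairs = cbind(p5 = t_start:(t_start + 4L),
                                  p3 = (t_start + 16L):(t_start + 12L)),
                    loop = c(t_start + 5L, t_start + 11L))
      pieces <- c(pieces, list(var, tstem, tloop,
                               rev(chartr("ACGT", "TGCA", tstem))))
      pos <- pos + 21L
    } else {
      repl <- rand_filler(10L, at)  # too short to host any T-arm
      t_arm <- list(present = FALSE)
      pieces <- c(pieces, list(repl))
      pos <- pos + 10L
    }
    acc3 <- rev(chartr("ACGT", "TGCA", acc5))
    disc <- rand_filler(1L, at)
    pieces <- c(pieces, list(acc3, disc))
    n <- pos + 8L - 1L
    seq <- paste(unlist(pieces), collapse = "")
    stopifnot(nchar(seq) == n)
    acceptor <- list(present = TRUE,
                     pairs = cbind(p5 = 1:7, p3 = (n - 1L):(n - 7L)),
                     loop = NULL)
    layout <- list(acceptor = acceptor, dhu = dhu_arm,
                   anticodon_arm = ac_arm, tpsic = t_arm)
    st <- suppressWarnings(fold_cloverleaf(seq, expected_anticodon = anticodon))
    if (fold_matches_layout(st, layout))
      return(list(seq = seq, arms = arms_from_layout(layout), length = n))
  }
  stop("failed to build a uniquely foldable tRNA after ", max_tries, " tries")
}

fold_matches_layout <- function(st, layout) {
  for (a in c("acceptor", "dhu", "anticodon_arm", "tpsic")) {
    want <- layout[[a]]
    got <- st[[a]]
    if (!identical(isTRUE(want$present), isTRUE(got$present))) return(FALSE)
    if (isTRUE(want$present)) {
      if (is.null(got$pairs)) return(FALSE)
      if (!identical(unname(want$pairs[, 1]), unname(got$pairs[, "p5"])) ||
          !identical(unname(want$pairs[, 2]), unname(got$pairs[, "p3"])))
        return(FALSE)
    }
  }
  TRUE
}

# ---- control region ---------------------------------------------------------

build_control_region <- function(cfg) {
  pl <- cfg$control_region_plants
  at <- cfg$target_at$control_region
  len <- cfg$template$size[cfg$template$gene_class == "control_region"][1]
  plants <- c(list(strrep("T", pl$poly_t), strrep("TA", pl$ta_copies)),
              as.list(rep(toupper(pl$repeats), each = 2L)),
              list(strrep("A", pl$poly_a)))
  kinds <- c("poly_t", "ta",
             rep(paste0("rep", seq_along(pl$repeats)), each = 2L), "poly_a")
  plant_len <- sum(nchar(unlist(plants)))
  fill_total <- len - plant_len
  nseg <- length(plants)    # fillers before each plant; poly_a is terminal
  if (fill_total < 2L * nseg)
    stop("control region too short for its plants")
  seg <- rep(fill_total %/% nseg, nseg)
  seg[seq_len(fill_total %% nseg)] <- seg[seq_len(fill_total %% nseg)] + 1L

  for (attempt in seq_len(cfg$max_retries)) {
    v <- character(0)
    starts <- integer(length(plants))
    for (i in seq_along(plants)) {
      v <- c(v, rand_filler(seg[i], at))
      starts[i] <- length(v) + 1L
      v <- c(v, strsplit(plants[[i]], "")[[1]])
    }
    stopifnot(length(v) == len)
    v <- repair_cr_boundaries(v, plants, kinds, starts)
    region <- paste(v, collapse = "")

    exp_h <- rbind(
      data.frame(kind = "homopolymer", start = starts[kinds == "poly_t"],
                 length = pl$poly_t, unit = "T", copies = pl$poly_t,
                 mate_start = NA_integer_, stringsAsFactors = FALSE),
      data.frame(kind = "homopolymer", start = starts[kinds == "poly_a"],
                 length = pl$poly_a, unit = "A", copies = pl$poly_a,
                 mate_start = NA_integer_, stringsAsFactors = FALSE))
    exp_m <- data.frame(kind = "microsatellite", start = starts[kinds == "ta"],
                        length = 2L * pl$ta_copies, unit = "TA",
                        copies = pl$ta_copies, mate_start = NA_integer_,
                        unit_canonical = "AT", stringsAsFactors = FALSE)
    exp_r <- do.call(rbind, lapply(seq_along(pl$repeats), function(k) {
      occ <- starts[kinds == paste0("rep", k)]
      data.frame(kind = "direct_repeat", start = occ[1],
                 length = nchar(pl$repeats[k]), unit = toupper(pl$repeats[k]),
                 copies = 2L, mate_start = occ[2], stringsAsFactors = FALSE)
    }))
    exp_r <- exp_r[order(exp_r$start), ]
    rownames(exp_r) <- NULL

    got_h <- homopolymer_runs(region, 10L)
    got_m <- microsatellites(region, 2L, 5L)
    got_r <- long_direct_repeats(region, 30L)
    rownames(exp_h) <- NULL
    if (isTRUE(all.equal(got_h, exp_h, check.attributes = FALSE)) &&
        isTRUE(all.equal(got_m, exp_m, check.attributes = FALSE)) &&
        isTRUE(all.equal(got_r, exp_r, check.attributes = FALSE))) {
      return(list(seq = region,
                  expected = list(homopolymers = exp_h, microsatellites = exp_m,
                                  direct_repeats = exp_r)))
    }
  }
  stop("failed to build a control region with exactly the planted features")
}

# deterministic single-character repairs at plant boundaries so planted
# features cannot extend or pair up with flanking filler
repair_cr_boundaries <- function(v, plants, kinds, starts) {
  n <- length(v)
  fix <- function(pos, forbidden) {
    if (pos < 1L || pos > n) return()
    if (!v[pos] %in% forbidden) return()
    for (cand in c("C", "G", "A", "T")) {
      if (cand %in% forbidden) next
      old <- v[pos]; v[pos] <<- cand
      if (filler_ok(v, pos, cand)) return()
      v[pos] <<- old
    }
    v[pos] <<- setdiff(c("C", "G"), forbidden)[1L]
  }
  for (i in seq_along(plants)) {
    s <- starts[i]
    e <- s + nchar(plants[[i]]) - 1L
    k <- kinds[i]
    if (k == "poly_t") { fix(s - 1L, "T"); fix(e + 1L, "T") }
    if (k == "poly_a") { fix(s - 1L, "A"); if (e < n) fix(e + 1L, "A") }
    if (k == "ta") { fix(s - 1L, "A"); fix(e + 1L, "T") }
  }
  for (k in unique(kinds[grepl("^rep", kinds)])) {
    occ <- starts[kinds == k]
    lenr <- nchar(plants[[which(kinds == k)[1]]])
    before <- occ - 1L
    after <- occ + lenr
    if (all(before >= 1L) && v[before[1]] == v[before[2]])
      fix(before[2], v[before[1]])
    if (all(after <= n) && v[after[1]] == v[after[2]])
      fix(after[2], v[after[1]])
  }
  v
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic mitogenome with a ground-truth manifest
#'
#' Deterministic given the configuration (including its seed). The
#' returned manifest is verified at generation time by running the
#' package's own analysis modules on the emitted genome: coordinates and
#' gaps, planted control-region features, junction motifs and tRNA arm
#' boundaries are recovered exactly, and codon counts are tallied from the
#' final sequence.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` ([genome_record()]), `table`
#'   ([annotation_table()]) and `manifest` (list: `genome_length`,
#'   `features`, `gaps`, `codon_counts`, `control_region`, `junctions`,
#'   `trna_arms`, `expected_at`).
#' @export
generate_mitogenome <- function(config = simulation_config()) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  d <- cfg$template
  nfeat <- nrow(d)

  trna_idx <- which(d$gene_class == "tRNA")
  trnas <- list()
  for (i in trna_idx) {
    nm <- d$name[i]
    trnas[[nm]] <- build_trna(cfg$anticodons[[nm]],
                              tpsic = !(nm %in% cfg$tpsic_absent),
                              dhu = !(nm %in% cfg$dhu_absent),
                              at = cfg$target_at$trna)
    d$size[i] <- trnas[[nm]]$length
  }

  # coordinates from sizes and gaps; genome length by conservation
  start <- integer(nfeat); end <- integer(nfeat)
  pos <- 1L
  for (i in seq_len(nfeat)) {
    start[i] <- pos
    end[i] <- pos + d$size[i] - 1L
    pos <- end[i] + 1L + d$gap_next[i]
  }
  L <- sum(d$size) + sum(d$gap_next)
  stopifnot(pos == L + 1L)

  overlap_prefix <- list()
  for (jp in cfg$junction_plants) {
    if (jp$mode == "overlap") overlap_prefix[[jp$gene_b]] <- toupper(jp$motif)
  }

  seqs <- list()
  for (i in seq_len(nfeat)) {
    nm <- d$name[i]
    seqs[[nm]] <- switch(d$gene_class[i],
      tRNA = trnas[[nm]]$seq,
      PCG = {
        sp <- cfg$pcg[[nm]]
        if (is.null(sp)) stop("no PCG spec for ", nm)
        build_cds(d$size[i], sp$start, sp$stop, cfg$codon_weights,
                  prefix = overlap_prefix[[nm]])
      },
      rRNA = paste(rand_filler(d$size[i], cfg$target_at$rrna), collapse = ""),
      control_region = {
        cr <- build_control_region(cfg)
        attr(cr$seq, "expected") <- cr$expected
        cr$seq
      })
  }
  cr_name <- d$name[d$gene_class == "control_region"][1]
  cr_expected <- attr(seqs[[cr_name]], "expected")

  genome_v <- rand_filler(L, cfg$target_at$spacer)
  for (i in seq_len(nfeat)) {
    s <- as.character(seqs[[d$name[i]]])
    if (d$strand[i] == "-") s <- revcomp(s)
    genome_v[start[i]:end[i]] <- strsplit(s, "")[[1]]
  }
  for (jp in cfg$junction_plants) {
    if (jp$mode != "spacer") next
    ia <- match(jp$gene_a, d$name)
    motif <- toupper(jp$motif)
    if (d$strand[ia] == "-") motif <- revcomp(motif)
    genome_v[(end[ia] + 1L):(end[ia] + nchar(motif))] <-
      strsplit(motif, "")[[1]]
  }
  genome <- genome_record("synthetic_mitogenome", paste(genome_v, collapse = ""))
  stopifnot(genome$length == L)

  feats <- lapply(seq_len(nfeat), function(i) {
    nm <- d$name[i]
    feature_annotation(nm, d$gene_class[i], d$strand[i], start[i], end[i],
                       anticodon = if (nm %in% names(cfg$anticodons))
                         cfg$anticodons[[nm]] else NA,
                       start_codon = if (nm %in% names(cfg$pcg))
                         cfg$pcg[[nm]]$start else NA,
                       stop_codon = if (nm %in% names(cfg$pcg))
                         cfg$pcg[[nm]]$stop else NA)
  })
  table <- annotation_table(genome$id, L, feats)

  # ---- verification against the intended layout ----
  rows <- build_arrangement(table)
  ord <- match(d$name, rows$name)
  stopifnot(identical(rows$size[ord], d$size),
            identical(rows$ign_next[ord], d$gap_next))

  trna_arms <- list()
  for (nm in d$name[trna_idx]) {
    f <- get_feature(table, nm)
    st <- suppressWarnings(fold_cloverleaf(extract_feature_sequence(genome, f),
                                           expected_anticodon = cfg$anticodons[[nm]]))
    want <- trnas[[nm]]$arms
    layout <- list(acceptor = list(present = want$acceptor$present,
                                   pairs = want$acceptor$pairs),
                   dhu = want$dhu, anticodon_arm = want$anticodon_arm,
                   tpsic = want$tpsic)
    layout <- lapply(layout, function(a)
      if (isTRUE(a$present)) list(present = TRUE, pairs = a$pairs)
      else list(present = FALSE))
    if (!fold_matches_layout(st, layout))
      stop("post-assembly tRNA fold mismatch for ", nm)
    trna_arms[[nm]] <- want
  }

  cr_f <- get_feature(table, cr_name)
  region <- extract_feature_sequence(genome, cr_f)
  stopifnot(isTRUE(all.equal(homopolymer_runs(region, 10L),
                             cr_expected$homopolymers,
                             check.attributes = FALSE)),
            isTRUE(all.equal(microsatellites(region, 2L, 5L),
                             cr_expected$microsatellites,
                             check.attributes = FALSE)),
            isTRUE(all.equal(long_direct_repeats(region, 30L),
                             cr_expected$direct_repeats,
                             check.attributes = FALSE)))

  junctions <- lapply(cfg$junction_plants, function(jp) {
    w <- junction_window(genome, table, jp$gene_a, jp$gene_b, 15L, 15L)
    hits <- motif_scan(list(w), jp$motif, 0L)
    if (nrow(hits) == 0L)
      stop("junction motif ", jp$motif, " not recovered at ",
           jp$gene_a, "/", jp$gene_b)
    list(gene_a = jp$gene_a, gene_b = jp$gene_b, motif = toupper(jp$motif),
         window_position = hits$position[1])
  })

  pcg_names <- d$name[d$gene_class == "PCG"]
  cds <- vapply(pcg_names, function(nm)
    extract_feature_sequence(genome, get_feature(table, nm)), character(1))
  codon_counts <- count_codons(cds)$counts

  class_len <- tapply(d$size, d$gene_class, sum)
  at_frac <- function(s) {
    n <- base_counts(s)
    (n["A"] + n["T"]) / sum(n)
  }
  w <- cfg$codon_weights / sum(cfg$codon_weights)
  at_per_codon <- vapply(names(w), function(cd)
    sum(strsplit(cd, "")[[1]] %in% c("A", "U")) / 3, numeric(1))
  pcg_at <- 100 * sum(w * at_per_codon)
  spacer_len <- L - sum(class_len)
  expected_at <- (class_len[["PCG"]] * pcg_at +
                  class_len[["tRNA"]] * cfg$target_at$trna +
                  class_len[["rRNA"]] * cfg$target_at$rrna +
                  class_len[["control_region"]] * 100 * at_frac(region) +
                  max(spacer_len, 0) * cfg$target_at$spacer) / L

  manifest <- list(
    genome_length = L,
    features = data.frame(name = d$name, gene_class = d$gene_class,
                          strand = d$strand, start = start, end = end,
                          size = d$size, stringsAsFactors = FALSE),
    gaps = stats::setNames(d$gap_next, d$name),
    codon_counts = codon_counts,
    control_region = c(list(start = cr_f$start, end = cr_f$end),
                       cr_expected),
    junctions = junctions,
    trna_arms = trna_arms,
    expected_at = unname(expected_at))
  list(genome = genome, table = table, manifest = manifest)
}

#' Write a simulation to disk
#'
#' Emits FASTA, a GenBank flat file, a Table-2-dialect feature table and
#' the manifest as YAML.
#'
#' @param sim output of [generate_mitogenome()].
#' @param outdir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "genome.fasta"),
    genbank = file.path(outdir, "genome.gb"),
    features = file.path(outdir, "features.tsv"),
    manifest = file.path(outdir, "manifest.yaml"))
  write_fasta(sim$genome, paths["fasta"])
  write_genbank(sim$genome, sim$table, paths["genbank"])
  write_feature_table(sim$table, paths["features"])
  man <- sim$manifest
  man$codon_counts <- as.list(man$codon_counts)
  man$trna_arms <- lapply(man$trna_arms, function(arms)
    lapply(arms, function(a)
      if (isTRUE(a$present)) list(present = TRUE,
                                  p5 = as.integer(a$pairs[, 1]),
                                  p3 = as.integer(a$pairs[, 2]))
      else list(present = FALSE)))
  man$features <- as.list(man$features)
  man$control_region <- lapply(man$control_region, function(x)
    if (is.data.frame(x)) as.list(x) else x)
  yaml::write_yaml(man, paths["manifest"])
  invisible(paths)
}
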