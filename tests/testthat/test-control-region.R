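test_that("homopolymer_runs finds maximal runs only", {
  s <- paste0("AA", strrep("T", 19), "CC")
  h <- homopolymer_runs(s, 10L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit, "T")
  expect_equal(h$length, 19L)
  expect_equal(h$start, 3L)
  expect_equal(nrow(homopolymer_runs("ACGT", 2L)), 0L)
  h5 <- homopolymer_runs(strrep("T", 5), 5L)
  expect_equal(nrow(h5), 1L)   # one maximal run, not sub-runs
  expect_equal(h5$length, 5L)
})

test_that("microsatellites finds maximal arrays and excludes homopolymer units", {
  s <- paste0("CCGG", strrep("TA", 10), "CGCG")
  m <- microsatellites(s, 2L, 5L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$unit, "TA")
  expect_equal(m$unit_canonical, "AT")
  expect_equal(m$copies, 10L)
  expect_equal(m$start, 5L)
  expect_equal(m$length, 20L)
  expect_equal(nrow(microsatellites("TATATA", 2L, 4L)), 0L)
  # a (TT)n is a homopolymer, not a microsatellite
  expect_equal(nrow(microsatellites(strrep("T", 12), 2L, 5L)), 0L)
})

test_that("microsatellite arrays agree with an exhaustive scan oracle", {
  set.seed(21)
  for (i in 1:15) {
    s <- rand_seq(120, p = c(A = .4, C = .1, G = .1, T = .4))
    m <- microsatellites(s, 2L, 3L)
    o <- oracle_microsats(s, 2L, 3L)
    expect_equal(nrow(m), length(o), info = s)
    if (length(o)) {
      expect_equal(m$start, vapply(o, `[[`, integer(1), "start"))
      expect_equal(m$copies, vapply(o, `[[`, integer(1), "copies"))
    }
  }
})

test_that("long_direct_repeats recovers planted repeats and nothing else", {
  set.seed(31)
  seg <- CR_LONG_REPEATS[1]
  filler <- function(n) rand_seq(n, p = c(A = .25, C = .25, G = .25, T = .25))
  s <- paste0(filler(60), seg, filler(80), seg, filler(60))
  r <- long_direct_repeats(s, 30L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit, seg)
  expect_equal(r$length, nchar(seg))
  expect_equal(r$copies, 2L)
  expect_equal(substr(s, r$start, r$start + r$length - 1L), seg)
  expect_equal(substr(s, r$mate_start, r$mate_start + r$length - 1L), seg)

  # random 4-letter string of this length has no >= 30 bp repeat
  s0 <- filler(100)
  expect_equal(nrow(long_direct_repeats(s0, 30L)), 0L)

  # back-to-back duplication of X with min_len = |X|
  x <- filler(40)
  r2 <- long_direct_repeats(paste0(x, x), 40L)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start, 1L)
  expect_equal(r2$mate_start, 41L)
})

test_that("long_direct_repeats agrees with the dictionary oracle", {
  set.seed(41)
  for (i in 1:8) {
    base <- rand_seq(80, p = c(A = .35, C = .15, G = .15, T = .35))
    seg <- substr(base, 10, 10 + sample(12:20, 1))
    s <- paste0(base, rand_seq(40), seg, rand_seq(30))
    got <- long_direct_repeats(s, 12L)
    want <- oracle_direct_repeats(s, 12L)
    expect_equal(nrow(got), length(want), info = s)
    got_units <- sort(got$unit)
    want_units <- sort(vapply(want, `[[`, character(1), "unit"))
    expect_equal(got_units, want_units)
  }
})

test_that("reported features re-extract to their descriptions and are maximal", {
  sim <- get_sim(2)
  cr <- sim$manifest$control_region
  f <- Filter(function(x) x$gene_class == "control_region",
              sim$table$features)[[1]]
  region <- extract_feature_sequence(sim$genome, f)
  h <- homopolymer_runs(region, 10L)
  for (i in seq_len(nrow(h))) {
    run <- substr(region, h$start[i], h$start[i] + h$length[i] - 1L)
    expect_equal(run, strrep(h$unit[i], h$copies[i]))
    # maximality: flanks break the run
    if (h$start[i] > 1)
      expect_false(substr(region, h$start[i] - 1, h$start[i] - 1) == h$unit[i])
    e <- h$start[i] + h$length[i]
    if (e <= nchar(region))
      expect_false(substr(region, e, e) == h$unit[i])
  }
  m <- microsatellites(region, 2L, 5L)
  for (i in seq_len(nrow(m))) {
    arr <- substr(region, m$start[i], m$start[i] + m$length[i] - 1L)
    expect_equal(arr, strrep(m$unit[i], m$copies[i]))
  }
})

test_that("region_report recovers exactly the planted features", {
  sim <- get_sim(1)
  rep <- region_report(sim$genome, sim$table)
  cr <- sim$manifest$control_region
  h <- rep$features[rep$features$kind == "homopolymer", ]
  expect_equal(h$start, cr$homopolymers$start)
  expect_equal(h$length, cr$homopolymers$length)
  expect_equal(h$unit, cr$homopolymers$unit)
  m <- rep$features[rep$features$kind == "microsatellite", ]
  expect_equal(m$start, cr$microsatellites$start)
  expect_equal(m$copies, cr$microsatellites$copies)
  r <- rep$features[rep$features$kind == "direct_repeat", ]
  expect_equal(r$start, cr$direct_repeats$start)
  expect_equal(r$mate_start, cr$direct_repeats$mate_start)
  expect_equal(r$unit, cr$direct_repeats$unit)
  # genome-absolute coordinates offset by the region start
  expect_equal(rep$features$genome_start,
               cr$start + rep$features$start - 1L)
  # composition row: the control region is extremely A+T rich
  expect_gt(rep$composition$pct_at, 85)
})

test_that("region_report errors without a control region; detectors are offset-invariant", {
  g <- genome_record("g", rand_seq(200))
  tab <- annotation_table("g", 200L,
                          list(feature_annotation("p", "PCG", "+", 1, 90)))
  expect_error(region_report(g, tab), "control_region")

  # translation invariance: same region content at two genomic offsets
  region <- paste0(rand_seq(30), strrep("T", 12), rand_seq(30))
  for (pad in c(10L, 50L)) {
    seq <- paste0(rand_seq(pad), region, rand_seq(20))
    gg <- genome_record("g", seq)
    tt <- annotation_table("g", nchar(seq), list(
      feature_annotation("cr", "control_region", "+", pad + 1L,
                         pad + nchar(region))))
    rr <- region_report(gg, tt)
    expect_equal(rr$features$start,
                 homopolymer_runs(region, 10L)$start)
  }
  # a pure ACGT tiling has no features at the default minima
  tile <- strrep("ACGT", 100)
  expect_equal(nrow(homopolymer_runs(tile, 10L)), 0L)
  expect_equal(nrow(microsatellites(tile, 2L, 5L)), 0L)
})
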