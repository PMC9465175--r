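test_that("feature_length matches coordinates, including origin wrap", {
  t2 <- table2_fixture()
  cox1 <- mitoprofile:::get_feature(t2, "cox1")
  expect_equal(feature_length(cox1), 1534L)
  expect_equal(feature_length(feature_annotation("s", "tRNA", "+", 7, 7)), 1L)
  wrapped <- feature_annotation("w", "PCG", "+", 15900, 200)
  # oracle: explicit position enumeration around the circle
  expect_equal(feature_length(wrapped, 16060L),
               length(c(15900:16060, 1:200)))
  expect_equal(feature_length(wrapped, 16060L), 361L)
})

test_that("intergenic_gap is next.start - prev.end - 1 with overlap negated", {
  t2 <- table2_fixture()
  gap <- function(a, b) intergenic_gap(mitoprofile:::get_feature(t2, a),
                                       mitoprofile:::get_feature(t2, b),
                                       16060L)
  # abutting cox2/trnK region boundary printed in the arrangement table
  expect_equal(gap("atp8", "atp6"), -9L)
  expect_equal(gap("trnL1(CUN)", "rrnL"), 0L)
  # overlap magnitude equals the coordinate-set intersection (oracle)
  a <- mitoprofile:::get_feature(t2, "atp8")
  b <- mitoprofile:::get_feature(t2, "atp6")
  expect_equal(-gap("atp8", "atp6"),
               length(intersect(a$start:a$end, b$start:b$end)))
  expect_error(intergenic_gap(a, a, 16060L), "itself")
})

test_that("build_arrangement reproduces the simulator manifest", {
  sim <- get_sim(1)
  rows <- build_arrangement(sim$table)
  m <- sim$manifest
  ord <- match(m$features$name, rows$name)
  expect_equal(rows$size[ord], m$features$size)
  expect_equal(rows$ign_next[ord], unname(m$gaps))
})

test_that("degenerate and tiling arrangements behave", {
  g1 <- annotation_table("g", 100L,
                         list(feature_annotation("a", "PCG", "+", 1, 60)))
  r1 <- build_arrangement(g1)
  expect_true(attr(r1, "degenerate"))
  expect_equal(r1$ign_next, 40L)

  g2 <- annotation_table("g", 100L,
                         list(feature_annotation("a", "PCG", "+", 1, 60),
                              feature_annotation("b", "PCG", "+", 61, 100)))
  r2 <- build_arrangement(g2)
  expect_equal(r2$ign_next, c(0L, 0L))
})

test_that("circumference is conserved: sum(size + ign) == genome length", {
  sim <- get_sim(1)
  rows <- build_arrangement(sim$table)
  expect_equal(sum(rows$size + rows$ign_next), sim$genome$length)
  # and on a random non-overlapping circular arrangement
  set.seed(42)
  starts <- sort(sample(500, 6))
  ends <- starts + c(diff(starts) - sample(0:3, 5, replace = TRUE) - 1, 20)
  feats <- lapply(seq_along(starts), function(i)
    feature_annotation(paste0("f", i), "PCG", "+", starts[i], ends[i]))
  tab <- annotation_table("g", 600L, feats)
  r <- build_arrangement(tab)
  expect_equal(sum(r$size + r$ign_next), 600L)
})

test_that("summarize_arrangement reproduces printed spacer statistics", {
  t2 <- table2_fixture()
  rows <- build_arrangement(t2)
  s <- summarize_arrangement(rows, 16060L, ign_source = "printed",
                             size_source = "printed")
  expect_equal(s$spacer_count, 15L)
  expect_equal(s$spacer_max, 9L)
  expect_equal(s$class_totals[["tRNA"]], 1484L)
  expect_equal(s$class_counts[["tRNA"]], 22L)
  expect_equal(s$class_counts[["PCG"]], 13L)

  sc <- summarize_arrangement(rows, 16060L)  # computed IGN
  pcg_total <- sum(rows$size[rows$gene_class == "PCG"])
  expect_equal(sc$pcg_fraction_of_genome,
               round(100 * pcg_total / 16060, 2))
})

test_that("summarize_arrangement handles all-zero IGN and missing columns", {
  g <- annotation_table("g", 100L,
                        list(feature_annotation("a", "PCG", "+", 1, 60),
                             feature_annotation("b", "PCG", "+", 61, 100)))
  r <- build_arrangement(g)
  s <- summarize_arrangement(r, 100L)
  expect_equal(s$spacer_count, 0L)
  expect_equal(s$overlap_count, 0L)
  expect_error(summarize_arrangement(r, 100L, ign_source = "printed"),
               "printed")
})

test_that("gene_order_signature compares arrangements, not coordinates", {
  f1 <- list(feature_annotation("trnI", "tRNA", "+", 1, 70),
             feature_annotation("nad2", "PCG", "+", 80, 1000),
             feature_annotation("cox1", "PCG", "-", 1010, 2500))
  f2 <- list(feature_annotation("nad2", "PCG", "+", 300, 1200),
             feature_annotation("cox1", "PCG", "-", 1300, 2800),
             feature_annotation("trnI", "tRNA", "+", 2900, 2970))
  t1 <- annotation_table("a", 3000L, f1)
  t2 <- annotation_table("b", 3000L, f2)
  expect_equal(gene_order_signature(t1), gene_order_signature(t2))

  f3 <- list(feature_annotation("trnI", "tRNA", "+", 1, 70),
             feature_annotation("cox1", "PCG", "-", 80, 1000),
             feature_annotation("nad2", "PCG", "+", 1010, 2500))
  t3 <- annotation_table("c", 3000L, f3)
  expect_false(gene_order_signature(t1) == gene_order_signature(t3))

  # anchor absent: lexicographically minimal rotation, still rotation-safe
  t1b <- annotation_table("d", 3000L, f1[c(2, 3, 1)])
  no_anchor <- function(t) gene_order_signature(t, anchor = "absent")
  expect_equal(no_anchor(t1), no_anchor(t1b))
})

test_that("synthetic genome signature equals the template signature", {
  sim <- get_sim(1)
  tmpl <- mitoprofile:::ancestral_template()
  want <- paste(sprintf("%s(%s)", tmpl$name, tmpl$strand), collapse = " ")
  expect_equal(gene_order_signature(sim$table), want)
})
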