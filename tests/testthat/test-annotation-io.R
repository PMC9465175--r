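test_that("read_fasta normalizes case, maps U to T and preserves order", {
  f <- write_tmp_fasta(c(">x", "ACGT", ">y lower", "acgt", ">z rna", "ACGU"))
  recs <- read_fasta(f)
  expect_length(recs, 3L)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("x", "y", "z"))
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[1]]$length, 4L)
  expect_equal(recs[[2]]$seq, "ACGT")
  expect_equal(recs[[3]]$seq, "ACGT")
})

test_that("read_fasta rejects empty files and non-IUPAC characters", {
  f <- write_tmp_fasta(character(0))
  expect_error(read_fasta(f), "empty")
  expect_error(genome_record("bad", "ACXGT"), "position 3")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("feature-table parsing handles dashes, commas and minus signs", {
  t2 <- table2_fixture()
  d <- as.data.frame(t2)
  cox1 <- d[d$name == "cox1", ]
  expect_equal(cox1$start, 1392L)
  expect_equal(cox1$end, 2925L)
  cr <- d[d$name == "A+T-rich region", ]
  expect_equal(cr$start, 14596L)
  expect_equal(cr$end, 16060L)
  expect_equal(cr$gene_class, "control_region")
  # printed IGN column retained verbatim, Unicode minus parsed
  expect_equal(d$ign_printed[d$name == "trnI"], -4L)
  expect_equal(d$ign_printed[d$name == "trnL1(CUN)"], -31L)
  expect_true(is.na(d$ign_printed[d$name == "A+T-rich region"]))
})

test_that("feature-table dialects map strands correctly", {
  # table2 dialect: dash = heavy (plus) strand, '+' = light (minus)
  d <- as.data.frame(table2_fixture())
  expect_equal(d$strand[d$name == "cox1"], "+")
  expect_equal(d$strand[d$name == "nad5"], "-")
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("Gene", "Direction", "Location", sep = "\t"),
               paste("g1", "+", "5-5", sep = "\t"),
               paste("g2", "-", "10-20", sep = "\t")), f)
  t <- read_feature_table(f, 100L)
  d2 <- as.data.frame(t)
  expect_equal(d2$strand, c("+", "-"))
  expect_equal(d2$start[1], 5L)
  expect_equal(d2$end[1], 5L)
})

test_that("feature-table errors name the offending row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("Gene", "Direction", "Location", sep = "\t"),
               paste("gX", "+", "abc", sep = "\t")), f)
  expect_error(read_feature_table(f, 100L), "gX")
  writeLines(c(paste("Gene", "Direction", "Location", sep = "\t"),
               paste("g1", "+", "1-5", sep = "\t"),
               paste("g1", "+", "6-9", sep = "\t")), f)
  expect_error(read_feature_table(f, 100L), "duplicate")
})

test_that("feature table write/read round-trips bit-exactly", {
  t2 <- table2_fixture()
  f <- tempfile(fileext = ".tsv")
  write_feature_table(t2, f, dialect = "table2")
  back <- read_feature_table(f, 16060L, genome_id = t2$genome_id)
  expect_equal(as.data.frame(back)[c("name", "strand", "start", "end")],
               as.data.frame(t2)[c("name", "strand", "start", "end")])
  expect_identical(back$ign, t2$ign)
  expect_identical(back$size_printed, t2$size_printed)
})

test_that("extract_feature_sequence honours strand and circular wrap", {
  g <- genome_record("g", "AACGTT")
  plus <- feature_annotation("p", "PCG", "+", 2, 4)
  minus <- feature_annotation("m", "PCG", "-", 2, 4)
  expect_equal(extract_feature_sequence(g, plus), "ACG")
  expect_equal(extract_feature_sequence(g, minus), "CGT")
  wrap <- feature_annotation("w", "PCG", "+", 5, 2)
  expect_equal(extract_feature_sequence(g, wrap), "TTAA")
  lin <- genome_record("l", "AACGTT", circular = FALSE)
  expect_error(extract_feature_sequence(lin, wrap), "circular")
})

test_that("minus-strand extraction is the reverse complement of plus", {
  set.seed(11)
  g <- genome_record("g", rand_seq(300))
  for (i in 1:20) {
    s <- sample(250, 1)
    e <- s + sample(40, 1)
    p <- feature_annotation("p", "PCG", "+", s, e)
    m <- feature_annotation("m", "PCG", "-", s, e)
    expect_equal(extract_feature_sequence(g, m),
                 oracle_revcomp(extract_feature_sequence(g, p)))
    expect_equal(nchar(extract_feature_sequence(g, p)), e - s + 1L)
  }
})

test_that("GenBank writer round-trips through the reader", {
  sim <- get_sim(1)
  f <- tempfile(fileext = ".gb")
  write_genbank(sim$genome, sim$table, f)
  back <- read_genbank(f)
  expect_equal(back$genome$seq, sim$genome$seq)
  expect_true(back$genome$circular)
  a <- as.data.frame(back$table)
  b <- as.data.frame(sim$table)
  expect_equal(a[c("name", "gene_class", "strand", "start", "end")],
               b[c("name", "gene_class", "strand", "start", "end")])
})

test_that("GenBank reader handles complement, origin-spanning join and errors", {
  f <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       tiny 40 bp    DNA     circular   INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     tRNA            complement(1..20)",
    '                     /gene="trnX"',
    "     CDS             join(35..40,1..6)",
    '                     /gene="wrapped"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//"), f)
  gb <- read_genbank(f)
  d <- as.data.frame(gb$table)
  expect_equal(d$strand[d$name == "trnX"], "-")
  expect_equal(d$start[d$name == "trnX"], 1L)
  expect_equal(d$end[d$name == "trnX"], 20L)
  w <- d[d$name == "wrapped", ]
  expect_equal(w$start, 35L)
  expect_equal(w$end, 6L)

  writeLines(c("LOCUS       x 10 bp DNA linear", "FEATURES",
               "     CDS             1..6", '                     /gene="g"'),
             f)
  expect_error(read_genbank(f), "ORIGIN")
})
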