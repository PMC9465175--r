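test_that("folding recovers all planted arm boundaries (manifest match)", {
  for (s in 1:2) {
    sim <- get_sim(s)
    trnas <- Filter(function(f) f$gene_class == "tRNA", sim$table$features)
    for (f in trnas) {
      st <- fold_cloverleaf(extract_feature_sequence(sim$genome, f),
                            expected_anticodon = f$anticodon)
      expect_true(compare_arms(st, sim$manifest$trna_arms[[f$name]]),
                  info = paste("seed", s, f$name))
    }
  }
})

test_that("T-arm-deleted tRNAs fold with tpsic absent, other arms present", {
  sim <- get_sim(1)
  folds <- fold_all(sim$genome, sim$table)
  rep <- folds$report
  expect_equal(sort(rep$gene[!rep$tpsic]), sort(c("trnF", "trnH", "trnM")))
  expect_true(all(rep$acceptor))
  expect_true(all(rep$dhu))
  expect_true(all(rep$anticodon_arm))
  expect_equal(unname(folds$missing_arm_counts["tpsic"]), 3L)
  # anticodon read from the loop equals the annotation
  acs <- mitoprofile:::default_anticodons()
  expect_equal(rep$anticodon, unname(acs[rep$gene]))
})

test_that("a stemless sequence yields no arms", {
  st <- suppressWarnings(fold_cloverleaf(strrep("A", 70)))
  expect_false(st$acceptor$present)
  expect_false(st$dhu$present)
  expect_false(st$anticodon_arm$present)
  expect_false(st$tpsic$present)
  expect_equal(st$diagnostic, "no anticodon arm candidate")
})

test_that("folding is deterministic and position-independent", {
  sim <- get_sim(1)
  f <- Filter(function(x) x$gene_class == "tRNA", sim$table$features)[[1]]
  seq <- extract_feature_sequence(sim$genome, f)
  a <- fold_cloverleaf(seq, f$anticodon)
  b <- fold_cloverleaf(seq, f$anticodon)
  expect_identical(a, b)
  expect_identical(dot_bracket(a), dot_bracket(b))
})

test_that("classify_pairs labels WC, G-U wobble and mismatches", {
  sim <- get_sim(1)
  f <- Filter(function(x) x$gene_class == "tRNA" &&
                !(x$name %in% c("trnH", "trnM", "trnF")),
              sim$table$features)[[1]]
  seq <- extract_feature_sequence(sim$genome, f)
  st <- fold_cloverleaf(seq, f$anticodon)
  cp <- classify_pairs(st)
  n_pairs <- nrow(mitoprofile:::structure_pairs(st))
  expect_equal(sum(cp$counts), n_pairs)
  expect_equal(cp$counts[["mismatch"]], nrow(cp$mismatch_list))

  # mutate one acceptor-stem base: G opposite T becomes a wobble,
  # T opposite T a mismatch (classification is over the supplied sequence)
  p <- st$acceptor$pairs[1, ]
  b <- strsplit(seq, "")[[1]]
  b3 <- b[p["p3"]]
  mut <- b
  mut[p["p5"]] <- if (b3 %in% c("T", "G")) c(T = "G", G = "T")[[b3]] else "X"
  if (mut[p["p5"]] != "X") {
    cpw <- classify_pairs(st, paste(mut, collapse = ""))
    expect_equal(sum(cpw$counts), n_pairs)
    expect_gte(cpw$counts[["gu_wobble"]], 1L)
  }
  mut2 <- b
  mut2[p["p5"]] <- b3   # X-X can never pair
  cpm <- classify_pairs(st, paste(mut2, collapse = ""))
  expect_gte(cpm$counts[["mismatch"]], 1L)
  listed <- cpm$mismatch_list
  expect_true(any(listed$pos5 == p[["p5"]] & listed$pos3 == p[["p3"]]))
  expect_equal(nrow(listed), cpm$counts[["mismatch"]])
})

test_that("pair classification matches the base alphabet exactly", {
  expect_equal(mitoprofile:::pair_class("G", "T"), "gu_wobble")
  expect_equal(mitoprofile:::pair_class("T", "G"), "gu_wobble")
  expect_equal(mitoprofile:::pair_class("T", "T"), "mismatch")
  expect_equal(mitoprofile:::pair_class("A", "T"), "watson_crick")
  expect_equal(mitoprofile:::pair_class("C", "G"), "watson_crick")
  expect_equal(mitoprofile:::pair_class("A", "G"), "mismatch")
})

test_that("fold_all requires annotated tRNAs and reports one row per gene", {
  sim <- get_sim(1)
  folds <- fold_all(sim$genome, sim$table)
  expect_equal(nrow(folds$report), 22L)
  expect_equal(length(folds$structures), 22L)
  g <- genome_record("g", rand_seq(500))
  tab <- annotation_table("g", 500L,
                          list(feature_annotation("p", "PCG", "+", 1, 90)))
  expect_error(fold_all(g, tab), "tRNA")
})

test_that("arm recovery holds across many seeded tRNAs", {
  # 22 tRNAs x seeds 1-10; at least 95% of arms must be recovered
  total <- 0L
  good <- 0L
  for (s in 1:10) {
    sim <- if (s <= 5) get_sim(s)
           else generate_mitogenome(simulation_config(seed = s))
    trnas <- Filter(function(f) f$gene_class == "tRNA", sim$table$features)
    for (f in trnas) {
      st <- fold_cloverleaf(extract_feature_sequence(sim$genome, f),
                            expected_anticodon = f$anticodon)
      man <- sim$manifest$trna_arms[[f$name]]
      for (a in c("acceptor", "dhu", "anticodon_arm", "tpsic")) {
        total <- total + 1L
        ok <- identical(isTRUE(man[[a]]$present), isTRUE(st[[a]]$present)) &&
          (!isTRUE(man[[a]]$present) ||
             (identical(unname(man[[a]]$pairs[, 1]),
                        unname(st[[a]]$pairs[, "p5"])) &&
              identical(unname(man[[a]]$pairs[, 2]),
                        unname(st[[a]]$pairs[, "p3"]))))
        if (ok) good <- good + 1L
      }
    }
  }
  expect_gte(good / total, 0.95)
})

test_that("dot-bracket strings are balanced and match stem pair counts", {
  sim <- get_sim(1)
  folds <- fold_all(sim$genome, sim$table)
  for (g in names(folds$structures)) {
    st <- folds$structures[[g]]
    db <- dot_bracket(st)
    expect_equal(nchar(db), st$n)
    n_open <- lengths(regmatches(db, gregexpr("(", db, fixed = TRUE)))
    n_close <- lengths(regmatches(db, gregexpr(")", db, fixed = TRUE)))
    expect_equal(n_open, n_close)
    expect_equal(unname(n_open), nrow(mitoprofile:::structure_pairs(st)))
  }
})
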