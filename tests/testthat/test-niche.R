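test_that("occupancy and abundance summaries follow the definitions", {
  # rows: OTU_1 counts (10, 0, 5); OTU_2 absent; OTU_3 fills the columns
  m <- toy_counts(3, 3, c(10, 0, 5, 0, 0, 0, 240, 100, 95))
  ot <- otu_table(m, toy_env(m))
  oa <- occupancy_abundance(ot, "drainage")
  expect_identical(oa$occupancy, c(2L, 0L, 3L))
  expect_equal(oa$mean_all[2], 0)
  expect_equal(oa$mean_occupied[2], 0)
  # relative abundances of OTU_1: 10/250, 0, 5/100
  expect_equal(oa$mean_occupied[1], mean(c(10 / 250, 5 / 100)))
  expect_equal(oa$mean_all[1], mean(c(10 / 250, 0, 5 / 100)))
  expect_equal(oa$max_ra[1], 5 / 100)
  expect_error(occupancy_abundance(ot, "bog"), "unknown environment")
})

test_that("the 2% occupancy-abundance rule labels generalists and specialists", {
  # six samples; OTU_1 everywhere at 5%; OTU_2 in two samples at 10%;
  # OTU_3 everywhere but rare; OTU_4 fills the remainder
  n <- 6
  m <- rbind(OTU_1 = rep(50, n),
             OTU_2 = c(100, 100, 0, 0, 0, 0),
             OTU_3 = rep(5, n),
             OTU_4 = c(845, 845, 945, 945, 945, 945))
  colnames(m) <- paste0("D", 1:n)
  ot <- otu_table(m, stats::setNames(rep("drainage", n), colnames(m)))
  nc <- classify_otus(ot, "drainage")
  lab <- stats::setNames(nc$label, nc$otu_id)
  expect_identical(unname(lab[c("OTU_1", "OTU_2", "OTU_3")]),
                   c("generalist", "specialist", "other"))
  expect_identical(unname(lab["OTU_4"]), "generalist")

  # under basis = "all", the 2-sample specialist at 10% still passes
  nc_all <- classify_otus(ot, "drainage", abundance_basis = "all")
  expect_identical(nc_all$label[nc_all$otu_id == "OTU_2"], "specialist")

  # threshold boundary counts as passing (>=)
  m2 <- rbind(OTU_1 = rep(2, 3), OTU_2 = rep(98, 3))
  colnames(m2) <- paste0("D", 1:3)
  ot2 <- otu_table(m2, stats::setNames(rep("drainage", 3), colnames(m2)))
  nc2 <- classify_otus(ot2, "drainage", threshold = 0.02)
  expect_identical(nc2$label[nc2$otu_id == "OTU_1"], "generalist")

  expect_error(classify_otus(ot, "drainage", threshold = 0), "threshold")
  expect_error(classify_otus(ot, "drainage", threshold = 1.2), "threshold")
})

test_that("classification is depth-invariant and monotone in the threshold", {
  set.seed(21)
  ot <- random_otu_table(60, 6)
  nc <- classify_otus(ot, "drainage", threshold = 0.01)
  # rescale depths per sample: labels unchanged
  m2 <- sweep(ot$counts, 2, c(3L, 1L, 7L, 2L, 5L, 4L), "*")
  ot2 <- otu_table(m2, ot$environment)
  nc2 <- classify_otus(ot2, "drainage", threshold = 0.01)
  expect_identical(nc$label, nc2$label)

  # raising the threshold never adds a generalist or specialist
  for (th in c(0.02, 0.05, 0.1)) {
    hi <- classify_otus(ot, "drainage", threshold = th)
    was <- nc$label != "other"
    expect_true(all(hi$label[!was] == "other"))
  }
})

test_that("core microbiota equals the brute-force no-zero-row scan", {
  ot <- toy_otu_table(c(1, 1, 1, 1, 1, 1,
                        5, 0, 3, 2, 8, 1,
                        2, 2, 2, 2, 2, 2), 3, 6)
  core <- core_microbiota(ot, "drainage")
  expect_identical(core$otu_ids, c("OTU_1", "OTU_3"))
  expect_identical(unname(core$totals), c(6, 12))

  set.seed(22)
  for (rep in 1:20) {
    ot <- random_otu_table(50, 6, lambda = 2)
    core <- core_microbiota(ot, "drainage")
    brute <- rownames(ot$counts)[apply(ot$counts > 0, 1, all)]
    expect_identical(core$otu_ids, brute)
  }
})

test_that("generalists are always core members", {
  set.seed(23)
  for (rep in 1:20) {
    ot <- random_otu_table(80, 6, lambda = 1)
    nc <- classify_otus(ot, "drainage")
    core <- core_microbiota(ot, "drainage")
    gen <- nc$otu_id[nc$label == "generalist"]
    expect_true(all(gen %in% core$otu_ids))
  }
})

test_that("core composition shares sum to 100 and follow the counts", {
  m <- rbind(OTU_1 = c(10, 10, 10), OTU_2 = c(20, 25, 25), OTU_3 = c(0, 5, 5))
  colnames(m) <- paste0("D", 1:3)
  ot <- otu_table(m, stats::setNames(rep("drainage", 3), colnames(m)))
  tax <- data.frame(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                    genus = c("GenusA", "GenusB", "GenusC"),
                    stringsAsFactors = FALSE)
  core <- core_microbiota(ot, "drainage")
  comp <- core_composition(ot, core, tax)
  expect_equal(sum(comp$share_pct), 100, tolerance = 1e-6)
  expect_equal(comp$share_pct[comp$taxon == "GenusB"], 70)
  expect_equal(comp$share_pct[comp$taxon == "GenusA"], 30)

  # single-taxon core and unclassified binning
  tax1 <- data.frame(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                     genus = c("GenusA", "GenusA", NA), stringsAsFactors = FALSE)
  comp1 <- core_composition(ot, core, tax1)
  expect_identical(comp1$taxon, "GenusA")
  expect_equal(comp1$share_pct, 100)

  tax2 <- data.frame(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                     genus = c(NA, "GenusB", NA), stringsAsFactors = FALSE)
  comp2 <- core_composition(ot, core, tax2)
  expect_true("unclassified" %in% comp2$taxon)

  core$otu_ids <- character(0); core$n_core <- 0L
  expect_error(core_composition(ot, core, tax), "empty")
})

test_that("planted labels are recovered exactly on noise-free communities", {
  cfg <- community_config(seed = 31)
  sim <- generate_community(cfg)
  counts <- round(sim$truth$expected_ra * 1e7)
  storage.mode(counts) <- "integer"
  ot <- otu_table(counts, sim$otu$environment)
  for (env in c("drainage", "soil")) {
    nc <- classify_otus(ot, env)
    truth <- sim$truth$labels[sim$truth$labels$environment == env, ]
    expect_identical(nc$label[match(truth$otu_id, nc$otu_id)], truth$label)
    core <- core_microbiota(ot, env)
    expect_identical(core$otu_ids, sim$truth$core[[env]])
  }
})
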