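test_that("generation is deterministic given config and seed", {
  cfg <- community_config(seed = 5)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$otu$counts, b$otu$counts)
  expect_identical(unclass(a$chemistry), unclass(b$chemistry))
  expect_identical(a$truth$labels, b$truth$labels)
  c2 <- generate_community(cfg, seed = 6)
  expect_false(identical(a$otu$counts, c2$otu$counts))

  np1 <- generate_null_pair(null_config(), seed = 1)
  np2 <- generate_null_pair(null_config(), seed = 1)
  expect_identical(np1$otu$counts, np2$otu$counts)
})

test_that("column sums equal the drawn depths and structure is planted", {
  cfg <- community_config(depth_cv = 0, depth_mean = 5000, seed = 8)
  sim <- generate_community(cfg)
  expect_true(all(colSums(sim$otu$counts) == 5000))
  # expected relative abundances are a proper composition
  expect_lt(max(abs(colSums(sim$truth$expected_ra) - 1)), 1e-9)

  # specialists have zero counts outside their designated samples
  spec <- sim$truth$labels[sim$truth$labels$label == "specialist", ]
  for (i in seq_len(nrow(spec))) {
    sid <- spec$otu_id[i]
    sites <- sim$truth$specialist_sites[[sid]]
    other <- setdiff(colnames(sim$otu$counts), sites)
    expect_true(all(sim$otu$counts[sid, other] == 0))
    expect_true(all(sim$otu$counts[sid, sites] > 0))
  }

  # planted expectations respect the margins around the threshold
  E <- sim$truth$expected_ra
  for (env in cfg$environments) {
    cols <- names(sim$otu$environment)[sim$otu$environment == env]
    lab <- sim$truth$labels[sim$truth$labels$environment == env, ]
    gens <- lab$otu_id[lab$label == "generalist"]
    occ_mean <- function(id) {
      v <- E[id, cols]; mean(v[v > 0])
    }
    for (g in gens) expect_gte(occ_mean(g), 0.03)
    others <- setdiff(lab$otu_id[lab$label == "other"], unlist(sim$truth$core))
    present <- others[rowSums(E[others, cols, drop = FALSE]) > 0]
    expect_true(all(vapply(present, occ_mean, numeric(1)) <= 0.01 + 1e-12))
  }
})

test_that("planted generalists land in the configured abundance band", {
  cfg <- community_config(environments = "drainage", n_samples = 6,
                          n_otus = 150, depth_mean = 1e5, depth_cv = 0,
                          n_generalists = c(drainage = 1),
                          n_specialists = c(drainage = 0),
                          n_core_background = c(drainage = 10),
                          generalist_ra = 0.10,
                          dominant_core_share = NULL,
                          associations = data.frame(environment = character(),
                                                    role = character(),
                                                    index = integer(),
                                                    parameter = character(),
                                                    rho = numeric()))
  means <- vapply(1:20, function(i) {
    sim <- generate_community(cfg, seed = 100 + i)
    gid <- sim$truth$labels$otu_id[sim$truth$labels$label == "generalist"]
    ra <- to_relative_abundance(sim$otu)[gid, ]
    expect_true(all(sim$otu$counts[gid, ] > 0))
    mean(ra)
  }, numeric(1))
  expect_true(all(means >= 0.08 & means <= 0.12))
})

test_that("infeasible configurations are rejected before sampling", {
  expect_error(community_config(generalist_ra = 0.025),
               "below threshold margin")
  expect_error(community_config(core_background_ra = 0.015),
               "above background margin")
  expect_error(community_config(n_otus = 30), "too small")
  expect_error(community_config(n_samples = 2), ">= 3 samples")
  expect_error(community_config(generalist_ra = 0.4,
                                n_generalists = 3,
                                dominant_core_share = NULL),
               "infeasible")
  bad_assoc <- data.frame(environment = "drainage", role = "generalist",
                          index = 5L, parameter = "sulfur", rho = 0.9,
                          stringsAsFactors = FALSE)
  cfg <- community_config(associations = bad_assoc)
  expect_error(generate_community(cfg, seed = 1), "exceeds")
})

test_that("chemistry associations hit the target Spearman in expectation", {
  # small-scale calibration check; the full-size one is in the acceptance suite
  assoc <- data.frame(environment = "drainage", role = "generalist",
                      index = 1L, parameter = "sulfur", rho = 0.9,
                      stringsAsFactors = FALSE)
  cfg <- community_config(environments = "drainage", n_samples = 40,
                          n_otus = 200, depth_mean = 1e4, depth_cv = 0,
                          n_generalists = c(drainage = 1),
                          n_specialists = c(drainage = 0),
                          n_core_background = c(drainage = 10),
                          dominant_core_share = NULL, associations = assoc)
  rhos <- vapply(1:40, function(i) {
    sim <- generate_community(cfg, seed = 400 + i)
    otu <- sim$truth$associations$otu_id[1]
    cor(to_relative_abundance(sim$otu)[otu, ],
        unclass(sim$chemistry)[, "sulfur"], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.9), 0.07)
})

test_that("the null process plants nothing and keeps the regime flag", {
  np <- generate_null_pair(null_config(), seed = 2)
  expect_identical(np$truth$regime, "null_process")
  expect_true(all(np$truth$labels$label == "other"))
  expect_true(all(colSums(np$otu$counts) == 1e4))
  # every sample shares the same expectation vector
  E <- np$truth$expected_ra
  expect_true(all(apply(E, 1, function(r) max(r) - min(r)) == 0))
})

test_that("overdispersion adds a Dirichlet layer without breaking depths", {
  cfg <- community_config(overdispersion = 0.05, depth_cv = 0, seed = 77)
  sim <- generate_community(cfg)
  expect_true(all(colSums(sim$otu$counts) == cfg$depth_mean))
  # zero expectation still forces zero counts under overdispersion
  spec <- sim$truth$labels[sim$truth$labels$label == "specialist", ]
  if (nrow(spec)) {
    sid <- spec$otu_id[1]
    zero_cols <- colnames(sim$truth$expected_ra)[sim$truth$expected_ra[sid, ] == 0]
    expect_true(all(sim$otu$counts[sid, zero_cols] == 0))
  }
})
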