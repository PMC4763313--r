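test_that("Bray-Curtis matches the formula on fixed cases", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  rownames(m) <- paste0("o", 1:3)
  expect_equal(bray_curtis(m)["a", "b"], 0)
  m <- cbind(a = c(1, 0), b = c(0, 1)); rownames(m) <- c("o1", "o2")
  expect_equal(bray_curtis(m)["a", "b"], 1)
  m <- cbind(a = c(0.5, 0.5, 0), b = c(0.25, 0.25, 0.5))
  rownames(m) <- paste0("o", 1:3)
  expect_equal(bray_curtis(m)["a", "b"], 0.5)
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("Bray-Curtis agrees with a naive double-loop oracle and vegan", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(rpois(40, 6) + (runif(40) < 0.2), 5, 8,
                dimnames = list(paste0("o", 1:5), paste0("s", 1:8)))
    m[, colSums(m) == 0] <- 1
    d <- bray_curtis(m, on = "counts")
    expect_lt(max(abs(d - bray_oracle(m))), 1e-12)
    expect_lt(max(abs(d - as.matrix(vegan::vegdist(t(m), "bray")))), 1e-12)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0) && all(d >= 0) && all(d <= 1))
  }
})

test_that("PCoA embeds semimetric distances exactly (real minus imaginary)", {
  # two-point closed form
  d0 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  o <- pcoa(d0)
  expect_equal(o$eigenvalues[1], 0.18)
  expect_equal(sort(o$points_real[, 1]), c(-0.3, 0.3), ignore_attr = TRUE)
  expect_identical(ncol(o$points_imag), 0L)

  # points on a line: Euclidean distances are recovered up to sign/shift
  x <- c(0, 1, 3, 6)
  d1 <- as.matrix(dist(x)); dimnames(d1) <- list(paste0("p", 1:4), paste0("p", 1:4))
  o1 <- pcoa(d1)
  expect_identical(ncol(o1$points_real), 1L)
  expect_equal(as.matrix(dist(o1$points_real)), d1, ignore_attr = TRUE,
               tolerance = 1e-10)

  # random Bray-Curtis: reconstruction oracle
  set.seed(12)
  for (rep in 1:10) {
    ot <- random_otu_table(20, 7)
    d <- bray_curtis(ot)
    o <- pcoa(d)
    rec <- as.matrix(dist(o$points_real))^2
    if (ncol(o$points_imag)) rec <- rec - as.matrix(dist(o$points_imag))^2
    expect_lt(max(abs(unclass(d)^2 - rec)), 1e-6)
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dispersion distances reduce to Euclidean distance-to-mean", {
  set.seed(13)
  pts <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(dist(pts))
  g <- stats::setNames(rep(c("a", "b"), each = 4), rownames(pts))
  z <- dispersion_distances(pcoa(d), g)
  oracle <- vapply(rownames(pts), function(i) {
    ctr <- colMeans(pts[names(g)[g == g[i]], , drop = FALSE])
    sqrt(sum((pts[i, ] - ctr)^2))
  }, numeric(1))
  expect_equal(unclass(z), oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(attr(z, "n_clamped"), 0L)

  # hand-computed two groups of 3 in the plane
  pts2 <- rbind(c(0, 0), c(2, 0), c(1, 3), c(10, 0), c(12, 0), c(11, 3))
  rownames(pts2) <- paste0("q", 1:6)
  d2 <- as.matrix(dist(pts2))
  g2 <- stats::setNames(rep(c("L", "R"), each = 3), rownames(pts2))
  z2 <- dispersion_distances(pcoa(d2), g2)
  # centroids (1,1) and (11,1); distances sqrt(2), sqrt(2), 2 per group
  expect_equal(as.numeric(z2), rep(c(sqrt(2), sqrt(2), 2), 2),
               tolerance = 1e-8)

  # coincident points -> all zero
  dz <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  z3 <- dispersion_distances(pcoa(dz), stats::setNames(rep(c("a", "b"), 2),
                                                       paste0("s", 1:4)))
  expect_equal(as.numeric(z3), rep(0, 4))

  expect_error(dispersion_distances(pcoa(d2),
                                    stats::setNames(c("a", rep("b", 5)),
                                                    rownames(pts2))),
               "singleton")
})

test_that("PERMDISP F equals the ANOVA oracle and vegan::betadisper", {
  skip_if_not_installed("vegan")
  set.seed(14)
  for (rep in 1:5) {
    pts <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
    pts[7:12, ] <- pts[7:12, ] * 2
    d <- as.matrix(dist(pts))
    g <- stats::setNames(rep(c("a", "b"), each = 6), rownames(pts))
    pd <- permdisp(d, g, n_permutations = 19, seed = 1)
    # independently coded oracle: brute-force distances to group means + lm
    z <- vapply(rownames(pts), function(i) {
      ctr <- colMeans(pts[names(g)[g == g[i]], , drop = FALSE])
      sqrt(sum((pts[i, ] - ctr)^2))
    }, numeric(1))
    f_oracle <- anova(lm(z ~ factor(g)))$`F value`[1]
    expect_equal(pd$F, f_oracle, tolerance = 1e-8)
    bd <- vegan::betadisper(as.dist(d), factor(g), type = "centroid")
    expect_equal(pd$F, anova(bd)$`F value`[1], tolerance = 1e-8)
  }
  # Bray-Curtis (semimetric) case against betadisper too
  ot <- random_otu_table(30, 10)
  d <- bray_curtis(ot)
  g <- stats::setNames(rep(c("a", "b"), each = 5), colnames(ot$counts))
  pd <- permdisp(d, g, n_permutations = 19, seed = 2)
  bd <- vegan::betadisper(as.dist(unclass(d)), factor(g), type = "centroid")
  expect_equal(pd$F, anova(bd)$`F value`[1], tolerance = 1e-8)
})

test_that("PERMDISP p-values are reproducible, valid and powered", {
  set.seed(15)
  pts <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  d <- as.matrix(dist(pts))
  g <- stats::setNames(rep(c("a", "b"), each = 10), rownames(pts))
  p1 <- permdisp(d, g, n_permutations = 99, seed = 42)
  p2 <- permdisp(d, g, n_permutations = 99, seed = 42)
  expect_identical(p1$p, p2$p)
  expect_true(p1$p > 0 && p1$p <= 1)
  expect_lt(abs(p1$p * 100 - round(p1$p * 100)), 1e-9)  # resolution 1/(n_perm+1)
  expect_error(permdisp(d, g, n_permutations = 0), "n_permutations")

  # power: one cloud scaled x5, n = 10 per group (reduced replication here;
  # the full-size run lives in the acceptance suite)
  rej <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30, sd = 5), 10, 3)
    pts <- rbind(a, b); rownames(pts) <- paste0("s", 1:20)
    permdisp(as.matrix(dist(pts)), g, n_permutations = 99,
             seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("null model preserves depths, pools abundances and is deterministic", {
  set.seed(16)
  ot <- random_otu_table(50, 6)
  nulls <- null_model_communities(ot, 5, seed = 3)
  for (nu in nulls)
    expect_identical(unname(colSums(nu$counts)), unname(colSums(ot$counts)))
  nulls2 <- null_model_communities(ot, 5, seed = 3)
  expect_identical(lapply(nulls, `[[`, "counts"), lapply(nulls2, `[[`, "counts"))

  # expected relative abundance of each OTU equals the pooled regional value,
  # within 3 binomial standard errors over many replicates
  regional <- rowSums(ot$counts) / sum(ot$counts)
  reps <- null_model_communities(ot, 400, seed = 9)
  depth_total <- sum(ot$counts)
  emp <- Reduce(`+`, lapply(reps, function(x) rowSums(x$counts))) / (400 * depth_total)
  se <- sqrt(regional * (1 - regional) / (400 * depth_total))
  expect_true(all(abs(emp - regional) <= 3 * se + 1e-12))
  expect_error(null_model_communities(ot, 0), "n_null")
})

test_that("stochasticity test is deterministic and degenerates sensibly", {
  set.seed(17)
  np <- generate_null_pair(null_config(), seed = 5)
  s1 <- stochasticity_test(np$otu, n_null = 4, n_permutations = 49, seed = 11)
  s2 <- stochasticity_test(np$otu, n_null = 4, n_permutations = 49, seed = 11)
  expect_identical(s1$permdisp$F, s2$permdisp$F)
  expect_identical(s1$permdisp$p, s2$permdisp$p)
  expect_identical(s1$verdict,
                   if (s1$permdisp$p >= 0.05) "consistent_with_stochastic"
                   else "deterministic_signal")

  # strong planted structure is detected (specialists drive dispersion)
  cfg <- community_config(environments = "drainage", n_samples = 6,
                          n_otus = 150, depth_mean = 1e4, depth_cv = 0,
                          n_generalists = c(drainage = 2),
                          n_specialists = c(drainage = 3),
                          n_core_background = c(drainage = 10),
                          specialist_ra = 0.2,
                          dominant_core_share = NULL,
                          associations = data.frame(environment = character(),
                                                    role = character(),
                                                    index = integer(),
                                                    parameter = character(),
                                                    rho = numeric()))
  rej <- vapply(1:20, function(i) {
    sim <- generate_community(cfg, seed = 300 + i)
    stochasticity_test(sim$otu, n_null = 6, n_permutations = 99,
                       seed = i)$permdisp$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
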