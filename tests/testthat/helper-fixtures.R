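# shared fixtures, all built in code

toy_counts <- function(nr = 3, nc = 2, values = NULL) {
  m <- if (is.null(values)) matrix(seq_len(nr * nc), nr, nc)
       else matrix(values, nr, nc, byrow = TRUE)
  dimnames(m) <- list(sprintf("OTU_%d", seq_len(nr)), sprintf("S%d", seq_len(nc)))
  m
}

toy_env <- function(m, env = "drainage") {
  stats::setNames(rep_len(env, ncol(m)), colnames(m))
}

toy_otu_table <- function(values, nr, nc, env = "drainage") {
  m <- toy_counts(nr, nc, values)
  otu_table(m, toy_env(m, env))
}

random_otu_table <- function(n_otu, n_samp, env = "drainage", lambda = 10) {
  m <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
              dimnames = list(sprintf("OTU_%d", seq_len(n_otu)),
                              sprintf("S%d", seq_len(n_samp))))
  m[, colSums(m) == 0][1] <- 1L  # guard against all-zero samples
  otu_table(m, toy_env(m, env))
}

# naive double-loop Bray-Curtis oracle: 1 - 2*sum(min)/sum(x+y), per element
bray_oracle <- function(v) {
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    num <- 0; den <- 0
    for (i in seq_len(nrow(v))) {
      num <- num + min(v[i, j], v[i, k])
      den <- den + v[i, j] + v[i, k]
    }
    d[j, k] <- 1 - 2 * num / den
  }
  d
}

# a community_config with no planted structure, used for null-regime fixtures
null_config <- function(n_samples = 6, n_otus = 200, depth = 1e4) {
  community_config(environments = "pooled", n_samples = n_samples,
                   n_otus = n_otus, depth_mean = depth, depth_cv = 0,
                   n_generalists = 0, n_specialists = 0,
                   n_core_background = 0, dominant_core_share = NULL,
                   associations = data.frame(environment = character(),
                                             role = character(),
                                             index = integer(),
                                             parameter = character(),
                                             rho = numeric()))
}

# independent full-enumeration Spearman oracle using the d^2 formula
# (valid without ties) and recursive permutation generation distinct from
# the implementation's cache
spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  stopifnot(!anyDuplicated(rx), !anyDuplicated(ry))
  rho_d2 <- function(a, b) 1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
  obs <- rho_d2(rx, ry)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(perm_rec(ry), function(p) rho_d2(rx, p), numeric(1))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

expect_tsv_roundtrip_dir <- function() {
  withr::local_tempdir()
}
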