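#' Bray-Curtis dissimilarity between samples
#'
#' For two samples with values \eqn{x_i, y_i} over OTUs,
#' \deqn{d(x, y) = 1 - \frac{2 \sum_i \min(x_i, y_i)}{\sum_i (x_i + y_i)}.}
#' By default counts are converted to relative abundances first, since
#' sequencing depths differ between samples; set `on = "counts"` to use the
#' raw counts.
#'
#' @param x an [otu_table] or a numeric matrix (OTUs x samples).
#' @param on `"relative"` (default) or `"counts"`.
#' @return a symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], class `distance_matrix`.
#' @export
bray_curtis <- function(x, on = c("relative", "counts")) {
  on <- match.arg(on)
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2) .stopf("need at least 2 samples")
  if (any(colSums(m) <= 0))
    .stopf("sample(s) with all-zero values: %s",
           paste(colnames(m)[colSums(m) <= 0], collapse = ", "))
  v <- if (on == "relative") to_relative_abundance(m) else m
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  tot <- colSums(v)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      shared <- sum(pmin(v[, j], v[, k]))
      d[j, k] <- d[k, j] <- 1 - 2 * shared / (tot[j] + tot[k])
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

.check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    .stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) .stopf("distance matrix must have a zero diagonal")
  if (is.null(rownames(d))) dimnames(d) <- list(paste0("s", seq_len(nrow(d))),
                                                paste0("s", seq_len(nrow(d))))
  d
}

#' Principal coordinates analysis retaining imaginary axes
#'
#' Gower double-centering of \eqn{-\tfrac12 d^2} followed by an
#' eigendecomposition. Axes with positive eigenvalues ("real") and axes with
#' negative eigenvalues ("imaginary") are kept separately and no eigenvalue
#' correction is applied: semimetric dissimilarities such as Bray-Curtis are
#' embedded exactly as
#' \eqn{d_{ij}^2 = \|x_i - x_j\|^2 - \|y_i - y_j\|^2}
#' with \eqn{x} the real and \eqn{y} the imaginary coordinates, which is what
#' the dispersion computation needs.
#'
#' @param d symmetric distance matrix (any object coercible by `as.matrix`).
#' @return object of class `pcoa_ordination`: list with `eigenvalues`
#'   (descending), `points_real`, `points_imag` (rows = samples) and `ids`.
#' @export
pcoa <- function(d) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values), .Machine$double.eps) * 1e-8
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pr <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  pi_ <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), length(neg))
  rownames(pr) <- rownames(pi_) <- rownames(d)
  structure(list(eigenvalues = e$values, points_real = pr, points_imag = pi_,
                 ids = rownames(d)),
            class = "pcoa_ordination")
}

# distances to group centroids from fixed coordinates; core of PERMDISP.
# Returns list(z, n_clamped). gi: integer group index per sample.
.centroid_distances <- function(xr, xi, gi) {
  ng <- tabulate(gi)
  cr <- rowsum(xr, gi, reorder = TRUE) / ng
  dr2 <- rowSums((xr - cr[gi, , drop = FALSE])^2)
  if (ncol(xi)) {
    ci <- rowsum(xi, gi, reorder = TRUE) / ng
    di2 <- rowSums((xi - ci[gi, , drop = FALSE])^2)
  } else di2 <- 0
  z2 <- dr2 - di2
  clamped <- sum(z2 < 0)
  list(z = sqrt(pmax(z2, 0)), n_clamped = clamped)
}

.anova_f <- function(z, gi) {
  ng <- tabulate(gi)
  k <- length(ng)
  n <- length(z)
  gmeans <- as.vector(rowsum(z, gi, reorder = TRUE)) / ng
  ssb <- sum(ng * (gmeans - mean(z))^2)
  ssw <- sum((z - gmeans[gi])^2)
  if (ssb <= .Machine$double.eps * max(1, sum(z^2))) return(0)
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Per-sample distance to the group centroid (PERMDISP construction)
#'
#' Centroids are computed separately on the real and imaginary principal
#' coordinate axes; the distance of sample \eqn{i} to its group centroid is
#' \eqn{z_i = \sqrt{\max(0, \Delta^2_{real} - \Delta^2_{imag})}}
#' (Anderson's construction for semimetric dissimilarities). Negative squared
#' distances are clamped to zero before the square root; the number of clamps
#' is recorded in attribute `"n_clamped"`.
#'
#' @param o a `pcoa_ordination` from [pcoa].
#' @param groups named character vector (sample id -> group label), or an
#'   unnamed vector in ordination order.
#' @return named numeric vector of distances, with attribute `"n_clamped"`.
#' @export
dispersion_distances <- function(o, groups) {
  stopifnot(inherits(o, "pcoa_ordination"))
  groups <- .align_groups(o$ids, groups)
  f <- factor(groups)
  if (any(table(f) < 2))
    .stopf("singleton group(s): %s",
           paste(names(table(f))[table(f) < 2], collapse = ", "))
  res <- .centroid_distances(o$points_real, o$points_imag, as.integer(f))
  z <- stats::setNames(res$z, o$ids)
  attr(z, "n_clamped") <- res$n_clamped
  z
}

.align_groups <- function(ids, groups) {
  if (!is.null(names(groups))) {
    missing <- setdiff(ids, names(groups))
    if (length(missing))
      .stopf("samples without a group label: %s", paste(missing, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    .stopf("groups must be named or match the number of samples")
  }
  as.character(groups)
}

#' PERMDISP: permutation test of multivariate dispersion homogeneity
#'
#' Tests whether groups differ in their mean distance to the group centroid
#' in principal-coordinates space. The statistic is the one-way ANOVA F on
#' the per-sample centroid distances; the p-value is obtained by permuting
#' the sample-to-group labels and recomputing centroids and distances from
#' scratch for every permutation, with the add-one estimator
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})} so p is never zero.
#'
#' @param d distance matrix (e.g. from [bray_curtis]).
#' @param groups named character vector mapping sample ids to groups (at
#'   least 2 groups with >= 2 members each).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream, or `NULL`.
#' @return object of class `permdisp_result`: list with elements `F`, `p`,
#'   `n_permutations`, `group_means` (mean distance to centroid per group),
#'   `distances`, `n_clamped`, `seed`.
#' @export
permdisp <- function(d, groups, n_permutations = 999, seed = NULL) {
  if (n_permutations < 1) .stopf("n_permutations must be >= 1")
  d <- .check_distance_matrix(as.matrix(d))
  groups <- .align_groups(rownames(d), groups)
  f <- factor(groups)
  if (nlevels(f) < 2) .stopf("need at least 2 groups")
  if (any(table(f) < 2))
    .stopf("each group needs at least 2 members")
  o <- pcoa(d)
  gi <- as.integer(f)
  obs <- .centroid_distances(o$points_real, o$points_imag, gi)
  f_obs <- .anova_f(obs$z, gi)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      gp <- sample(gi)
      .anova_f(.centroid_distances(o$points_real, o$points_imag, gp)$z, gp)
    }, numeric(1)) >= f_obs)
  })
  p <- (1 + exceed) / (1 + n_permutations)
  gm <- tapply(obs$z, f, mean)
  structure(list(F = f_obs, p = p, n_permutations = as.integer(n_permutations),
                 group_means = gm, distances = stats::setNames(obs$z, rownames(d)),
                 n_clamped = obs$n_clamped, seed = seed),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_permutations))
  cat("mean distance to centroid:\n")
  print(round(x$group_means, 4))
  invisible(x)
}
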