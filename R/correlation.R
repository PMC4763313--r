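# permutations of 1..n, one column per permutation; cached per n (n <= 8)
.perm_cache <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(cbind, lapply(seq_along(v), function(i) {
      rbind(v[i], perms(v[-i]))
    }))
  }
  p <- perms(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' The correlation is the Pearson correlation of mid-ranks (average ranks on
#' ties), via `stats::cor(method = "spearman")`. For `n <= exact_max_n`
#' (default 8, i.e. at most 40,320 permutations) the two-sided p-value is
#' computed exactly by full enumeration of all permutations of one vector:
#' \eqn{p = \#\{|\rho^*| \ge |\rho|\} / n!}. For larger n the usual
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} is used. The exact
#' route matters because the motivating design has only six samples per
#' environment, where the t-approximation is poor.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with at least
#'   two distinct values.
#' @param exact_max_n largest n for which the exact enumeration is used.
#' @return list with `rho`, `p`, `n`, and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman <- function(x, y, exact_max_n = 8) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) .stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    .stopf("constant vector: Spearman rho is undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= exact_max_n) {
    rx <- rank(x)
    ry <- rank(y)
    perm <- .all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_all <- as.vector(crossprod(rxc, matrix(ryc[perm], n))) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r2 <- min(rho^2, 1 - .Machine$double.eps)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Correlate OTU relative abundances with chemistry parameters
#'
#' Spearman screening of a set of OTUs (typically the classified generalists
#' and specialists) against every chemistry parameter, on relative abundances
#' (depth-robust). Significance is flagged at raw `p < alpha`, matching the
#' classical screen; Benjamini-Hochberg q-values are reported alongside for
#' information but do not drive the flag. By default the correlation is
#' restricted to the samples of one environment (the motivating design
#' correlates within habitat, n = 6); pass `environment = NULL` to pool all
#' shared samples.
#'
#' @param t an [otu_table].
#' @param chem a [chemistry_table]; samples are matched by id and the
#'   intersection is used.
#' @param otus character vector of OTU ids to screen (subset of the table's
#'   OTUs).
#' @param environment restrict to this environment's samples (default:
#'   `NULL`, pool all shared samples).
#' @param alpha raw-p significance level (default 0.05).
#' @param exact_max_n see [spearman].
#' @return data.frame of class `correlation_table`, one row per
#'   (otu, parameter), sorted by (otu_id, parameter), with columns `otu_id`,
#'   `parameter`, `rho`, `p`, `q`, `n`, `significant`. OTUs that are constant
#'   across the used samples get `NA` rho/p and `significant = FALSE`, with a
#'   warning.
#' @export
correlate <- function(t, chem, otus, environment = NULL, alpha = 0.05,
                      exact_max_n = 8) {
  stopifnot(inherits(t, "otu_table"), inherits(chem, "chemistry_table"))
  bad <- setdiff(otus, rownames(t$counts))
  if (length(bad)) .stopf("unknown OTU id(s): %s", paste(bad, collapse = ", "))
  samples <- colnames(t$counts)
  if (!is.null(environment)) samples <- environment_samples(t, environment)
  samples <- intersect(samples, rownames(chem))
  if (length(samples) < 3)
    .stopf("fewer than 3 shared samples between OTU table and chemistry")
  ra <- to_relative_abundance(t$counts[, samples, drop = FALSE])
  cm <- unclass(chem)[samples, , drop = FALSE]
  otus <- sort(unique(as.character(otus)))
  params <- sort(colnames(cm))
  grid <- expand.grid(parameter = params, otu_id = otus,
                      stringsAsFactors = FALSE)[, c("otu_id", "parameter")]
  res <- mapply(function(o, pm) {
    xv <- ra[o, ]
    yv <- cm[, pm]
    if (length(unique(xv)) < 2 || length(unique(yv)) < 2)
      return(c(NA_real_, NA_real_))
    s <- spearman(xv, yv, exact_max_n = exact_max_n)
    c(s$rho, s$p)
  }, grid$otu_id, grid$parameter)
  out <- data.frame(grid, rho = res[1, ], p = res[2, ],
                    q = stats::p.adjust(res[2, ], method = "BH"),
                    n = length(samples),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < alpha
  if (anyNA(out$rho))
    warning("constant OTU abundance or parameter across the used samples; NA rho reported")
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "environment") <- environment
  class(out) <- c("correlation_table", "data.frame")
  out
}
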