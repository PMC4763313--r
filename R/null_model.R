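#' Null-model randomizations of an OTU table
#'
#' Generates randomized communities representing purely stochastic assembly.
#' The default `regional_multinomial` model preserves every sample's total
#' count (sequencing depth) and draws its composition by multinomial sampling
#' from the pooled regional relative-abundance vector, i.e. taxa are
#' allocated proportionally to their regional abundance. The alternative
#' `row_shuffle` model permutes each OTU's counts across samples (preserving
#' row totals instead of expectations).
#'
#' @param t an [otu_table].
#' @param n_null number of null replicates (>= 1).
#' @param seed integer seed, or `NULL`.
#' @param method `"regional_multinomial"` (default) or `"row_shuffle"`.
#' @return list of [otu_table] replicates; sample ids are suffixed
#'   `"_null<r>"` and environment labels are inherited.
#' @export
null_model_communities <- function(t, n_null, seed = NULL,
                                   method = c("regional_multinomial", "row_shuffle")) {
  stopifnot(inherits(t, "otu_table"))
  method <- match.arg(method)
  if (n_null < 1) .stopf("n_null must be >= 1")
  m <- t$counts
  depths <- colSums(m)
  regional <- rowSums(m) / sum(m)
  with_seed(seed, {
    lapply(seq_len(n_null), function(r) {
      nm <- if (method == "regional_multinomial") {
        vapply(depths, function(s) as.integer(stats::rmultinom(1, s, regional)),
               integer(nrow(m)))
      } else {
        t(apply(m, 1, sample))
      }
      dimnames(nm) <- list(rownames(m), paste0(colnames(m), "_null", r))
      env <- stats::setNames(unname(t$environment), colnames(nm))
      otu_table(nm, env)
    })
  })
}

#' Stochastic vs deterministic assembly test (Bray-Curtis null model + PERMDISP)
#'
#' Tests whether the observed community's beta-diversity differs from the
#' beta-diversity expected under purely stochastic assembly. Null communities
#' are generated with [null_model_communities]; one combined Bray-Curtis
#' distance matrix is built over the observed samples and all null samples;
#' PERMDISP then compares the dispersion of the observed group against the
#' null group. A non-significant result (p >= alpha) is consistent with
#' stochastic assembly; a significant one indicates deterministic signal in
#' the beta-diversity.
#'
#' @param t an [otu_table] with >= 3 samples.
#' @param n_null number of null replicate tables (default 6, mirroring the
#'   group size of the motivating design).
#' @param n_permutations PERMDISP permutations (default 999).
#' @param alpha significance level for the verdict (default 0.05).
#' @param seed integer seed; sub-streams for null generation and the
#'   permutation test are derived from it.
#' @param method null model, see [null_model_communities].
#' @return object of class `stochasticity_result`: list with `permdisp`
#'   (a `permdisp_result`), `n_null`, `alpha`, `verdict`
#'   (`"consistent_with_stochastic"` iff p >= alpha, else
#'   `"deterministic_signal"`), `distance` (the combined distance matrix)
#'   and `seed`.
#' @export
stochasticity_test <- function(t, n_null = 6, n_permutations = 999,
                               alpha = 0.05, seed = NULL,
                               method = c("regional_multinomial", "row_shuffle")) {
  stopifnot(inherits(t, "otu_table"))
  method <- match.arg(method)
  if (ncol(t$counts) < 3) .stopf("need at least 3 samples")
  seeds <- if (is.null(seed)) list(NULL, NULL)
           else list(derive_seed(seed, 1), derive_seed(seed, 2))
  nulls <- null_model_communities(t, n_null, seed = seeds[[1]], method = method)
  combined <- do.call(cbind, c(list(t$counts), lapply(nulls, function(x) x$counts)))
  groups <- stats::setNames(
    rep(c("observed", "null"), c(ncol(t$counts), ncol(combined) - ncol(t$counts))),
    colnames(combined))
  d <- bray_curtis(combined)
  pd <- permdisp(d, groups, n_permutations = n_permutations, seed = seeds[[2]])
  verdict <- if (pd$p >= alpha) "consistent_with_stochastic" else "deterministic_signal"
  structure(list(permdisp = pd, n_null = as.integer(n_null), alpha = alpha,
                 verdict = verdict, distance = d, seed = seed),
            class = "stochasticity_result")
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat(sprintf("Assembly stochasticity test (%d null replicates)\n", x$n_null))
  cat(sprintf("  PERMDISP F = %.4g, p = %.4g (alpha = %g)\n",
              x$permdisp$F, x$permdisp$p, x$alpha))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
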