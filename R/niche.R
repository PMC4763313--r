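#' Occupancy and abundance summaries per OTU within one environment
#'
#' Occupancy counts the samples of the environment in which the OTU is
#' detected (count > 0). Relative abundances are computed within the
#' environment's samples only. Two mean-abundance variants are returned: the
#' mean over occupied samples and the mean over all samples of the
#' environment.
#'
#' @param t an [otu_table].
#' @param environment environment label.
#' @return data.frame with columns `otu_id`, `occupancy`, `mean_occupied`,
#'   `mean_all`, `max_ra`; attribute `"n_samples"` holds the number of
#'   samples in the environment.
#' @export
occupancy_abundance <- function(t, environment) {
  stopifnot(inherits(t, "otu_table"))
  samples <- environment_samples(t, environment)
  sub <- t$counts[, samples, drop = FALSE]
  ra <- to_relative_abundance(sub)
  occ <- rowSums(sub > 0)
  mean_all <- rowMeans(ra)
  sum_ra <- rowSums(ra)
  mean_occ <- ifelse(occ > 0, sum_ra / occ, 0)
  out <- data.frame(otu_id = rownames(sub), occupancy = as.integer(occ),
                    mean_occupied = mean_occ, mean_all = mean_all,
                    max_ra = apply(ra, 1, max), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- length(samples)
  out
}

#' Classify OTUs as habitat generalists, specialists or other
#'
#' Implements the occupancy-abundance rule: within one environment, an OTU is
#' a *generalist* if it is present in every sample and its mean relative
#' abundance is at or above the threshold (default 2%); a *specialist* if it
#' is present in only one or two samples at mean relative abundance at or
#' above the threshold; everything else (including OTUs absent from the
#' environment) is *other*. The mean is taken over occupied samples by
#' default (`abundance_basis = "occupied"`); both variants are stored so the
#' choice is auditable. A Tukey-fence flag (value above Q3 + 1.5 IQR of
#' log10 mean abundance among detected OTUs) is reported for comparison with
#' box-plot outlier readings, but plays no part in the labelling.
#'
#' @param t an [otu_table].
#' @param environment environment label (must have >= 3 samples so that
#'   occupancy 1-2 is a strict subset of full occupancy).
#' @param threshold relative-abundance threshold in (0, 1); default 0.02.
#'   Abundance exactly equal to the threshold passes.
#' @param abundance_basis `"occupied"` (default) or `"all"`.
#' @return data.frame of class `niche_classification` with the columns of
#'   [occupancy_abundance] plus `label` and `tukey_outlier`; attributes
#'   `"environment"`, `"n_samples"`, `"threshold"`, `"abundance_basis"`.
#' @export
classify_otus <- function(t, environment, threshold = 0.02,
                          abundance_basis = c("occupied", "all")) {
  abundance_basis <- match.arg(abundance_basis)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    .stopf("threshold must be a single value in (0, 1)")
  oa <- occupancy_abundance(t, environment)
  n <- attr(oa, "n_samples")
  if (n < 3) .stopf("environment '%s' has fewer than 3 samples", environment)
  basis <- if (abundance_basis == "occupied") oa$mean_occupied else oa$mean_all
  label <- rep("other", nrow(oa))
  label[oa$occupancy == n & basis >= threshold] <- "generalist"
  label[oa$occupancy %in% c(1L, 2L) & basis >= threshold] <- "specialist"
  detected <- oa$occupancy > 0
  tukey <- rep(FALSE, nrow(oa))
  if (any(detected)) {
    lv <- log10(basis[detected])
    q <- stats::quantile(lv, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    tukey[detected] <- lv > fence
  }
  out <- cbind(oa, data.frame(label = label, tukey_outlier = tukey,
                              stringsAsFactors = FALSE))
  attr(out, "environment") <- environment
  attr(out, "n_samples") <- n
  attr(out, "threshold") <- threshold
  attr(out, "abundance_basis") <- abundance_basis
  class(out) <- c("niche_classification", "data.frame")
  out
}

#' Core microbiota of one environment
#'
#' The core is the set of OTUs present (count > 0) in every sample of the
#' environment — a deterministic, threshold-free definition. Generalists are
#' always a subset of the core.
#'
#' @param t an [otu_table].
#' @param environment environment label.
#' @return object of class `core_result`: list with `environment`, `otu_ids`
#'   (core members), `totals` (per-core-OTU total counts over the
#'   environment's samples), `n_samples`, `n_core`.
#' @export
core_microbiota <- function(t, environment) {
  stopifnot(inherits(t, "otu_table"))
  samples <- environment_samples(t, environment)
  sub <- t$counts[, samples, drop = FALSE]
  in_core <- rowSums(sub > 0) == length(samples)
  ids <- rownames(sub)[in_core]
  structure(list(environment = environment, otu_ids = ids,
                 totals = stats::setNames(rowSums(sub)[in_core], ids),
                 n_samples = length(samples), n_core = length(ids)),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("Core microbiota of '%s': %d OTUs present in all %d samples\n",
              x$environment, x$n_core, x$n_samples))
  invisible(x)
}

#' Taxonomic composition of the core microbiota
#'
#' Shares each taxon's percentage of the core sequences:
#' 100 x (counts of core OTUs assigned to the taxon) / (counts of all core
#' OTUs), over the environment's samples. Core OTUs lacking the requested
#' rank are binned as `"unclassified"`.
#'
#' @param t the [otu_table] the core was extracted from.
#' @param core a `core_result` from [core_microbiota].
#' @param taxonomy taxonomy map data.frame (see [read_taxonomy]) with column
#'   `otu_id` and rank columns.
#' @param rank taxonomic rank column to aggregate at (default `"genus"`).
#' @return data.frame of class `core_composition` with columns `taxon`,
#'   `counts`, `share_pct`, sorted by decreasing share; shares sum to 100.
#' @export
core_composition <- function(t, core, taxonomy, rank = "genus") {
  stopifnot(inherits(t, "otu_table"), inherits(core, "core_result"))
  if (core$n_core == 0) .stopf("core of '%s' is empty", core$environment)
  if (!rank %in% names(taxonomy)) .stopf("taxonomy has no rank column '%s'", rank)
  taxa <- taxonomy[[rank]][match(core$otu_ids, taxonomy$otu_id)]
  taxa[is.na(taxa) | !nzchar(taxa)] <- "unclassified"
  agg <- tapply(as.numeric(core$totals), taxa, sum)
  out <- data.frame(taxon = names(agg), counts = as.numeric(agg),
                    share_pct = 100 * as.numeric(agg) / sum(agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$share_pct, out$taxon), ]
  rownames(out) <- NULL
  attr(out, "environment") <- core$environment
  attr(out, "rank") <- rank
  class(out) <- c("core_composition", "data.frame")
  out
}
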