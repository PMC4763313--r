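#' Occupancy-abundance plot with the classification threshold line
#'
#' Box plots of log10 mean relative abundance by occupancy, with generalists
#' and specialists highlighted and a horizontal reference line at the
#' classification threshold (default 2%). Mirrors the classical box-plot
#' reading of niche breadth; the explicit threshold rule, not the box-plot
#' outliers, drives the labels.
#'
#' @param nc a `niche_classification` from [classify_otus].
#' @param file optional path; when it ends in `.svg` the plot is written as
#'   SVG, otherwise drawn on the current device.
#' @return invisibly, `nc`.
#' @export
plot_occupancy_abundance <- function(nc, file = NULL) {
  stopifnot(inherits(nc, "niche_classification"))
  if (!is.null(file)) {
    grDevices::svg(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  basis <- if (attr(nc, "abundance_basis") == "occupied") nc$mean_occupied else nc$mean_all
  keep <- nc$occupancy > 0
  x <- factor(nc$occupancy[keep], levels = seq_len(attr(nc, "n_samples")))
  y <- log10(basis[keep])
  graphics::boxplot(y ~ x, xlab = "occupancy (number of samples)",
                    ylab = "log10 mean relative abundance",
                    main = sprintf("%s (n = %d samples)",
                                   attr(nc, "environment"), attr(nc, "n_samples")),
                    outline = FALSE, col = "grey90")
  lab <- nc$label[keep]
  pts <- function(which, col) {
    i <- lab == which
    if (any(i)) graphics::points(jitter(as.integer(x[i]), 0.3), y[i],
                                 pch = 19, col = col)
  }
  pts("generalist", "red3")
  pts("specialist", "blue3")
  graphics::abline(h = log10(attr(nc, "threshold")), lty = 2)
  graphics::legend("bottomright", legend = c("generalist", "specialist",
                                             sprintf("%.0f%% threshold",
                                                     100 * attr(nc, "threshold"))),
                   col = c("red3", "blue3", "black"),
                   pch = c(19, 19, NA), lty = c(NA, NA, 2), bty = "n")
  invisible(nc)
}
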