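#' Tidy table of simulated transients
#'
#' Long-format export of an `la_transients` object: one row per time
#' step and region, with unit-annotated column names, suitable for
#' [write_table_csv()].
#'
#' @param transients an `la_transients` object
#' @return data.frame with columns `time_frac`, `pressure_mmHg`,
#'   `d_MV_mm`, `volume_ml`, `region`, `R_mm`, `d_mm`
#' @export
transients_table <- function(transients) {
  stopifnot(inherits(transients, "la_transients"))
  tr <- transients
  nt <- length(tr$time)
  regions <- rownames(tr$R)
  do.call(rbind, lapply(seq_along(regions), function(i)
    data.frame(time_frac = tr$time, pressure_mmHg = tr$pressure,
               d_MV_mm = tr$d_MV, volume_ml = tr$volume,
               region = regions[i], R_mm = tr$R[i, ],
               d_mm = tr$d_region[i, ], stringsAsFactors = FALSE)))
}

#' Sensitivity heatmap and ranking barplot
#'
#' Two-panel display of a [gsa_emulators()] result: total effects of
#' every input (columns) on every output (rows) as a shaded matrix, and
#' the normalised cross-output ranking as a bar chart.
#'
#' @param gsa list with `tables` and `ranking` from [gsa_emulators()]
#' @return invisibly, the total-effect matrix
#' @export
plot_sensitivity <- function(gsa) {
  stopifnot(is.list(gsa), !is.null(gsa$tables), !is.null(gsa$ranking))
  inputs <- gsa$tables[[1]]$input
  ST <- vapply(gsa$tables, function(tb) tb$ST[match(inputs, tb$input)],
               numeric(length(inputs)))
  ST <- matrix(ST, nrow = length(inputs),
               dimnames = list(inputs, names(gsa$tables)))
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 6, 2, 1))
  on.exit(graphics::par(old))
  graphics::image(seq_len(nrow(ST)), seq_len(ncol(ST)), pmax(ST, 0),
                  col = grDevices::grey.colors(64, start = 0.95, end = 0.1),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Total effect")
  graphics::axis(1, seq_len(nrow(ST)), rownames(ST), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(ST)), colnames(ST), las = 2,
                 cex.axis = 0.7)
  rk <- gsa$ranking
  graphics::barplot(rev(rk$weight), names.arg = rev(rk$input),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "normalised max total effect",
                    main = "Parameter ranking")
  invisible(ST)
}

#' Corner plot of a posterior sample
#'
#' Pairwise projections of the retained samples: histograms on the
#' diagonal (with the MAP marked) and bivariate density contours drawn
#' at the levels containing 11.8%, 39.3%, 67.5% and 86.4% of the
#' samples (the 0.5-2 sigma Gaussian masses) off the diagonal.
#'
#' @param posterior an `la_posterior`
#' @param parameters optional subset of parameter names to display
#' @param grid_n kernel-density grid resolution per axis
#' @return invisibly, the sample matrix displayed
#' @export
plot_corner <- function(posterior, parameters = NULL, grid_n = 41) {
  stopifnot(inherits(posterior, "la_posterior"))
  S <- posterior$samples
  if (!is.null(parameters)) S <- S[, parameters, drop = FALSE]
  d <- ncol(S)
  masses <- c(0.118, 0.393, 0.675, 0.864)
  old <- graphics::par(mfrow = c(d, d), mar = c(1.2, 1.2, 0.4, 0.4),
                       mgp = c(1, 0.3, 0))
  on.exit(graphics::par(old))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (j > i) { graphics::plot.new(); next }
    if (i == j) {
      graphics::hist(S[, i], breaks = 30, main = "", xlab = "",
                     ylab = "", axes = FALSE, col = "grey80",
                     border = "white")
      graphics::abline(v = posterior$map[colnames(S)[i]], col = "blue")
      graphics::axis(1, cex.axis = 0.5)
      graphics::mtext(colnames(S)[i], 3, line = -1, cex = 0.5)
    } else {
      kd <- MASS::kde2d(S[, j], S[, i], n = grid_n)
      # density thresholds holding the requested sample masses
      dens <- kd$z / sum(kd$z)
      ord <- order(dens, decreasing = TRUE)
      cum <- cumsum(dens[ord])
      levels <- vapply(masses, function(m)
        dens[ord][which(cum >= m)[1]] * sum(kd$z), numeric(1))
      graphics::plot(S[, j], S[, i], pch = ".", col = "grey60",
                     axes = FALSE, xlab = "", ylab = "")
      graphics::contour(kd, levels = sort(unique(levels)),
                        drawlabels = FALSE, add = TRUE, col = "black")
      graphics::box(col = "grey70")
    }
  }
  invisible(S)
}
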