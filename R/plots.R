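#' Plot a nucleus's observed K against its null envelope
#'
#' Observed K (red) over the radius grid with the min/median/max of the
#' Monte-Carlo null (black) and the upper-alpha significance cut-off (open
#' circles), the standard per-nucleus diagnostic for the clustering test.
#'
#' @param result a `ripley_result` from [cluster_test()].
#' @param ... passed to [graphics::plot()].
#' @return the result, invisibly.
#' @export
plot_k_envelope <- function(result, ...) {
  stopifnot(inherits(result, "ripley_result"))
  if (result$excluded) {
    stop("nucleus was excluded: ", result$reason, call. = FALSE)
  }
  tab <- result$table
  graphics::plot(tab$radius_um, tab$observed_k, type = "b", col = "red",
                 pch = 16, xlab = "radius (um)",
                 ylab = expression(K(r) ~ (mu * m^3)),
                 ylim = range(c(tab$observed_k, tab$null_min, tab$null_max)),
                 main = sprintf("nucleus %s (n = %d foci)",
                                as.character(result$nucleus_id),
                                result$n_foci), ...)
  graphics::lines(tab$radius_um, tab$null_min, col = "black", lty = 2)
  graphics::lines(tab$radius_um, tab$null_median, col = "black")
  graphics::lines(tab$radius_um, tab$null_max, col = "black", lty = 2)
  graphics::points(tab$radius_um, tab$null_cutoff, pch = 1)
  invisible(result)
}

#' Plot erosion-shell intensity profiles
#'
#' DAPI-normalised intensity per shell (shell 1 = periphery) for each
#' channel of one or more nuclei.
#'
#' @param profiles an `erosion_profile` or list of them.
#' @param channel channel to plot.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted values (nuclei x shells).
#' @export
plot_erosion_profile <- function(profiles, channel, ...) {
  if (inherits(profiles, "erosion_profile")) profiles <- list(profiles)
  mat <- t(vapply(profiles, function(p) {
    tab <- p$table[p$table$channel == channel, ]
    tab$normalized[order(tab$shell)]
  }, numeric(profiles[[1]]$n_shells)))
  graphics::matplot(t(mat), type = "b", pch = 16, lty = 1,
                    xlab = "shell (1 = periphery)",
                    ylab = "normalised intensity",
                    main = channel, ...)
  invisible(mat)
}
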