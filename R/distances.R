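#' Per-focus shortest distances within or between channels
#'
#' For every focus of the source channel, computes the 3D centre-to-centre
#' Euclidean distance to its nearest focus of the target channel (excluding
#' itself when source and target coincide). This is the per-nucleus
#' shortest-interprobe-distance summary used to ask whether ecDNA foci sit
#' within hub-like proximity (~200 nm) of one another.
#'
#' Cross-channel summaries are directional: `(A, B)` and `(B, A)` generally
#' differ because each source focus picks its own nearest target. A nucleus
#' with fewer than 2 relevant foci (same channel) or an empty source/target
#' (cross channel) yields an *empty* summary flagged via `n_source = 0`,
#' not an error, so cohort loops can skip it cleanly.
#'
#' @param foci a [foci_set].
#' @param source_channel,target_channel channel labels; equal labels give the
#'   within-channel nearest-neighbour distances.
#' @return An object of class `distance_summary`: list with `nucleus_id`,
#'   `channel_pair`, `per_focus_shortest` (um, one per source focus),
#'   `mean_shortest`, `min_shortest`, `n_source`, `empty`.
#' @examples
#' fs <- foci_set(data.frame(channel = "EGFR", x_um = c(0, 1, 3),
#'                           y_um = 0, z_um = 0))
#' shortest_distances(fs, "EGFR", "EGFR")$per_focus_shortest  # 1, 1, 2
#' @export
shortest_distances <- function(foci, source_channel, target_channel) {
  stopifnot(inherits(foci, "foci_set"))
  src <- foci_coords(foci, source_channel)
  tgt <- foci_coords(foci, target_channel)
  same <- identical(source_channel, target_channel)
  empty <- if (same) nrow(src) < 2 else (nrow(src) < 1 || nrow(tgt) < 1)
  if (empty) {
    return(new_distance_summary(foci$nucleus_id,
                                c(source_channel, target_channel), numeric(0)))
  }
  d <- cross_min_distances(src, tgt, exclude_self = same)
  new_distance_summary(foci$nucleus_id, c(source_channel, target_channel), d)
}

# per-row minimum distance from src to tgt; with exclude_self, src and tgt
# are the same matrix and the diagonal is excluded
cross_min_distances <- function(src, tgt, exclude_self = FALSE) {
  d2 <- outer(rowSums(src^2), rowSums(tgt^2), "+") - 2 * src %*% t(tgt)
  d2[d2 < 0] <- 0  # numerical guard
  if (exclude_self) diag(d2) <- Inf
  unname(sqrt(apply(d2, 1, min)))
}

new_distance_summary <- function(nucleus_id, channel_pair, d) {
  structure(list(
    nucleus_id = nucleus_id,
    channel_pair = channel_pair,
    per_focus_shortest = d,
    mean_shortest = if (length(d) > 0) mean(d) else NA_real_,
    min_shortest = if (length(d) > 0) min(d) else NA_real_,
    n_source = length(d),
    empty = length(d) == 0
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance_summary> nucleus '%s' %s -> %s: n=%d, mean=%s um, min=%s um\n",
    as.character(x$nucleus_id), x$channel_pair[1], x$channel_pair[2],
    x$n_source,
    if (x$empty) "NA" else sprintf("%.4f", x$mean_shortest),
    if (x$empty) "NA" else sprintf("%.4f", x$min_shortest)))
  invisible(x)
}

#' Fraction of foci with a near neighbour below a distance threshold
#'
#' Counts source foci whose shortest distance to the target channel is
#' strictly below `threshold` (the "< 200 nm" proximity convention), and
#' reports the proportion, e.g. 4 of 1011 CDK4 foci within 200 nm of a
#' PDGFRA focus is 0.39%.
#'
#' @param summary a `distance_summary` from [shortest_distances()].
#' @param threshold distance threshold in micrometres (strict `<`).
#' @return list with `count`, `total`, `proportion` (in \[0,1\], `NaN` when
#'   the summary is empty) and `percent` (the proportion as a percentage
#'   truncated to 2 decimals for display; truncation, not rounding, is the
#'   convention the reference proportions such as 4/1011 = 0.39\% follow).
#' @export
proximity_fraction <- function(summary, threshold) {
  stopifnot(inherits(summary, "distance_summary"))
  assert_scalar_number(threshold, "threshold", 0, strict_lower = TRUE)
  total <- summary$n_source
  count <- sum(summary$per_focus_shortest < threshold)
  prop <- if (total == 0) NaN else count / total
  list(count = count, total = total, proportion = prop,
       percent = trunc(100 * prop * 100) / 100)
}

#' Pooled cumulative distribution of shortest distances
#'
#' Pools the per-focus shortest distances across a cohort of nuclei and
#' returns the empirical CDF on a distance grid (the cumulative relative
#' frequency curve of shortest interprobe distances).
#'
#' @param summaries list of `distance_summary` objects; empty summaries are
#'   dropped (their count is reported in the `n_excluded` attribute).
#' @param grid distance grid in micrometres; defaults to 100 points spanning
#'   0 to the pooled maximum.
#' @return data frame with columns `distance_um` and `cum_freq`
#'   (non-decreasing, ending at 1); attributes `n_pooled`, `n_excluded`.
#' @export
cumulative_distance_distribution <- function(summaries, grid = NULL) {
  if (inherits(summaries, "distance_summary")) summaries <- list(summaries)
  empty <- vapply(summaries, function(s) s$empty, logical(1))
  pooled <- unlist(lapply(summaries[!empty],
                          function(s) s$per_focus_shortest))
  if (length(pooled) == 0) {
    stop("all summaries are empty; nothing to pool", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(0, max(pooled), length.out = 100)
  cdf <- stats::ecdf(pooled)
  out <- data.frame(distance_um = grid, cum_freq = cdf(grid))
  attr(out, "n_pooled") <- length(pooled)
  attr(out, "n_excluded") <- sum(empty)
  out
}

#' Filter candidate foci to large foci (>= 500 nm diameter)
#'
#' Large immunofluorescence foci of RNA polymerase II ("PolII hubs") are
#' defined by a diameter of at least 0.5 um; this filter applies that
#' inclusive cut.
#'
#' @param candidates data frame with columns `x_um`, `y_um`, `z_um`,
#'   `diameter_um`.
#' @param min_diameter inclusive diameter threshold in micrometres
#'   (default 0.5).
#' @param nucleus_id identifier carried on the result.
#' @return An object of class `large_foci_set`: list with `nucleus_id` and a
#'   `foci` data frame of the retained rows.
#' @export
filter_large_foci <- function(candidates, min_diameter = 0.5,
                              nucleus_id = "nucleus_1") {
  if (!is.data.frame(candidates)) {
    stop("'candidates' must be a data frame", call. = FALSE)
  }
  required <- c("x_um", "y_um", "z_um", "diameter_um")
  missing <- setdiff(required, names(candidates))
  if (length(missing) > 0) {
    stop("candidates are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) > 0 && anyNA(candidates$diameter_um)) {
    stop("missing diameter_um values", call. = FALSE)
  }
  keep <- candidates[candidates$diameter_um >= min_diameter, , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(nucleus_id = nucleus_id, foci = keep),
            class = "large_foci_set")
}

#' Distances from FISH foci to the nearest large focus
#'
#' Per FISH focus, the centre-to-centre distance to the nearest large
#' (>= 500 nm) focus in the same nucleus; the per-nucleus mean and single
#' minimum summarise how close ecDNA sit to PolII hubs.
#'
#' @param foci a [foci_set] (the FISH channel of interest).
#' @param hubs a `large_foci_set` from [filter_large_foci()].
#' @param channel optional channel selection within `foci`.
#' @return a `distance_summary` with channel pair `(channel, "large_foci")`;
#'   empty (flagged) when there are no foci or no hubs.
#' @export
foci_to_hub_distances <- function(foci, hubs, channel = NULL) {
  stopifnot(inherits(foci, "foci_set"), inherits(hubs, "large_foci_set"))
  src <- foci_coords(foci, channel)
  tgt <- as.matrix(hubs$foci[, c("x_um", "y_um", "z_um"), drop = FALSE])
  pair <- c(if (is.null(channel)) "all" else channel, "large_foci")
  if (nrow(src) == 0 || nrow(tgt) == 0) {
    return(new_distance_summary(foci$nucleus_id, pair, numeric(0)))
  }
  d <- cross_min_distances(src, tgt, exclude_self = FALSE)
  new_distance_summary(foci$nucleus_id, pair, d)
}

#' Tabulate distance summaries across nuclei
#'
#' @param summaries list of `distance_summary` objects.
#' @return data frame with one row per summary: nucleus id, channel pair,
#'   n of source foci, mean and minimum shortest distance (um, 4 dp).
#' @export
distance_summary_table <- function(summaries) {
  if (inherits(summaries, "distance_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(nucleus_id = as.character(s$nucleus_id),
               source_channel = s$channel_pair[1],
               target_channel = s$channel_pair[2],
               n_source = s$n_source,
               mean_shortest_um = round(s$mean_shortest, 4),
               min_shortest_um = round(s$min_shortest, 4))
  }))
}
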