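#' Point-pattern simulators for foci in a spherical nucleus
#'
#' These generators produce [foci_set] objects with known spatial structure so
#' that the distance and clustering analyses can be validated end to end:
#' complete spatial randomness (CSR, the null of the clustering test), a
#' Thomas cluster process (a clustered alternative emulating hypothesised
#' "ecDNA hubs"), doublets at fixed separation (emulating double minutes),
#' and a dual-channel pattern with a controlled colocalised fraction
#' (emulating two ecDNA species sharing a subset of molecules).
#'
#' The nucleus is modelled as a ball of radius `bounding_radius` micrometres
#' centred at the origin; all coordinates are in micrometres.
#'
#' @name simulate_points
NULL

# n points uniform in the ball of given radius (isotropic direction,
# radius ~ R * U^(1/3)); consumes the current RNG stream
runif_ball <- function(n, radius) {
  if (n == 0) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x_um", "y_um", "z_um"))))
  }
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v * v))
  p <- v * (radius * stats::runif(n)^(1 / 3))
  colnames(p) <- c("x_um", "y_um", "z_um")
  p
}

# exact draw from an isotropic Gaussian (sd sigma) centred at `centre`,
# truncated to the ball of `radius`. For sigma <= radius plain rejection of
# Gaussian draws is efficient; for larger sigma the acceptance rate decays
# like (radius/sigma)^3, so propose uniform in the ball and accept against
# the Gaussian density (whose maximum over the ball is at `centre`, which
# lies inside it) — the same distribution, O(1) acceptance in both regimes.
rtrunc_gauss_ball <- function(centre, sigma, radius) {
  if (sigma <= radius) {
    repeat {
      cand <- centre + stats::rnorm(3, sd = sigma)
      if (sum(cand^2) <= radius^2) return(cand)
    }
  }
  repeat {
    cand <- drop(runif_ball(1, radius))
    if (stats::runif(1) <
        exp(-sum((cand - centre)^2) / (2 * sigma^2))) return(cand)
  }
}

coords_to_foci <- function(coords, channel, nucleus_id, bounding_radius,
                           extra = NULL, metadata = list()) {
  df <- as.data.frame(coords)
  names(df) <- c("x_um", "y_um", "z_um")
  df <- cbind(channel = rep_len(channel, nrow(df)), df)
  if (!is.null(extra)) df <- cbind(df, extra)
  foci_set(df, nucleus_id = nucleus_id, bounding_radius = bounding_radius,
           metadata = metadata)
}

#' @rdname simulate_points
#' @param n number of foci.
#' @param bounding_radius nucleus bounding radius in micrometres.
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @param channel channel label attached to the simulated foci.
#' @param nucleus_id nucleus identifier.
#' @return A [foci_set].
#' @examples
#' fs <- simulate_csr_nucleus(40, seed = 1)
#' max(sqrt(rowSums(foci_as_matrix(fs)^2))) <= 5
#' @export
simulate_csr_nucleus <- function(n, bounding_radius = 5, seed = NULL,
                                 channel = "EGFR", nucleus_id = "nucleus_1") {
  assert_scalar_number(n, "n", 0)
  assert_scalar_number(bounding_radius, "bounding_radius", 0,
                       strict_lower = TRUE)
  coords <- with_local_seed(seed, runif_ball(n, bounding_radius))
  coords_to_foci(coords, channel, nucleus_id, bounding_radius,
                 metadata = list(process = "csr", seed = seed))
}

#' @rdname simulate_points
#' @param n_parents number of Thomas parent points (uniform in the ball;
#'   parents themselves are not emitted as foci, as in the standard Thomas
#'   process — only offspring are observable).
#' @param mean_children Poisson mean number of children per parent.
#' @param sigma isotropic Gaussian scatter (sd per axis, um) of children
#'   around their parent; children falling outside the ball are resampled so
#'   the parent-child distance structure is preserved.
#' @export
simulate_thomas_nucleus <- function(n_parents, mean_children, sigma,
                                    bounding_radius = 5, seed = NULL,
                                    channel = "EGFR",
                                    nucleus_id = "nucleus_1") {
  assert_scalar_number(n_parents, "n_parents", 1)
  assert_scalar_number(mean_children, "mean_children", 0)
  assert_scalar_number(sigma, "sigma", 0, strict_lower = TRUE)
  assert_scalar_number(bounding_radius, "bounding_radius", 0,
                       strict_lower = TRUE)
  sim <- with_local_seed(seed, {
    parents <- runif_ball(n_parents, bounding_radius)
    counts <- stats::rpois(n_parents, mean_children)
    kids <- vector("list", n_parents)
    for (i in seq_len(n_parents)) {
      if (counts[i] == 0) {
        kids[[i]] <- matrix(numeric(0), 0, 3)
        next
      }
      pts <- matrix(NA_real_, counts[i], 3)
      for (j in seq_len(counts[i])) {
        pts[j, ] <- rtrunc_gauss_ball(parents[i, ], sigma, bounding_radius)
      }
      kids[[i]] <- pts
    }
    list(coords = do.call(rbind, kids),
         parent_id = rep(seq_len(n_parents), counts))
  })
  coords_to_foci(sim$coords, channel, nucleus_id, bounding_radius,
                 extra = data.frame(parent_id = sim$parent_id),
                 metadata = list(process = "thomas", seed = seed,
                                 n_parents = n_parents, sigma = sigma))
}

#' @rdname simulate_points
#' @param n_pairs number of doublet pairs; anchors are uniform in the ball and
#'   each partner sits at exactly `separation` um in a uniformly random
#'   direction (resampled until inside the ball).
#' @param separation fixed anchor-partner distance in micrometres; must not
#'   exceed the ball diameter.
#' @export
simulate_doublets <- function(n_pairs, separation, bounding_radius = 5,
                              seed = NULL, channel = "EGFR",
                              nucleus_id = "nucleus_1") {
  assert_scalar_number(n_pairs, "n_pairs", 0)
  assert_scalar_number(separation, "separation", 0)
  assert_scalar_number(bounding_radius, "bounding_radius", 0,
                       strict_lower = TRUE)
  if (separation > 2 * bounding_radius) {
    stop("'separation' exceeds the ball diameter; no partner can fit",
         call. = FALSE)
  }
  sim <- with_local_seed(seed, {
    anchors <- runif_ball(n_pairs, bounding_radius)
    partners <- matrix(NA_real_, n_pairs, 3)
    for (i in seq_len(n_pairs)) {
      repeat {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u * u))
        cand <- anchors[i, ] + separation * u
        if (sum(cand^2) <= bounding_radius^2) break
      }
      partners[i, ] <- cand
    }
    list(anchors = anchors, partners = partners)
  })
  coords <- rbind(sim$anchors, sim$partners)
  pair_id <- rep(seq_len(n_pairs), 2)
  coords_to_foci(coords, channel, nucleus_id, bounding_radius,
                 extra = data.frame(pair_id = pair_id),
                 metadata = list(process = "doublets", seed = seed,
                                 separation = separation))
}

#' @rdname simulate_points
#' @param n_a,n_b focus counts for channels `channel_a` and `channel_b`.
#' @param coloc_fraction fraction of `min(n_a, n_b)` foci that form A-B pairs
#'   at `coloc_separation`; must yield an integer number of pairs.
#' @param coloc_separation A-B distance (um) within a colocalised pair.
#' @param channel_a,channel_b channel labels.
#' @export
simulate_dual_channel <- function(n_a, n_b, coloc_fraction = 0,
                                  coloc_separation = 0.1, bounding_radius = 5,
                                  seed = NULL, channel_a = "CDK4",
                                  channel_b = "PDGFRA",
                                  nucleus_id = "nucleus_1") {
  assert_scalar_number(n_a, "n_a", 0)
  assert_scalar_number(n_b, "n_b", 0)
  assert_scalar_number(coloc_fraction, "coloc_fraction", 0, 1)
  assert_scalar_number(coloc_separation, "coloc_separation", 0)
  n_pairs_real <- coloc_fraction * min(n_a, n_b)
  n_pairs <- round(n_pairs_real)
  if (abs(n_pairs_real - n_pairs) > 1e-8) {
    stop("coloc_fraction * min(n_a, n_b) must be an integer count of pairs",
         call. = FALSE)
  }
  sim <- with_local_seed(seed, {
    a_free <- runif_ball(n_a - n_pairs, bounding_radius)
    b_free <- runif_ball(n_b - n_pairs, bounding_radius)
    anchors <- runif_ball(n_pairs, bounding_radius)
    partners <- matrix(numeric(0), 0, 3)
    if (n_pairs > 0) {
      partners <- matrix(NA_real_, n_pairs, 3)
      for (i in seq_len(n_pairs)) {
        repeat {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u * u))
          cand <- anchors[i, ] + coloc_separation * u
          if (sum(cand^2) <= bounding_radius^2) break
        }
        partners[i, ] <- cand
      }
    }
    list(a = rbind(anchors, a_free), b = rbind(partners, b_free))
  })
  df <- data.frame(
    channel = c(rep(channel_a, n_a), rep(channel_b, n_b)),
    rbind(sim$a, sim$b)
  )
  names(df)[2:4] <- c("x_um", "y_um", "z_um")
  df$paired <- c(seq_len(n_a) <= n_pairs, seq_len(n_b) <= n_pairs)
  foci_set(df, nucleus_id = nucleus_id, bounding_radius = bounding_radius,
           metadata = list(process = "dual", seed = seed,
                           n_pairs = n_pairs,
                           coloc_separation = coloc_separation))
}

#' Coordinate matrix of a foci_set
#'
#' @param x a [foci_set].
#' @param channel optional channel label(s) to select.
#' @return numeric matrix with columns `x_um`, `y_um`, `z_um`.
#' @export
foci_as_matrix <- function(x, channel = NULL) foci_coords(x, channel)
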