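# Synthetic helmet-shaped sensor array and spatial topographies.

#' Construct a helmet-like sensor array
#'
#' Places `n_channels` quasi-uniform points on the upper unit hemisphere via a
#' Fibonacci lattice (rotated about the vertical axis by a seeded random
#' angle), and derives a channel adjacency graph by thresholding pairwise
#' Euclidean distance. The threshold is set from the distribution of
#' 7th-nearest-neighbour distances so that the median degree falls in 6-8;
#' any channel left with fewer than two neighbours is connected to its two
#' nearest channels.
#'
#' @param n_channels Number of sensors (>= 8; the study system has 274).
#' @param seed Seed controlling the lattice rotation.
#' @return A `sensor_array`: list with `n_channels`, `positions`
#'   (n x 3 unit vectors), `adjacency` (list of neighbour index vectors) and
#'   `channel_ids`.
#' @export
make_sensor_array <- function(n_channels = 274, seed = 1L) {
  if (n_channels < 8) stop("n_channels must be at least 8")
  local_rng(seed)
  phi_rot <- stats::runif(1, 0, 2 * pi)
  i <- seq_len(n_channels) - 0.5
  golden <- pi * (3 - sqrt(5))
  # upper hemisphere: z from ~1 down to ~0
  z <- 1 - i / n_channels
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n_channels) - 1) + phi_rot
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)

  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  knn7 <- apply(d, 1, function(row) sort(row)[min(7, n_channels - 1)])
  thresh <- stats::median(knn7) * 1.0001
  adj <- lapply(seq_len(n_channels), function(j) which(d[j, ] <= thresh))
  # guarantee >= 2 neighbours per channel
  for (j in seq_len(n_channels)) {
    if (length(adj[[j]]) < 2) {
      nn <- order(d[j, ])[1:2]
      adj[[j]] <- sort(union(adj[[j]], nn))
      for (k in nn) adj[[k]] <- sort(union(adj[[k]], j))
    }
  }
  structure(list(n_channels = n_channels, positions = pos, adjacency = adj,
                 channel_ids = sprintf("MEG%03d", seq_len(n_channels)),
                 threshold = thresh, seed = seed),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("Sensor array: %d channels, median degree %g (range %d-%d)\n",
              x$n_channels, stats::median(deg), min(deg), max(deg)))
  invisible(x)
}

# Unit vector from azimuth (rad, 0 = +x, pi/2 = +y) and elevation (rad).
direction_vector <- function(azimuth, elevation) {
  v <- c(cos(elevation) * cos(azimuth), cos(elevation) * sin(azimuth),
         sin(elevation))
  v / sqrt(sum(v^2))
}

# Rotate unit vector v by angle about unit axis k (Rodrigues).
rotate_about <- function(v, k, angle) {
  k <- k / sqrt(sum(k^2))
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Spatial topography over a sensor array
#'
#' Gaussian-in-angle channel weights centred on a direction; in dipolar mode,
#' the difference of two opposite-polarity lobes separated by `lobe_sep`
#' radians (mimicking the field pattern of an axial-gradiometer array over a
#' tangential source). Weights are normalized to unit maximum absolute value.
#'
#' @param array A `sensor_array`.
#' @param center Unit 3-vector (or `c(azimuth, elevation)` in radians) of the
#'   topography centre.
#' @param width Angular width (SD, radians) of each lobe; `Inf` gives a flat
#'   map in non-dipolar mode.
#' @param dipolar If TRUE, return a two-lobe, zero-mean-like pattern.
#' @param lobe_sep Angular separation between the two lobes (radians).
#' @return Numeric weight vector of length `n_channels`, max |w| = 1.
#' @export
make_topography <- function(array, center, width = 0.5, dipolar = FALSE,
                            lobe_sep = pi / 2) {
  if (width <= 0) stop("width must be positive")
  if (length(center) == 2) center <- direction_vector(center[1], center[2])
  center <- center / sqrt(sum(center^2))
  pos <- array$positions
  ang_to <- function(ctr) {
    cosang <- pmin(1, pmax(-1, pos %*% ctr))
    acos(cosang)
  }
  gauss <- function(a) if (is.infinite(width)) rep(1, length(a)) else exp(-a^2 / (2 * width^2))
  if (!dipolar) {
    w <- gauss(ang_to(center))
  } else {
    # displace the lobes azimuthally (constant elevation) so that, on a
    # quasi-uniform array, the two lobes cover comparable channel sets
    axis <- if (abs(center[3]) < 0.95) c(0, 0, 1) else c(1, 0, 0)
    c1 <- rotate_about(center, axis, lobe_sep / 2)
    c2 <- rotate_about(center, axis, -lobe_sep / 2)
    w <- gauss(ang_to(c1)) - gauss(ang_to(c2))
  }
  m <- max(abs(w))
  if (m > 0) w <- w / m
  as.numeric(w)
}
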