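# Spherical-head geometry and the analytic leadfield.
#
# The head is a homogeneous unit-radius spherical conductor (sigma = 1) with an
# insulating exterior. Sensors sit on the upper surface, sources on a
# concentric inner sphere with radial orientations. The surface potential of a
# radial unit current dipole at radius b, at a surface point separated by angle
# gamma from the dipole axis, follows from matching the insulated-boundary
# condition term by term in the Legendre expansion:
#
#   V(gamma; b) = (1 / 4 pi) * sum_{n >= 1} (2n + 1) b^(n-1) P_n(cos gamma)
#
# The series converges geometrically for b < 1 and is truncated at n = 200
# (relative truncation error < 1e-6 for b <= 0.9).

#' Surface potential of radial dipoles in a homogeneous sphere
#'
#' Evaluates the analytic leadfield of the spherical head model: the electric
#' potential generated at unit-sphere surface points by unit-strength radial
#' current dipoles inside the sphere.
#'
#' @param sensor_positions numeric matrix (n_sensors x 3) of points on the unit
#'   sphere surface.
#' @param source_positions numeric matrix (n_sources x 3) of dipole positions
#'   strictly inside the sphere (radius < 1).
#' @param n_terms number of Legendre terms retained in the series.
#' @return gain matrix, n_sensors x n_sources (unitless; sigma = 1, R = 1).
#' @export
sphere_dipole_gain <- function(sensor_positions, source_positions, n_terms = 200L) {
  sensor_positions <- rbind(sensor_positions)
  source_positions <- rbind(source_positions)
  check_finite(sensor_positions, "sensor_positions")
  check_finite(source_positions, "source_positions")
  b <- sqrt(rowSums(source_positions^2))
  if (any(b >= 1) || any(b <= 0)) {
    stop_invalid_argument("source radii must lie strictly inside the unit sphere (0 < |r| < 1)")
  }
  e_hat <- sensor_positions / sqrt(rowSums(sensor_positions^2))
  s_hat <- source_positions / b
  cosg <- tcrossprod(e_hat, s_hat) # n_sensors x n_sources
  cosg <- pmin(pmax(cosg, -1), 1)
  # Legendre recurrence, accumulating sum (2n+1) b^(n-1) P_n(cosg) columnwise.
  n_sen <- nrow(cosg)
  n_src <- ncol(cosg)
  p_prev <- matrix(1, n_sen, n_src)        # P_0
  p_cur <- cosg                            # P_1
  bpow <- matrix(1, n_sen, n_src)          # b^(n-1) for n = 1
  brow <- matrix(b, n_sen, n_src, byrow = TRUE)
  acc <- 3 * p_cur                         # n = 1 term
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * cosg * p_cur - (n - 1) * p_prev) / n
    bpow <- bpow * brow
    acc <- acc + (2 * n + 1) * bpow * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

# Fibonacci lattice with n points, z descending from the pole (z = 1 is always
# included so degenerate 1-point layouts sit at the vertex).
fibonacci_cap <- function(n, z_low, azimuth0 = 0) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n)
  z <- if (n == 1L) 1 else 1 - (i - 1) / (n - 1) * (1 - z_low)
  phi <- 2 * pi * i / golden^2 + azimuth0
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Construct a spherical-head leadfield geometry
#'
#' Places `n_sensors` electrodes on the upper unit hemisphere (Fibonacci
#' lattice, emulating a dense EEG montage) and `n_sources` radially oriented
#' dipoles on a concentric sphere of radius `source_radius` covering the upper
#' cortex-like cap, then evaluates the analytic spherical gain between every
#' sensor-source pair. When the layout has 68 sources with one dipole per ROI,
#' region labels follow the 68 cortical parcels of the Desikan-Killiany atlas;
#' otherwise generic labels are generated.
#'
#' @param n_sensors number of scalp electrodes.
#' @param n_sources number of dipoles.
#' @param seed integer; rotates the source lattice azimuthally so distinct
#'   seeds give distinct (but statistically equivalent) geometries.
#' @param source_radius radius of the source shell (fraction of head radius).
#' @param dipoles_per_roi dipoles sharing each ROI label; `n_sources` must be a
#'   multiple. Values > 1 exercise ROI aggregation: the extra dipoles are
#'   jittered around the ROI seed point and carry random orientation signs.
#' @param azimuth optional fixed azimuthal rotation of the source lattice
#'   (radians); overrides the seed-drawn rotation. Used to derive per-subject
#'   anatomies from a template geometry.
#' @return an object of class `leadfield` with fields `gain`
#'   (n_sensors x n_sources), `sensor_positions`, `source_positions`,
#'   `source_orientations` (unit radial vectors, possibly sign-flipped in
#'   multi-dipole mode), `roi_labels`.
#' @export
make_geometry <- function(n_sensors, n_sources, seed = 1L, source_radius = 0.8,
                          dipoles_per_roi = 1L, azimuth = NULL) {
  n_sensors <- check_count(n_sensors, "n_sensors")
  n_sources <- check_count(n_sources, "n_sources")
  dipoles_per_roi <- check_count(dipoles_per_roi, "dipoles_per_roi")
  if (n_sources %% dipoles_per_roi != 0L) {
    stop_invalid_argument("n_sources must be a multiple of dipoles_per_roi")
  }
  n_rois <- n_sources %/% dipoles_per_roi
  with_seed(seed, {
    sensors <- fibonacci_cap(n_sensors, z_low = 0.02)
    az <- if (is.null(azimuth)) runif(1, 0, 2 * pi) else azimuth
    centers <- fibonacci_cap(n_rois, z_low = -0.4, azimuth0 = az) * source_radius
    if (dipoles_per_roi == 1L) {
      src <- centers
      orient_sign <- rep(1, n_sources)
    } else {
      jit <- matrix(rnorm(n_sources * 3, sd = 0.03), ncol = 3)
      src <- centers[rep(seq_len(n_rois), each = dipoles_per_roi), , drop = FALSE] + jit
      rad <- sqrt(rowSums(src^2))
      src <- src / rad * pmin(rad, 0.95) # keep strictly inside the sphere
      orient_sign <- sample(c(-1, 1), n_sources, replace = TRUE)
    }
    orientations <- src / sqrt(rowSums(src^2)) * orient_sign
    gain <- sphere_dipole_gain(sensors, src) * rep(orient_sign, each = n_sensors)
    labels <- roi_label_set(n_rois)
    structure(
      list(
        gain = gain,
        sensor_positions = sensors,
        source_positions = src,
        source_orientations = orientations,
        roi_labels = rep(labels, each = dipoles_per_roi),
        azimuth = az
      ),
      class = "leadfield"
    )
  })
}

# 34 cortical parcel names per hemisphere (Desikan-Killiany); used verbatim
# when the layout has 68 ROIs so atlas-based node subsetting works by name.
dk_parcels <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

roi_label_set <- function(n_rois) {
  if (n_rois == 68L) {
    c(paste0("lh.", dk_parcels), paste0("rh.", dk_parcels))
  } else {
    sprintf("roi_%03d", seq_len(n_rois))
  }
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf(
    "<leadfield> %d sensors x %d sources (%d ROIs)\n",
    nrow(x$gain), ncol(x$gain), length(unique(x$roi_labels))
  ))
  invisible(x)
}

#' Multiplicative perturbation of a leadfield gain
#'
#' Applies independent multiplicative Gaussian noise to every gain entry,
#' breaking the "inverse crime" of inverting with the exact simulation
#' leadfield. Intended for sensitivity studies.
#'
#' @param lf a `leadfield`.
#' @param sd standard deviation of the multiplicative noise.
#' @param seed integer seed.
#' @return a new `leadfield` with perturbed gain.
#' @export
perturb_gain <- function(lf, sd = 0.1, seed = 1L) {
  stopifnot(inherits(lf, "leadfield"))
  with_seed(seed, {
    lf$gain <- lf$gain * (1 + matrix(rnorm(length(lf$gain), sd = sd), nrow(lf$gain)))
  })
  lf
}
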