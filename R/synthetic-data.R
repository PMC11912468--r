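# Synthetic-data generators.
#
# Every downstream stage of the pipeline (deuterium NMR, NOESY, FCS,
# TCSPC lifetimes, trajectory geometry) consumes an input that these
# generators can produce with known ground truth, so the complete analysis
# is testable without any instrument data. Noiseless outputs agree with
# their closed forms to near machine precision; a given seed reproduces a
# dataset bit-identically.

#' Bundle ground-truth parameters for a synthetic dataset
#'
#' Collects the "true" values behind one synthetic dataset: the per-carbon
#' order profile driving the powder spectrum, the cross-relaxation rates per
#' lipid group, the FCS model parameters, the fluorescence decay components,
#' and the depth/orientation distribution of the ligand in the bilayer.
#' Downstream recovery tests compare fitted values against this object, and
#' \code{\link{write_manifest}} records it next to the generated files.
#'
#' @param order_profile numeric vector of C--D order parameters for carbons
#'   2..16 of the palmitoyl chain, each in \eqn{[0, 0.5]} and monotone
#'   non-increasing toward the terminal methyl.
#' @param sigma_true named numeric vector of NOESY cross-relaxation rates
#'   (1/s), one per lipid functional group.
#' @param fcs_params an \code{\link{fcs_params}} object.
#' @param decay_components data frame with columns \code{tau} (ns, > 0) and
#'   \code{amplitude} (fractions summing to 1).
#' @param depth_mean,depth_sd mean and sd (nm) of the ligand minimum distance
#'   to the bilayer center; \code{depth_sd} must be positive.
#' @param ring_angle_mean,ring_angle_sd mean and sd (degrees) of the angle
#'   between the indole long axis and the bilayer normal.
#' @param seed integer RNG seed used for every generator drawing from this
#'   ground truth.
#' @return an object of class \code{ground_truth} (a validated list).
#' @export
ground_truth <- function(order_profile, sigma_true, fcs_params,
                         decay_components, depth_mean, depth_sd,
                         ring_angle_mean, ring_angle_sd, seed) {
  if (any(order_profile < 0 | order_profile > 0.5)) {
    stop("order parameters must lie in [0, 0.5]")
  }
  if (is.unsorted(rev(order_profile))) {
    stop("order profile must be monotone non-increasing toward the chain end")
  }
  if (any(sigma_true < 0)) stop("sigma_true rates must be non-negative")
  if (is.null(names(sigma_true))) stop("sigma_true must be named by lipid group")
  stopifnot(inherits(fcs_params, "fcs_params"))
  decay_components <- validate_components(decay_components)
  stopifnot_scalar_pos(depth_sd, "depth_sd")
  stopifnot_scalar_pos(depth_mean, "depth_mean")
  structure(list(
    order_profile = order_profile, sigma_true = sigma_true,
    fcs_params = fcs_params, decay_components = decay_components,
    depth_mean = depth_mean, depth_sd = depth_sd,
    ring_angle_mean = ring_angle_mean, ring_angle_sd = ring_angle_sd,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

validate_components <- function(components) {
  components <- as.data.frame(components)
  if (!all(c("tau", "amplitude") %in% names(components))) {
    stop("decay components need columns 'tau' and 'amplitude'")
  }
  if (any(components$tau <= 0)) stop("all lifetimes must be positive")
  if (any(components$amplitude < 0)) stop("amplitudes must be non-negative")
  if (abs(sum(components$amplitude) - 1) > 1e-8) {
    stop("amplitudes must sum to 1")
  }
  components
}

#' Deuteron weights along a perdeuterated acyl chain
#'
#' Methylene carbons carry two deuterons, the terminal methyl three; for the
#' palmitoyl-d31 chain (carbons 2..16) this gives weights 2,...,2,3.
#'
#' @param n_segments number of CD segments (last one is the terminal CD3).
#' @return integer vector of deuteron counts.
#' @export
deuteron_weights <- function(n_segments) {
  if (n_segments < 1) stop("no segments")
  w <- rep(2L, n_segments)
  if (n_segments > 1) w[n_segments] <- 3L
  w
}

#' Simulate a deuterium powder spectrum from an order profile
#'
#' Builds the powder average of axially symmetric quadrupolar doublets, one
#' per chain carbon. A C--D segment with order parameter \eqn{S} gives an
#' oriented doublet at \eqn{\pm (3/4)\chi S}; at orientation \eqn{\theta} of
#' the bilayer normal the doublet scales by \eqn{(3\cos^2\theta - 1)/2}, and
#' the powder average is taken by quadrature over \eqn{u = \cos\theta}
#' uniformly on \eqn{[0, 1]} (the uniform-in-\eqn{u} grid carries the
#' \eqn{\sin\theta} orientational weight). The dominant 90-degree edges
#' ("horns") of a single segment are therefore separated by
#' \eqn{(3/4)\chi S}. Each carbon is weighted by its deuteron count.
#'
#' With \code{n_orientations >= 1e4} the quadrature agrees with the analytic
#' lineshape to well below the default line broadening; the noiseless
#' spectrum is deterministic.
#'
#' @param order_profile numeric vector of order parameters (carbon 2 first,
#'   terminal methyl last); values in \eqn{[0, 0.5]}.
#' @param coupling_khz static quadrupolar coupling constant \eqn{\chi} in
#'   kHz (default 167 for C--D).
#' @param noise_sd additive Gaussian noise sd, in units of the maximum
#'   noiseless intensity.
#' @param seed RNG seed for the noise.
#' @param freq_range_khz half spectral width; the grid spans +/- this value.
#' @param n_points number of frequency grid points.
#' @param n_orientations quadrature points over \eqn{\cos\theta}.
#' @param broadening_khz Gaussian line-broadening sd applied to the stick
#'   powder pattern.
#' @param weights deuteron count per carbon; default
#'   \code{\link{deuteron_weights}}.
#' @return a \code{powder_spectrum}: data frame with columns
#'   \code{frequency_khz}, \code{intensity}.
#' @export
make_powder_spectrum <- function(order_profile, coupling_khz = 167,
                                 noise_sd = 0, seed = NULL,
                                 freq_range_khz = 250, n_points = 2001,
                                 n_orientations = 10000,
                                 broadening_khz = 0.4,
                                 weights = deuteron_weights(length(order_profile))) {
  if (length(order_profile) == 0) stop("no segments")
  stopifnot_scalar_pos(coupling_khz, "coupling constant")
  if (length(weights) != length(order_profile)) {
    stop("weights must match order_profile in length")
  }
  freq <- seq(-freq_range_khz, freq_range_khz, length.out = n_points)
  df <- freq[2] - freq[1]
  # midpoint rule over u = cos(theta)
  u <- (seq_len(n_orientations) - 0.5) / n_orientations
  scal <- (3 * u^2 - 1) / 2
  intensity <- numeric(n_points)
  f0 <- 0.75 * coupling_khz * order_profile  # oriented (0 deg) component position
  for (k in seq_along(f0)) {
    for (sgn in c(-1, 1)) {
      pos <- sgn * f0[k] * scal
      # deposit du mass per orientation with linear interpolation between bins
      idx <- (pos - freq[1]) / df
      i0 <- floor(idx)
      frac <- idx - i0
      keep <- i0 >= 0 & i0 < n_points - 1
      w <- weights[k] / n_orientations
      if (any(keep)) {
        intensity <- intensity +
          rowsum_into(i0[keep] + 1L, (1 - frac[keep]) * w, n_points) +
          rowsum_into(i0[keep] + 2L, frac[keep] * w, n_points)
      }
    }
  }
  if (broadening_khz > 0) {
    intensity <- gauss_smooth(intensity, broadening_khz / df)
  }
  peak <- max(intensity)
  if (peak > 0) intensity <- intensity / peak
  if (noise_sd > 0) {
    intensity <- intensity + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  }
  structure(data.frame(frequency_khz = freq, intensity = intensity),
            class = c("powder_spectrum", "data.frame"),
            broadening_khz = broadening_khz)
}

# Accumulate weights w at integer positions idx into a length-n vector.
rowsum_into <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Gaussian smoothing with kernel sd given in grid points; conserves mass.
gauss_smooth <- function(y, sd_pts) {
  if (sd_pts <= 0) return(y)
  half <- max(1L, ceiling(4 * sd_pts))
  kern <- stats::dnorm(seq(-half, half), sd = sd_pts)
  kern <- kern / sum(kern)
  n <- length(y)
  padded <- c(numeric(half), y, numeric(half))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Simulate NOESY buildup volumes for a set of lipid groups
#'
#' Generates cross-peak and diagonal-peak volumes of one metabolite proton
#' against each lipid functional group under the two-spin (spin-pair) model:
#' with cross-relaxation rate \eqn{\sigma} and leakage rate \eqn{\rho}, the
#' normalized cross volume at mixing time \eqn{\tau_m} is
#' \deqn{a(\tau_m) = \tfrac12 e^{-\rho\tau_m}(e^{\sigma\tau_m} -
#'   e^{-\sigma\tau_m})}
#' and the diagonal is \eqn{\tfrac12 e^{-\rho\tau_m}(e^{\sigma\tau_m} +
#' e^{-\sigma\tau_m})}. The default mixing times are 0.1, 100, 200, 300 and
#' 500 ms; the 0.1 ms point serves as the reference magnetization.
#'
#' @param sigma_true named numeric vector of cross-relaxation rates (1/s).
#' @param rho_leak leakage/auto-relaxation rate (1/s), scalar or one per
#'   group; must satisfy \code{rho_leak >= abs(sigma_true)}.
#' @param mixing_times mixing times in seconds (all >= 0).
#' @param noise_frac multiplicative Gaussian noise fraction.
#' @param seed RNG seed.
#' @param proton label for the metabolite proton column.
#' @param scale overall volume scale (arbitrary units).
#' @return long-format data frame with columns \code{proton},
#'   \code{lipid_group}, \code{mixing_time_s}, \code{cross_volume},
#'   \code{diagonal_volume}.
#' @export
make_noesy_volumes <- function(sigma_true, rho_leak,
                               mixing_times = c(1e-4, 0.1, 0.2, 0.3, 0.5),
                               noise_frac = 0, seed = NULL,
                               proton = "H1", scale = 1000) {
  if (any(mixing_times < 0)) stop("negative mixing time")
  if (is.null(names(sigma_true))) stop("sigma_true must be named by lipid group")
  rho <- rep_len(rho_leak, length(sigma_true))
  if (any(rho < abs(sigma_true))) {
    stop("rho_leak must be >= |sigma| for every group")
  }
  grid <- expand.grid(lipid_group = names(sigma_true),
                      mixing_time_s = mixing_times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- sigma_true[grid$lipid_group]
  r <- stats::setNames(rho, names(sigma_true))[grid$lipid_group]
  tm <- grid$mixing_time_s
  cross <- scale * exp(-r * tm) * sinh(s * tm)
  diag <- scale * exp(-r * tm) * cosh(s * tm)
  if (noise_frac > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * length(cross), 0, noise_frac))
    cross <- cross * (1 + noise[seq_along(cross)])
    diag <- diag * (1 + noise[length(cross) + seq_along(diag)])
  }
  data.frame(proton = proton, grid,
             cross_volume = as.numeric(cross),
             diagonal_volume = as.numeric(diag),
             row.names = NULL)
}

#' Simulate an FCS autocorrelation trace
#'
#' Evaluates the two-component three-dimensional diffusion model with a
#' triplet component (see \code{\link{model_g}}) on a log-spaced lag grid
#' and adds lag-dependent Gaussian noise: the sd at each lag is
#' \code{noise_frac} times the local correlation amplitude above background,
#' plus a floor of 5\% of the zero-lag amplitude so the tail is not
#' noise-free.
#'
#' @param params an \code{\link{fcs_params}} object (ground truth).
#' @param lag_grid positive, strictly increasing lag times (s); default 200
#'   points log-spaced over 1e-7..1 s.
#' @param noise_frac relative noise level (e.g. 0.02 for 2\%).
#' @param seed RNG seed.
#' @return an \code{fcs_trace}: data frame with columns \code{lag_s},
#'   \code{g}.
#' @export
make_fcs_trace <- function(params,
                           lag_grid = 10^seq(-7, 0, length.out = 200),
                           noise_frac = 0, seed = NULL) {
  stopifnot(inherits(params, "fcs_params"))
  if (any(lag_grid <= 0) || is.unsorted(lag_grid, strictly = TRUE)) {
    stop("lags must be positive and strictly increasing")
  }
  g <- model_g(lag_grid, params)
  if (noise_frac > 0) {
    amp <- g - params$bl
    amp0 <- model_g(min(lag_grid), params) - params$bl
    sd_lag <- noise_frac * (abs(amp) + 0.05 * abs(amp0))
    g <- g + with_seed(seed, stats::rnorm(length(g), 0, sd_lag))
  }
  structure(data.frame(lag_s = lag_grid, g = g),
            class = c("fcs_trace", "data.frame"))
}

#' Simulate a TCSPC fluorescence decay histogram
#'
#' Poisson-samples a multi-exponential decay on a fixed channel grid. Each
#' component contributes an exponential of amplitude fraction
#' \code{amplitude} at the decay origin, convolved with a Gaussian
#' instrument response of sd \code{irf_width_ps}. Total expected counts are
#' \code{counts_total}.
#'
#' @param components data frame with columns \code{tau} (ns) and
#'   \code{amplitude} (fractions summing to 1).
#' @param irf_width_ps Gaussian IRF sd in picoseconds (default 50).
#' @param counts_total total expected photon count (> 0).
#' @param seed RNG seed.
#' @param t_max_ns,n_channels histogram window (ns) and channel count.
#' @param t0_ns decay origin (IRF center position) within the window.
#' @param background_frac fraction of counts in a flat background.
#' @return a \code{decay_histogram}: data frame with columns \code{time_ns},
#'   \code{counts}; attributes record \code{t0_ns}, \code{irf_width_ps} and
#'   the generating components.
#' @export
make_decay <- function(components, irf_width_ps = 50, counts_total,
                       seed = NULL, t_max_ns = 100, n_channels = 4096,
                       t0_ns = 5, background_frac = 0) {
  components <- validate_components(components)
  if (missing(counts_total) || counts_total <= 0) {
    stop("counts_total must be positive")
  }
  dt <- t_max_ns / n_channels
  t <- (seq_len(n_channels) - 0.5) * dt
  sigma <- irf_width_ps / 1000
  shape <- numeric(n_channels)
  for (k in seq_len(nrow(components))) {
    shape <- shape + components$amplitude[k] *
      exgauss_amp(t, t0_ns, components$tau[k], sigma)
  }
  shape <- shape * (1 - background_frac) / sum(shape) +
    background_frac / n_channels
  lambda <- counts_total * shape
  counts <- with_seed(seed, stats::rpois(n_channels, lambda))
  structure(data.frame(time_ns = t, counts = counts),
            class = c("decay_histogram", "data.frame"),
            t0_ns = t0_ns, irf_width_ps = irf_width_ps,
            components = components)
}

# Amplitude-form exponential decay convolved with a Gaussian of sd sigma:
# tends to exp(-(t - t0)/tau) far past t0 and to 0 far before it.
exgauss_amp <- function(t, t0, tau, sigma) {
  if (sigma <= 0) {
    return(ifelse(t >= t0, exp(-(t - t0) / tau), 0))
  }
  loge <- sigma^2 / (2 * tau^2) - (t - t0) / tau +
    stats::pnorm((t - t0) / sigma - sigma / tau, log.p = TRUE)
  exp(loge)
}

# ---------------------------------------------------------------------------
# Bilayer coordinate ensembles

# Rigid indole-like template (nm), aligned so that the ring long axis
# (C2 -> midpoint of C5-C6) is exactly +z and C2 sits at the origin.
# H1 is bonded to N1 and HN to the side-chain amine N, so hydrogen-bond
# geometry can be evaluated on generated frames.
indole_template <- function() {
  raw <- rbind(
    C2 = c(0.00, 0, 0.00),
    C3 = c(0.12, 0, 0.08),
    C4 = c(0.22, 0, 0.20),
    C5 = c(0.18, 0, 0.40),
    C6 = c(-0.02, 0, 0.48),
    C7 = c(-0.14, 0, 0.36),
    N1 = c(-0.10, 0, 0.10),
    N  = c(0.25, 0, -0.15),
    H1 = c(-0.20, 0, 0.04),
    HN = c(0.33, 0, -0.22)
  )
  colnames(raw) <- c("x", "y", "z")
  v <- (raw["C5", ] + raw["C6", ]) / 2 - raw["C2", ]
  v <- v / sqrt(sum(v^2))
  # rotation taking v to +z (Rodrigues about axis v x z)
  z <- c(0, 0, 1)
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2)); c_ <- sum(v * z)
  if (s < 1e-12) {
    rot <- diag(3) * sign(c_)
  } else {
    k <- axis / s
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
    rot <- diag(3) + s * kx + (1 - c_) * kx %*% kx
  }
  out <- raw %*% t(rot)
  sweep(out, 2, out["C2", ])
}

rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

#' Generate a synthetic bilayer coordinate ensemble
#'
#' Builds frames containing (i) pseudo-lipid phosphate beads on two flat
#' leaflets placed mirror-symmetrically about the bilayer midplane, so their
#' mean z defines the bilayer center exactly; (ii) rigid indole-template
#' ligands whose minimum heavy-atom distance to the midplane is drawn from
#' \code{N(depth_mean, depth_sd)} and whose ring long axis makes an angle
#' drawn from \code{N(ring_angle_mean, ring_angle_sd)} with the bilayer
#' normal (azimuth uniform); and (iii) optional water beads excluded from
#' \code{|z| < water_min_dist}, with an optional depletion band emulating
#' reduced interfacial hydration.
#'
#' The bilayer is flat by construction (no undulations): every analyzed
#' statistic is referenced to the midplane z, so curvature would only blur
#' the ground truth the recovery tests rely on.
#'
#' @param n_frames,n_ligands number of frames and ligand copies per frame.
#' @param depth_mean,depth_sd Gaussian parameters (nm) of the minimum
#'   heavy-atom distance to the bilayer center.
#' @param ring_angle_mean,ring_angle_sd Gaussian parameters (degrees) of the
#'   ring-axis tilt from the bilayer normal.
#' @param box box dimensions in nm, length 3 (bilayer normal along z).
#' @param seed RNG seed.
#' @param n_lipids_per_leaflet pseudo-lipid beads per leaflet.
#' @param leaflet_offset mean |z| of the pseudo-lipid beads (nm).
#' @param n_waters water beads per frame (0 to omit).
#' @param water_min_dist minimum |z| from the midplane for water (nm).
#' @param water_depletion_band optional length-2 vector (nm): |z| band in
#'   which water is thinned.
#' @param water_depletion_frac fraction of water removed inside the band.
#' @return a \code{\link{frame_ensemble}}.
#' @export
make_bilayer_frames <- function(n_frames, n_ligands, depth_mean, depth_sd,
                                ring_angle_mean = 90, ring_angle_sd = 30,
                                box = c(8, 8, 10), seed = NULL,
                                n_lipids_per_leaflet = 64,
                                leaflet_offset = 2.2,
                                n_waters = 0, water_min_dist = 1.5,
                                water_depletion_band = NULL,
                                water_depletion_frac = 0) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  box <- rep_len(box, 3)
  if (depth_mean > box[3] / 2) stop("depth_mean exceeds half the box height")
  if (depth_sd < 0) stop("depth_sd must be >= 0")
  zc <- box[3] / 2
  tmpl <- indole_template()
  heavy <- !grepl("^H", rownames(tmpl))
  n_t <- nrow(tmpl)

  atoms <- data.frame(
    name = c(rep("PL", 2 * n_lipids_per_leaflet),
             rep(rownames(tmpl), n_ligands),
             rep("OW", n_waters)),
    resname = c(rep("LIP", 2 * n_lipids_per_leaflet),
                rep("LIG", n_t * n_ligands),
                rep("WAT", n_waters)),
    resid = c(rep(seq_len(2 * n_lipids_per_leaflet), each = 1),
              1000 + rep(seq_len(n_ligands), each = n_t),
              5000 + seq_len(max(n_waters, 0))),
    stringsAsFactors = FALSE
  )
  n_atoms <- nrow(atoms)
  coords <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
    for (fr in seq_len(n_frames)) {
      # mirrored lipid beads: mean z is exactly zc
      dz <- leaflet_offset + stats::rnorm(n_lipids_per_leaflet, 0, 0.08)
      lx <- stats::runif(2 * n_lipids_per_leaflet, 0, box[1])
      ly <- stats::runif(2 * n_lipids_per_leaflet, 0, box[2])
      lip <- cbind(lx, ly, zc + c(dz, -dz))
      lig <- matrix(NA_real_, n_t * n_ligands, 3)
      for (l in seq_len(n_ligands)) {
        depth <- max(stats::rnorm(1, depth_mean, depth_sd), 0.05)
        ang <- stats::rnorm(1, ring_angle_mean, ring_angle_sd) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        xyz <- tmpl %*% t(rot_y(ang)) %*% t(rot_z(phi))
        zbase <- zc + depth - min(xyz[heavy, 3])
        xyz <- sweep(xyz, 2, c(stats::runif(1, 0.5, box[1] - 0.5),
                               stats::runif(1, 0.5, box[2] - 0.5),
                               zbase), "+")
        lig[(l - 1) * n_t + seq_len(n_t), ] <- xyz
      }
      wat <- NULL
      if (n_waters > 0) {
        wz <- numeric(0)
        while (length(wz) < n_waters) {
          cand <- stats::runif(n_waters, water_min_dist, zc)
          if (!is.null(water_depletion_band) && water_depletion_frac > 0) {
            inband <- cand >= water_depletion_band[1] &
              cand <= water_depletion_band[2]
            keep <- !inband | stats::runif(n_waters) > water_depletion_frac
            cand <- cand[keep]
          }
          wz <- c(wz, cand)
        }
        wz <- wz[seq_len(n_waters)] * sample(c(-1, 1), n_waters, replace = TRUE)
        wat <- cbind(stats::runif(n_waters, 0, box[1]),
                     stats::runif(n_waters, 0, box[2]), zc + wz)
      }
      arr[, , fr] <- rbind(lip, lig, wat)
    }
    arr
  })
  frame_ensemble(atoms, coords, box)
}
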