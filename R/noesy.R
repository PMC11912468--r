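# NOESY spin-pair cross-relaxation fitting and membrane depth mapping.

#' Fit the two-spin (spin-pair) model to a NOESY buildup series
#'
#' Cross-peak volumes are normalized by the diagonal volume at the shortest
#' mixing time (the reference magnetization) and fitted by least squares to
#' the two-spin solution
#' \deqn{a(\tau_m) = \tfrac12 e^{-\rho\tau_m}\,(e^{\sigma\tau_m} -
#'   e^{-\sigma\tau_m}),}
#' where \eqn{\sigma} is the cross-relaxation rate and \eqn{\rho} the
#' leakage (auto-relaxation) rate. The initial buildup slope equals
#' \eqn{\sigma}, which also seeds the fit. Spin diffusion beyond the two
#' spins is deliberately ignored (spin-pair approximation).
#'
#' @param series data frame with columns \code{mixing_time_s},
#'   \code{cross_volume}, \code{diagonal_volume} for one (proton, lipid
#'   group) pair; at least 4 mixing times, one much shorter than the rest.
#' @return a \code{spin_pair_fit} list: \code{sigma}, \code{rho} (1/s),
#'   \code{residuals}, \code{fitted}, \code{degenerate} (TRUE when the
#'   buildup is flat and \code{sigma} is forced to 0).
#' @export
fit_spin_pair <- function(series) {
  series <- series[order(series$mixing_time_s), , drop = FALSE]
  tm <- series$mixing_time_s
  if (length(tm) < 4) stop("need at least 4 mixing times")
  ref <- series$diagonal_volume[1]
  if (!is.finite(ref) || ref <= 0) {
    stop("diagonal volume at the shortest mixing time must be positive")
  }
  a <- series$cross_volume / ref
  model <- function(sigma, rho, t) 0.5 * exp(-rho * t) *
    (exp(sigma * t) - exp(-sigma * t))
  # degenerate: no detectable transfer
  if (max(abs(a)) < 1e-12) {
    warning("flat buildup: sigma set to 0")
    return(structure(list(sigma = 0, rho = NA_real_, residuals = a,
                          fitted = a * 0, degenerate = TRUE),
                     class = "spin_pair_fit"))
  }
  # initial slope estimate from the shortest informative interval
  i2 <- which(tm > tm[1])[1]
  sigma0 <- a[i2] / tm[i2]
  if (!is.finite(sigma0) || sigma0 == 0) sigma0 <- sign(a[which.max(abs(a))]) * 0.01
  fit <- minpack.lm::nls.lm(
    par = list(sigma = sigma0, rho = max(1, abs(sigma0))),
    fn = function(p) model(p$sigma, p$rho, tm) - a,
    lower = c(-Inf, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(stats::coef(fit))
  fitted <- model(p$sigma, p$rho, tm)
  structure(list(sigma = p$sigma, rho = p$rho,
                 residuals = a - fitted, fitted = fitted,
                 degenerate = FALSE),
            class = "spin_pair_fit")
}

#' Fit spin-pair rates for every (proton, lipid group) series in a table
#'
#' @param volumes long-format data frame with columns \code{proton},
#'   \code{lipid_group}, \code{mixing_time_s}, \code{cross_volume},
#'   \code{diagonal_volume} (the format written by
#'   \code{\link{make_noesy_volumes}}).
#' @return a \code{cross_relaxation_set}: data frame with one row per
#'   (proton, lipid_group), columns \code{sigma}, \code{rho}, \code{rss},
#'   \code{degenerate}.
#' @export
fit_cross_relaxation <- function(volumes) {
  key <- interaction(volumes$proton, volumes$lipid_group, drop = TRUE)
  rows <- lapply(split(volumes, key), function(d) {
    f <- fit_spin_pair(d)
    data.frame(proton = d$proton[1], lipid_group = d$lipid_group[1],
               sigma = f$sigma, rho = f$rho,
               rss = sum(f$residuals^2), degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out[order(out$proton, out$lipid_group), ],
            class = c("cross_relaxation_set", "data.frame"))
}

#' Load lipid functional-group z-distributions
#'
#' Reads a wide table (column \code{z_angstrom} plus one density column per
#' lipid functional group), validates non-negativity, renormalizes each
#' density to unit integral (with a warning when the input was not
#' normalized), and re-references the z origin so that the mean position of
#' the reference group (terminal CH3 by default) is zero -- the convention
#' used throughout the depth mapping.
#'
#' @param source a data frame or the path of a tab/whitespace-separated file.
#' @param reference_group group whose mean z defines the origin; set to
#'   \code{NULL} to keep the input origin.
#' @return a \code{group_distributions} list: \code{z} (Angstrom) and
#'   \code{density}, a named list of unit-integral densities.
#' @export
load_group_distributions <- function(source, reference_group = "CH3") {
  tab <- if (is.character(source)) {
    utils::read.table(source, header = TRUE, check.names = FALSE)
  } else {
    as.data.frame(source, check.names = FALSE)
  }
  if (!"z_angstrom" %in% names(tab)) stop("table needs a z_angstrom column")
  z <- tab$z_angstrom
  groups <- setdiff(names(tab), "z_angstrom")
  dens <- lapply(groups, function(g) {
    d <- tab[[g]]
    if (any(d < 0)) stop(sprintf("negative densities in group '%s'", g))
    tot <- trapz_int(z, d)
    if (tot <= 0) stop(sprintf("group '%s' has zero integral", g))
    if (abs(tot - 1) > 1e-6) {
      warning(sprintf("group '%s' renormalized (integral was %.4g)", g, tot))
    }
    d / tot
  })
  names(dens) <- groups
  if (!is.null(reference_group)) {
    if (!reference_group %in% groups) {
      warning(sprintf("reference group '%s' absent; z origin kept",
                      reference_group))
    } else {
      mu <- trapz_int(z, z * dens[[reference_group]])
      z <- z - mu
    }
  }
  structure(list(z = z, density = dens), class = "group_distributions")
}

#' Synthetic default lipid functional-group distributions
#'
#' A stand-in table of Gaussian z-distributions for the POPC functional
#' groups used in the depth mapping (terminal CH3 at the origin, then the
#' chain, glycerol, phosphate and choline groups at increasing distance from
#' the bilayer midplane). Means and widths are field-plausible placeholders,
#' not simulation output; substitute measured distributions via
#' \code{\link{load_group_distributions}} for real analyses.
#'
#' @param z_step grid spacing in Angstrom.
#' @return a wide data frame suitable for
#'   \code{\link{load_group_distributions}}.
#' @export
synthetic_group_distributions <- function(z_step = 0.5) {
  z <- seq(-10, 35, by = z_step)
  gaussians <- list(
    CH3 = c(0, 3.0), CH2 = c(4, 3.5), `CH2-C=` = c(8, 3.0), `=CH` = c(9, 3.0),
    C3 = c(11, 2.5), C2 = c(12, 2.5), G1 = c(13, 2.2), G2 = c(14, 2.2),
    G3 = c(15, 2.2), phosphate = c(17, 2.0), `choline-a` = c(18.5, 2.0),
    `choline-b` = c(19.5, 2.0), `choline-g` = c(20.5, 2.2))
  out <- data.frame(z_angstrom = z, check.names = FALSE)
  for (g in names(gaussians)) {
    out[[g]] <- stats::dnorm(z, gaussians[[g]][1], gaussians[[g]][2])
  }
  out
}

#' Build a membrane depth profile from cross-relaxation rates
#'
#' Multiplies each lipid functional group's z-distribution by the
#' cross-relaxation rate from that group to the metabolite proton and sums
#' over groups:
#' \deqn{A(z) = \sum_g \sigma_g \, p_g(z).}
#' The result estimates where in the membrane the proton resides; its
#' amplitude carries the units of the transfer rate, so it is not a
#' normalized probability density. Distributions are resampled onto a
#' common z grid by linear interpolation.
#'
#' @param rates named numeric vector of rates \eqn{\sigma_g} (1/s), or a
#'   \code{cross_relaxation_set} restricted to one proton.
#' @param dists a \code{group_distributions} object.
#' @param z_step output grid spacing (Angstrom).
#' @param proton_counts optional named vector: divide each rate by the
#'   number of equivalent protons in the group before summing.
#' @return a \code{depth_profile}: data frame with columns \code{z},
#'   \code{amplitude}.
#' @export
build_depth_profile <- function(rates, dists, z_step = 0.5,
                                proton_counts = NULL) {
  if (inherits(rates, "cross_relaxation_set") || is.data.frame(rates)) {
    if (length(unique(rates$proton)) > 1) {
      stop("restrict the rate set to a single proton")
    }
    rates <- stats::setNames(rates$sigma, rates$lipid_group)
  }
  missing_g <- setdiff(names(rates), names(dists$density))
  if (length(missing_g) > 0) {
    stop(sprintf("no distribution for group(s): %s",
                 paste(missing_g, collapse = ", ")))
  }
  if (!is.null(proton_counts)) {
    rates <- rates / proton_counts[names(rates)]
  }
  zg <- seq(min(dists$z), max(dists$z), by = z_step)
  amp <- numeric(length(zg))
  for (g in names(rates)) {
    amp <- amp + rates[[g]] * interp_zero(dists$z, dists$density[[g]], zg)
  }
  structure(data.frame(z = zg, amplitude = amp),
            class = c("depth_profile", "data.frame"))
}

#' Summarize a depth profile
#'
#' Reports the location of the maximum, the amplitude-weighted mean z, the
#' full width at half maximum, and a multimodality flag set when two or more
#' local maxima exceed half the global maximum.
#'
#' @param profile a \code{depth_profile}.
#' @return list with \code{mode_z}, \code{mean_z}, \code{fwhm},
#'   \code{multimodal}.
#' @export
profile_summary <- function(profile) {
  z <- profile$z
  a <- profile$amplitude
  if (max(a) <= 0) stop("zero profile")
  mode_z <- z[which.max(a)]
  mean_z <- sum(z * a) / sum(a)
  half <- max(a) / 2
  above <- a >= half
  lo <- cross_at(z, a, half, which(above)[1], -1)
  hi <- cross_at(z, a, half, rev(which(above))[1], +1)
  pk <- pracma::findpeaks(a, minpeakheight = half)
  n_modes <- if (is.null(pk)) as.integer(above[1] || above[length(a)]) else nrow(pk)
  list(mode_z = mode_z, mean_z = mean_z, fwhm = hi - lo,
       multimodal = n_modes >= 2)
}

# Linear interpolation of the half-max crossing adjacent to index i in
# direction dir (-1 left edge, +1 right edge).
cross_at <- function(z, a, level, i, dir) {
  j <- i + dir
  if (j < 1 || j > length(z) || a[j] >= level) return(z[i])
  z[i] + (z[j] - z[i]) * (level - a[i]) / (a[j] - a[i])
}
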