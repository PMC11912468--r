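# Fluorescence correlation spectroscopy: two-component 3D diffusion with a
# triplet component, and hydrodynamic radii calibrated against a free-dye
# standard.

fcs_param_names <- c("f", "tau_t", "tau_d1", "tau_d2", "g1", "g2", "a", "bl")

#' Construct an FCS parameter set
#'
#' Parameters of the two-component three-dimensional diffusion + triplet
#' autocorrelation model (see \code{\link{model_g}}): triplet fraction
#' \code{f} in \eqn{[0, 1)}, triplet lifetime \code{tau_t} (s), diffusion
#' times \code{tau_d1 <= tau_d2} (s) of the two diffusing species with
#' amplitudes \code{g1}, \code{g2 >= 0}, structure parameter \code{a}
#' (axial-to-lateral aspect ratio \eqn{z_0/w_0} of the Gaussian focal
#' volume, > 0), and background offset \code{bl}. The amplitudes are not
#' constrained to sum to 1; report fractions as \eqn{g_i / \sum g}.
#'
#' @param f,tau_t,tau_d1,tau_d2,g1,g2,a,bl model parameters (see above).
#' @return an \code{fcs_params} list.
#' @export
fcs_params <- function(f = 0, tau_t = 1e-6, tau_d1, tau_d2 = tau_d1,
                       g1 = 1, g2 = 0, a = 5, bl = 0) {
  if (f < 0 || f >= 1) stop("triplet fraction f must lie in [0, 1)")
  stopifnot_scalar_pos(tau_t, "tau_t")
  stopifnot_scalar_pos(tau_d1, "tau_d1")
  stopifnot_scalar_pos(tau_d2, "tau_d2")
  stopifnot_scalar_pos(a, "structure parameter a")
  if (g1 < 0 || g2 < 0) stop("amplitudes must be non-negative")
  if (tau_d1 > tau_d2) stop("convention requires tau_d1 <= tau_d2")
  structure(list(f = f, tau_t = tau_t, tau_d1 = tau_d1, tau_d2 = tau_d2,
                 g1 = g1, g2 = g2, a = a, bl = bl),
            class = "fcs_params")
}

#' Evaluate the FCS autocorrelation model
#'
#' \deqn{G(\tau) = \left[1 + \frac{f}{1-f} e^{-\tau/\tau_t}\right]
#'   \sum_{i=1,2} g_i \left(1 + \frac{\tau}{\tau_{Di}}\right)^{-1}
#'   \left(1 + \frac{\tau}{a^2 \tau_{Di}}\right)^{-1/2} + bl}
#'
#' Each diffusing species contributes a 3D Gaussian-volume diffusion factor;
#' the prefactor models fast triplet blinking; \code{bl} is the long-lag
#' background. At \eqn{\tau = \tau_{Di}} the i-th diffusion factor equals
#' \eqn{\tfrac12 (1 + a^{-2})^{-1/2}}.
#'
#' @param lag lag times (s).
#' @param params an \code{\link{fcs_params}} object.
#' @return correlation amplitudes at \code{lag}.
#' @export
model_g <- function(lag, params) {
  p <- params
  diff_term <- function(tau_d) {
    p_g <- (1 + lag / tau_d)^(-1) * (1 + lag / (p$a^2 * tau_d))^(-0.5)
    p_g
  }
  trip <- 1 + (p$f / (1 - p$f)) * exp(-lag / p$tau_t)
  trip * (p$g1 * diff_term(p$tau_d1) + p$g2 * diff_term(p$tau_d2)) + p$bl
}

#' Fit the FCS model to an autocorrelation trace
#'
#' Nonlinear least squares (Levenberg--Marquardt, uniform weights in
#' log-spaced lag) of \code{\link{model_g}} to a measured trace. Any subset
#' of parameters can be held fixed -- typically the structure parameter
#' \code{a} (from instrument calibration) and \code{tau_d1} (the free-dye
#' diffusion time). Positivity of times/amplitudes and \eqn{f \in [0, 1)}
#' are enforced through internal log / logit transforms.
#'
#' Starting values default to trace heuristics: background from the tail,
#' total amplitude from the shortest lags, diffusion times from the lags at
#' which the correlation has lost one and three quarters of its amplitude.
#'
#' @param trace data frame with columns \code{lag_s}, \code{g} (at least 50
#'   points spanning several decades).
#' @param init optional \code{\link{fcs_params}} with starting values.
#' @param fixed character vector of parameter names to hold at their
#'   \code{init} values.
#' @return an \code{fcs_fit} list: \code{params} (an \code{fcs_params}),
#'   \code{residuals}, \code{converged}, \code{degenerate} (diffusive
#'   amplitude indistinguishable from zero), \code{rss}.
#' @export
fit_fcs <- function(trace, init = NULL, fixed = character()) {
  lag <- trace$lag_s
  g <- trace$g
  if (length(lag) < 50) stop("need at least 50 lag points")
  if (diff(range(log10(lag))) < 4) {
    warning("lag range spans fewer than 4 decades; fit may be ill-conditioned")
  }
  if (is.null(init)) init <- fcs_init_heuristic(lag, g)
  bad <- setdiff(fixed, fcs_param_names)
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))

  to_internal <- function(p) c(
    f = stats::qlogis(min(max(p$f, 1e-6), 0.999)),
    tau_t = log(p$tau_t), tau_d1 = log(p$tau_d1), tau_d2 = log(p$tau_d2),
    g1 = log(max(p$g1, 1e-12)), g2 = log(max(p$g2, 1e-12)),
    a = log(p$a), bl = p$bl)
  from_internal <- function(th) list(
    f = stats::plogis(th[["f"]]), tau_t = exp(th[["tau_t"]]),
    tau_d1 = exp(th[["tau_d1"]]), tau_d2 = exp(th[["tau_d2"]]),
    g1 = exp(th[["g1"]]), g2 = exp(th[["g2"]]),
    a = exp(th[["a"]]), bl = th[["bl"]])

  th0 <- to_internal(init)
  free <- setdiff(fcs_param_names, fixed)
  resid_fn <- function(th_free) {
    th <- th0
    th[free] <- th_free
    p <- from_internal(th)
    model_g(lag, structure(p, class = "fcs_params")) - g
  }
  fit <- minpack.lm::nls.lm(par = th0[free], fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  th <- th0
  th[free] <- stats::coef(fit)
  p <- from_internal(th)
  # restore the tau_d1 <= tau_d2 convention when both were free
  if (!any(c("tau_d1", "tau_d2") %in% fixed) && p$tau_d1 > p$tau_d2) {
    p[c("tau_d1", "tau_d2")] <- p[c("tau_d2", "tau_d1")]
    p[c("g1", "g2")] <- p[c("g2", "g1")]
  }
  params <- structure(p, class = "fcs_params")
  res <- model_g(lag, params) - g
  amp_obs <- diff(range(g))
  degenerate <- (p$g1 + p$g2) < max(1e-3 * amp_obs, 1e-6)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("FCS fit did not converge; returning best-so-far parameters")
  }
  structure(list(params = params, residuals = res, converged = converged,
                 degenerate = degenerate, rss = sum(res^2)),
            class = "fcs_fit")
}

# Heuristic starting values from the trace itself.
fcs_init_heuristic <- function(lag, g) {
  n <- length(g)
  tail_i <- lag >= stats::quantile(lag, 0.9)
  bl0 <- mean(g[tail_i])
  head_g <- mean(g[seq_len(max(3, n %/% 50))])
  amp0 <- max(head_g - bl0, 1e-6)
  # lags where the amplitude has decayed to 3/4 and 1/4 of its start
  dec <- (g - bl0) / amp0
  lag_at <- function(level) {
    i <- which(dec <= level)[1]
    if (is.na(i)) lag[n] else lag[max(i, 2)]
  }
  fcs_params(f = 0.05, tau_t = max(min(lag) * 5, 1e-7),
             tau_d1 = lag_at(0.75), tau_d2 = max(lag_at(0.25), lag_at(0.75) * 2),
             g1 = amp0 / 2, g2 = amp0 / 2, a = 5, bl = bl0)
}

#' Convert a diffusion time to a hydrodynamic radius
#'
#' At fixed focal geometry, temperature and viscosity the Stokes--Einstein
#' relation makes the focal-transit diffusion time proportional to the
#' hydrodynamic radius, so a species with diffusion time \code{tau_d} has
#' \deqn{R_H = R_{H,cal} \cdot \tau_D / \tau_{D,cal}.}
#' The default calibration is free rhodamine B in HEPES buffer at 25 C:
#' \eqn{\tau_D = 27\,\mu s}, \eqn{R_H = 0.58} nm.
#'
#' @param tau_d diffusion time(s) in seconds.
#' @param cal_tau calibration diffusion time (s).
#' @param cal_rh calibration hydrodynamic radius (nm).
#' @return hydrodynamic radius in nm.
#' @export
radius_from_tau <- function(tau_d, cal_tau = 27e-6, cal_rh = 0.58) {
  if (any(tau_d <= 0) || cal_tau <= 0 || cal_rh <= 0) {
    stop("diffusion times and calibration values must be positive")
  }
  cal_rh * tau_d / cal_tau
}

#' Summarize hydrodynamic radii over replicates
#'
#' @param r_h numeric vector of per-replicate radii (nm), or a list of
#'   \code{fcs_fit} objects (the vesicle component \code{tau_d2} of each is
#'   converted via \code{\link{radius_from_tau}}).
#' @param ... passed to \code{\link{radius_from_tau}} when fits are given.
#' @return a \code{hydrodynamic_result} list: \code{r_h} (mean, nm),
#'   \code{sem} (nm), \code{n}.
#' @export
replicate_summary <- function(r_h, ...) {
  if (is.list(r_h) && !is.numeric(r_h)) {
    r_h <- vapply(r_h, function(f) radius_from_tau(f$params$tau_d2, ...),
                  numeric(1))
  }
  n <- length(r_h)
  if (n < 2) stop("need at least 2 replicates")
  structure(list(r_h = mean(r_h), sem = stats::sd(r_h) / sqrt(n), n = n),
            class = "hydrodynamic_result")
}
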