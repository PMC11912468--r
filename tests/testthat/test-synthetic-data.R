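# Generators: closed-form agreement, seed contracts, input validation.

test_that("powder generator collapses to a central line for zero order", {
  sp <- make_powder_spectrum(rep(0, 5), noise_sd = 0,
                             n_points = 1001, freq_range_khz = 50)
  expect_equal(sp$frequency_khz[which.max(sp$intensity)], 0)
  # all mass within the broadening width of zero
  inside <- abs(sp$frequency_khz) < 2
  expect_gt(sum(sp$intensity[inside]) / sum(sp$intensity), 0.999)
})

test_that("single-segment powder horns sit at the 90-degree edge splitting", {
  # S = 0.2, chi = 167 kHz: horns separated by (3/4) * 167 * 0.2 = 25.05 kHz
  sp <- make_powder_spectrum(0.2, coupling_khz = 167, noise_sd = 0,
                             n_points = 4001, freq_range_khz = 40,
                             broadening_khz = 0.1)
  f <- sp$frequency_khz
  y <- sp$intensity
  sep <- f[f > 0][which.max(y[f > 0])] - f[f < 0][which.max(y[f < 0])]
  expect_equal(sep, 25.05, tolerance = 0.01)
})

test_that("powder noise respects the seed contract", {
  args <- list(order_profile = c(0.2, 0.1), noise_sd = 0.02,
               n_points = 501, freq_range_khz = 50)
  a1 <- do.call(make_powder_spectrum, c(args, seed = 11))
  a2 <- do.call(make_powder_spectrum, c(args, seed = 11))
  b <- do.call(make_powder_spectrum, c(args, seed = 12))
  clean <- do.call(make_powder_spectrum, c(args[-2], noise_sd = 0))
  expect_identical(a1$intensity, a2$intensity)
  expect_false(identical(a1$intensity, b$intensity))
  # differing seeds differ only in noise
  expect_lt(max(abs((a1$intensity - clean$intensity))), 0.02 * 6)
  expect_error(make_powder_spectrum(numeric(0)), "no segments")
})

test_that("NOESY volumes follow the two-spin closed form", {
  # sigma = 0.05/s, rho = 1/s, tau_m = 0.1 s
  v <- make_noesy_volumes(c(CH2 = 0.05), rho_leak = 1,
                          mixing_times = c(1e-4, 0.1), scale = 1)
  expected <- 0.5 * exp(-1 * 0.1) * (exp(0.05 * 0.1) - exp(-0.05 * 0.1))
  expect_equal(v$cross_volume[v$mixing_time_s == 0.1], expected,
               tolerance = 1e-12)
  # sigma = 0: no transfer at any mixing time
  v0 <- make_noesy_volumes(c(CH2 = 0), rho_leak = 1)
  expect_true(all(v0$cross_volume == 0))
  expect_error(make_noesy_volumes(c(a = 0.1), rho_leak = 1,
                                  mixing_times = c(-0.1, 0.2)),
               "negative mixing time")
  expect_error(make_noesy_volumes(c(a = 0.5), rho_leak = 0.1), "rho_leak")
})

test_that("two-spin generator matches numerical integration of the
           relaxation matrix", {
  skip_if_not_installed("deSolve")
  sigma <- 0.04; rho <- 1.5
  tms <- c(0.05, 0.1, 0.3, 0.5)
  ode_out <- deSolve::ode(
    y = c(ma = 1, mb = 0), times = c(0, tms),
    func = function(t, y, p) {
      list(c(-rho * y[1] - sigma * y[2], -sigma * y[1] - rho * y[2]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  v <- make_noesy_volumes(c(g = sigma), rho_leak = rho, mixing_times = tms,
                          scale = 1)
  expect_equal(v$cross_volume, unname(abs(ode_out[-1, "mb"])),
               tolerance = 1e-7)
})

test_that("NOESY buildup initial slope equals sigma", {
  sigma <- 0.07
  eps <- 1e-5
  v <- make_noesy_volumes(c(g = sigma), rho_leak = 2, mixing_times = eps,
                          scale = 1)
  expect_equal(v$cross_volume / eps, sigma, tolerance = 1e-4)
})

test_that("FCS trace equals the model and honors the triplet switch", {
  p <- fcs_params(f = 0, tau_t = 1e-6, tau_d1 = 27e-6, g1 = 1, a = 4, bl = 0)
  tr <- make_fcs_trace(p, lag_grid = c(1e-6, 27e-6, 1e-3))
  # at tau = tau_D the one-component factor is (1/2) (1 + 1/a^2)^(-1/2)
  expect_equal(tr$g[2], 0.5 * (1 + 1 / 16)^(-0.5), tolerance = 1e-12)
  p_trip <- fcs_params(f = 0.2, tau_t = 2e-6, tau_d1 = 27e-6, g1 = 1, a = 4)
  p_notrip <- fcs_params(f = 0, tau_t = 2e-6, tau_d1 = 27e-6, g1 = 1, a = 4)
  lags <- 10^seq(-7, -1, length.out = 80)
  g_trip0 <- model_g(lags, p_trip) /
    (1 + (0.2 / 0.8) * exp(-lags / 2e-6))
  expect_equal(g_trip0, model_g(lags, p_notrip), tolerance = 1e-12)
  expect_error(fcs_params(tau_d1 = -1), "tau_d1")
  expect_error(make_fcs_trace(p, lag_grid = c(2e-6, 1e-6)), "increasing")
})

test_that("decay generator validates inputs and has the right tail slope", {
  expect_error(make_decay(data.frame(tau = 3, amplitude = 0.7),
                          counts_total = 1e4), "sum to 1")
  expect_error(make_decay(data.frame(tau = 3, amplitude = 1),
                          counts_total = 0), "positive")
  d <- make_decay(data.frame(tau = 3, amplitude = 1), counts_total = 2e6,
                  seed = 4, t_max_ns = 40, n_channels = 2048)
  sel <- d$time_ns > 8 & d$time_ns < 20 & d$counts > 30
  slope <- stats::coef(stats::lm(log(counts) ~ time_ns, d[sel, ]))[2]
  expect_equal(unname(slope), -1 / 3, tolerance = 0.02)
})

test_that("bilayer generator honors degenerate ground truths", {
  ens <- make_bilayer_frames(n_frames = 3, n_ligands = 4,
                             depth_mean = 1.0, depth_sd = 0,
                             ring_angle_mean = 0, ring_angle_sd = 0,
                             seed = 5)
  zc <- bilayer_center_z(ens, select_atoms(ens, resname = "LIP"))
  expect_equal(zc, rep(ens$box[3] / 2, 3), tolerance = 1e-12)
  md <- min_distance_distribution(ens)
  expect_equal(unique(round(md$dist_min, 10)), 1.0)
  # ring axis parallel to the normal in every frame
  ro <- ring_orientation_distribution(ens)
  expect_lt(max(ro$angles), 1e-6)
  expect_error(make_bilayer_frames(2, 2, depth_mean = 6, depth_sd = 0.1,
                                   box = c(8, 8, 10)),
               "half the box")
})

test_that("bilayer ensembles are seed-reproducible", {
  e1 <- make_bilayer_frames(4, 3, 1.2, 0.2, 45, 10, seed = 9)
  e2 <- make_bilayer_frames(4, 3, 1.2, 0.2, 45, 10, seed = 9)
  e3 <- make_bilayer_frames(4, 3, 1.2, 0.2, 45, 10, seed = 10)
  expect_identical(e1$coords, e2$coords)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("ground-truth container enforces its invariants", {
  p <- fcs_params(tau_d1 = 27e-6, tau_d2 = 2.7e-3, g1 = 1, g2 = 0.5)
  comps <- data.frame(tau = c(0.65, 3), amplitude = c(0.3, 0.7))
  gt <- ground_truth(order_profile = plateau_profile(),
                     sigma_true = c(CH3 = 0.02), fcs_params = p,
                     decay_components = comps, depth_mean = 1.4,
                     depth_sd = 0.1, ring_angle_mean = 30,
                     ring_angle_sd = 5, seed = 1)
  expect_s3_class(gt, "ground_truth")
  expect_error(ground_truth(c(0.1, 0.2), c(CH3 = 0.02), p, comps,
                            1.4, 0.1, 30, 5, 1),
               "monotone")
  expect_error(ground_truth(plateau_profile(), c(CH3 = 0.02), p,
                            data.frame(tau = c(3, -1),
                                       amplitude = c(0.5, 0.5)),
                            1.4, 0.1, 30, 5, 1),
               "positive")
})
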