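# Spin-pair fitting and depth-profile construction.

test_that("spin-pair fit recovers generator rates without noise", {
  v <- make_noesy_volumes(c(CH2 = 0.03), rho_leak = 1.2)
  fit <- fit_spin_pair(v)
  expect_equal(fit$sigma, 0.03, tolerance = 0.01)
  expect_equal(fit$rho, 1.2, tolerance = 0.01)
  expect_false(fit$degenerate)
})

test_that("flat buildups are flagged degenerate with sigma zero", {
  v <- make_noesy_volumes(c(CH2 = 0), rho_leak = 1)
  expect_warning(fit <- fit_spin_pair(v), "flat buildup")
  expect_identical(fit$sigma, 0)
  expect_true(fit$degenerate)
})

test_that("fitted sigma matches the initial slope of the buildup", {
  sigma <- 0.05
  v <- make_noesy_volumes(c(g = sigma), rho_leak = 2,
                          mixing_times = c(1e-4, 0.05, 0.1, 0.2, 0.3, 0.5))
  fit <- fit_spin_pair(v)
  a <- v$cross_volume / v$diagonal_volume[v$mixing_time_s == 1e-4]
  slope <- (a[2] - a[1]) / (v$mixing_time_s[2] - v$mixing_time_s[1])
  expect_equal(fit$sigma, slope, tolerance = 0.05)
})

test_that("sigma recovery is unbiased over the physical parameter grid", {
  grid <- expand.grid(sigma = c(0.005, 0.02, 0.05, 0.1),
                      rho = c(0.5, 1, 2, 3))
  errs <- mapply(function(s, r) {
    v <- make_noesy_volumes(c(g = s), rho_leak = r)
    abs(fit_spin_pair(v)$sigma - s) / s
  }, grid$sigma, grid$rho)
  expect_lt(max(errs), 0.02)
})

test_that("sigma is recovered within tolerance under multiplicative noise", {
  errs <- vapply(1:50, function(i) {
    v <- make_noesy_volumes(c(g = 0.03), rho_leak = 1.2, noise_frac = 0.05,
                            seed = 300 + i)
    abs(fit_spin_pair(v)$sigma - 0.03) / 0.03
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fit_cross_relaxation handles a full volume table", {
  sig <- c(CH3 = 0.01, CH2 = 0.04, phosphate = 0.02)
  v <- make_noesy_volumes(sig, rho_leak = 1.5)
  set <- fit_cross_relaxation(v)
  expect_equal(nrow(set), 3)
  expect_equal(stats::setNames(set$sigma, set$lipid_group)[names(sig)],
               sig, tolerance = 0.01)
})

test_that("packaged synthetic distributions load normalized and
           CH3-referenced", {
  path <- system.file("extdata", "group_distributions_synthetic.tsv",
                      package = "memloc")
  dists <- suppressWarnings(load_group_distributions(path))
  one <- data.frame(z_angstrom = seq(-15, 15, 0.5),
                    CH3 = stats::dnorm(seq(-15, 15, 0.5), 0, 2) * 3)
  expect_warning(load_group_distributions(one), "renormalized")
  ints <- vapply(dists$density, function(d) pracma::trapz(dists$z, d),
                 numeric(1))
  expect_equal(unname(ints), rep(1, length(ints)), tolerance = 1e-9)
  ch3_mean <- pracma::trapz(dists$z, dists$z * dists$density$CH3)
  expect_lt(abs(ch3_mean), 1e-6)
  # shifted z origin is re-referenced back to the CH3 mean
  tab <- synthetic_group_distributions()
  tab$z_angstrom <- tab$z_angstrom + 7
  shifted <- suppressWarnings(load_group_distributions(tab))
  expect_lt(abs(pracma::trapz(shifted$z, shifted$z * shifted$density$CH3)),
            1e-6)
  neg <- synthetic_group_distributions()
  neg$CH2[3] <- -1
  expect_error(suppressWarnings(load_group_distributions(neg)), "negative")
})

test_that("depth profiles are linear in the rates", {
  dists <- suppressWarnings(
    load_group_distributions(synthetic_group_distributions()))
  # single group, sigma = 1: profile equals that group's density
  p1 <- build_depth_profile(c(CH3 = 1), dists)
  d_ref <- stats::approx(dists$z, dists$density$CH3, xout = p1$z)$y
  expect_equal(p1$amplitude, d_ref, tolerance = 1e-9)
  # additivity and scaling
  pa <- build_depth_profile(c(CH3 = 1, phosphate = 2), dists)
  pb <- build_depth_profile(c(CH3 = 1), dists)
  pc <- build_depth_profile(c(phosphate = 1), dists)
  expect_equal(pa$amplitude, pb$amplitude + 2 * pc$amplitude,
               tolerance = 1e-9)
  p3 <- build_depth_profile(c(CH3 = 3), dists)
  expect_equal(p3$amplitude, 3 * p1$amplitude, tolerance = 1e-9)
  # zero rates give a zero profile; unknown groups are named in errors
  p0 <- build_depth_profile(c(CH3 = 0, CH2 = 0), dists)
  expect_true(all(p0$amplitude == 0))
  expect_error(build_depth_profile(c(nosuch = 1), dists), "nosuch")
})

test_that("profile summaries report mode, moments and multimodality", {
  z <- seq(-10, 35, by = 0.25)
  g1 <- stats::dnorm(z, 15, 2)
  s1 <- profile_summary(structure(data.frame(z = z, amplitude = g1),
                                  class = c("depth_profile", "data.frame")))
  expect_equal(s1$mode_z, 15, tolerance = 0.25)
  expect_equal(s1$mean_z, 15, tolerance = 0.01)
  expect_equal(s1$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.05)
  expect_false(s1$multimodal)
  bim <- g1 + stats::dnorm(z, 2, 2)
  s2 <- profile_summary(structure(data.frame(z = z, amplitude = bim),
                                  class = c("depth_profile", "data.frame")))
  expect_true(s2$multimodal)
  expect_error(profile_summary(
    structure(data.frame(z = z, amplitude = 0 * z),
              class = c("depth_profile", "data.frame"))),
    "zero")
})
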