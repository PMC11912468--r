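# Shared fixtures. Expensive objects (dePaked spectra) are computed once and
# cached for the whole suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# plateau-plus-linear-decay order profile: 0.21 for carbons 2-8, then linear
# decay to 0.02 at carbon 16
plateau_profile <- function() {
  c(rep(0.21, 7), seq(0.21, 0.02, length.out = 9)[-1])
}

# noiseless powder spectrum of the plateau profile and its dePaked spectrum,
# on a grid fine enough to resolve the terminal methyl splitting
nmr_roundtrip_fixture <- function() {
  fixture("nmr_roundtrip", function() {
    prof <- plateau_profile()
    sp <- make_powder_spectrum(prof, noise_sd = 0,
                               n_points = 2401, freq_range_khz = 60)
    sym <- baseline_and_symmetrize(sp)
    list(profile = prof, spectrum = sp, symmetrized = sym,
         depaked = depake(sym))
  })
}

# small bilayer ensemble with known depth and orientation ground truth
bilayer_fixture <- function() {
  fixture("bilayer", function() {
    make_bilayer_frames(n_frames = 25, n_ligands = 10,
                        depth_mean = 1.4, depth_sd = 0.1,
                        ring_angle_mean = 30, ring_angle_sd = 5,
                        seed = 71)
  })
}

# hand-built lifetime models for bound-fraction algebra tests
lifetime_model_of <- function(tau, amplitude) {
  structure(list(components = data.frame(tau = tau, amplitude = amplitude)),
            class = "lifetime_model")
}
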