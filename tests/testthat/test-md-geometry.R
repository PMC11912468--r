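# Trajectory geometry statistics.

test_that("bilayer center is exact and translation-equivariant", {
  ens <- bilayer_fixture()
  lip <- select_atoms(ens, resname = "LIP")
  zc <- bilayer_center_z(ens, lip)
  expect_equal(zc, rep(ens$box[3] / 2, ens$n_frames), tolerance = 1e-10)
  shifted <- ens
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 1
  expect_equal(bilayer_center_z(shifted, lip), zc + 1, tolerance = 1e-10)
  expect_error(bilayer_center_z(ens, integer(0)), "at least 2")
})

test_that("depth histograms peak at the generator depth and normalize to
           the modal bin", {
  ens <- bilayer_fixture()  # depth_mean 1.4, sd 0.1
  md <- min_distance_distribution(ens)
  expect_equal(max(md$normalized), 1)
  expect_lte(abs(md$peak_bin - 1.4), 0.05)
  # totals conserve frames x ligands before normalization
  expect_equal(sum(md$counts), ens$n_frames * 10)
})

test_that("two fixed-depth populations give the expected bin ratio", {
  e1 <- make_bilayer_frames(6, 2, 1.0, 0, seed = 1)
  e2 <- make_bilayer_frames(6, 4, 1.5, 0, seed = 1)
  # merge: same atoms frame-wise is awkward, so just concatenate dist_min
  d <- c(min_distance_distribution(e1)$dist_min,
         min_distance_distribution(e2)$dist_min)
  h <- graphics::hist(d, breaks = seq(0, 2, by = 0.05), plot = FALSE)$counts
  h <- h / max(h)
  expect_equal(h[h > 0], c(0.5, 1))
})

test_that("minimum distances equal a brute-force double loop", {
  ens <- make_bilayer_frames(8, 5, 1.2, 0.3, seed = 17)
  lip <- select_atoms(ens, resname = "LIP")
  md <- min_distance_distribution(ens)
  zc <- bilayer_center_z(ens, lip)
  a <- ens$atoms
  brute <- c()
  for (fr in seq_len(ens$n_frames)) {
    for (rid in unique(a$resid[a$resname == "LIG"])) {
      best <- Inf
      for (i in seq_len(nrow(a))) {
        if (a$resname[i] != "LIG" || a$resid[i] != rid) next
        if (grepl("^H", a$name[i])) next
        best <- min(best, abs(ens$coords[i, 3, fr] - zc[fr]))
      }
      brute <- c(brute, best)
    }
  }
  expect_equal(sort(md$dist_min), sort(brute), tolerance = 1e-12)
})

test_that("distributions are invariant to rigid translation and frame
           relabeling", {
  ens <- make_bilayer_frames(10, 4, 1.3, 0.15, ring_angle_mean = 40,
                             ring_angle_sd = 8, seed = 23)
  md <- min_distance_distribution(ens)
  ro <- ring_orientation_distribution(ens)
  moved <- ens
  moved$coords <- moved$coords + 0.4  # rigid translation of every frame
  perm <- ens
  perm$coords <- perm$coords[, , sample(ens$n_frames)]
  expect_equal(min_distance_distribution(moved)$counts, md$counts)
  expect_equal(min_distance_distribution(perm)$counts, md$counts)
  expect_equal(ring_orientation_distribution(moved)$density, ro$density)
})

test_that("ring orientation reproduces hand-built geometries", {
  # one ligand: C2 at origin-ish, ring axis exactly along +z, then in-plane
  atoms <- data.frame(name = c("PL", "PL", "C2", "C5", "C6"),
                      resname = c("LIP", "LIP", "LIG", "LIG", "LIG"),
                      resid = c(1, 2, 10, 10, 10))
  up <- rbind(c(1, 1, 6), c(1, 1, 2),
              c(2, 2, 5), c(2.1, 2, 5.5), c(1.9, 2, 5.5))
  planar <- rbind(c(1, 1, 6), c(1, 1, 2),
                  c(2, 2, 5), c(2.5, 2.1, 5), c(2.5, 1.9, 5))
  e_up <- frame_ensemble(atoms, up, c(8, 8, 8))
  e_pl <- frame_ensemble(atoms, planar, c(8, 8, 8))
  expect_equal(ring_orientation_distribution(e_up)$angles, 0)
  expect_equal(ring_orientation_distribution(e_pl)$angles, 90)
  bad <- atoms; bad$name[4] <- "C9"
  expect_error(ring_orientation_distribution(
    frame_ensemble(bad, up, c(8, 8, 8))), "C5")
})

test_that("generator ring angles are recovered within a degree", {
  ens <- bilayer_fixture()  # mean 30 deg, sd 5 deg
  ro <- ring_orientation_distribution(ens)
  expect_lt(abs(ro$mean_angle - 30), 1)
  expect_equal(sum(ro$density), 1, tolerance = 1e-12)
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  # donor D--H pointing at acceptor A: linear geometry, D-A 0.28 nm
  atoms <- data.frame(name = c("N", "HN", "O"),
                      resname = c("LIG", "LIG", "LIP"),
                      resid = c(1, 1, 2))
  lin <- rbind(c(0, 0, 0), c(0, 0, 0.10), c(0, 0, 0.28))
  far <- rbind(c(0, 0, 0), c(0, 0, 0.10), c(0, 0, 0.50))
  bent <- rbind(c(0, 0, 0), c(0, 0, 0.10), c(0, 0.27, 0.05))  # ~90 degrees
  donors <- data.frame(d = 1, h = 2)
  count_of <- function(xyz) {
    hbond_count(frame_ensemble(atoms, xyz, c(4, 4, 4)), donors,
                acceptors = 3)$n_bonds
  }
  expect_equal(count_of(lin), 1)
  expect_equal(count_of(far), 0)
  expect_equal(count_of(bent), 0)
  expect_error(hbond_count(frame_ensemble(atoms, lin, c(4, 4, 4)),
                           donors[0, ], acceptors = 3), "non-empty")
})

test_that("per-molecule hydrogen bond means count bonded frames", {
  # 10 frames, exactly 4 with the bond formed -> mean 0.40
  atoms <- data.frame(name = c("N", "HN", "O"),
                      resname = c("LIG", "LIG", "LIP"),
                      resid = c(1, 1, 2))
  coords <- array(0, c(3, 3, 10))
  for (fr in 1:10) {
    coords[2, 3, fr] <- 0.10
    coords[3, 3, fr] <- if (fr <= 4) 0.28 else 0.60
  }
  hb <- hbond_count(frame_ensemble(atoms, coords, c(4, 4, 4)),
                    data.frame(d = 1, h = 2), acceptors = 3)
  expect_equal(hb$mean_per_molecule, 0.40)
})

test_that("water profiles reflect exclusion zones and depletion bands", {
  ens <- make_bilayer_frames(6, 1, 1.0, 0.05, seed = 3, n_waters = 4000,
                             water_min_dist = 1.5)
  wp <- water_penetration_profile(ens)
  expect_true(all(wp$mean_counts[wp$bin_mid < 1.45] == 0))
  # uniform slab: flat within counting noise
  slab <- wp$mean_counts[wp$bin_mid > 1.6 & wp$bin_mid < 4.4]
  expect_lt(stats::sd(slab) / mean(slab), 0.15)
  dep <- make_bilayer_frames(6, 1, 1.0, 0.05, seed = 3, n_waters = 4000,
                             water_min_dist = 1.5,
                             water_depletion_band = c(1.7, 2.1),
                             water_depletion_frac = 0.5)
  wpd <- water_penetration_profile(dep)
  band <- wpd$bin_mid > 1.75 & wpd$bin_mid < 2.05
  ref <- wpd$bin_mid > 2.5 & wpd$bin_mid < 4.4
  expect_equal(mean(wpd$mean_counts[band]) / mean(wpd$mean_counts[ref]),
               0.5, tolerance = 0.1)
})

test_that("frame ensembles round-trip through multi-model PDB text", {
  ens <- make_bilayer_frames(3, 2, 1.2, 0.1, seed = 13, n_waters = 5)
  path <- tempfile(fileext = ".pdb")
  write_frames_pdb(ens, path)
  back <- read_frames_pdb(path)
  expect_equal(back$atoms$name, ens$atoms$name)
  expect_equal(back$atoms$resid %% 100000, ens$atoms$resid %% 100000)
  expect_equal(back$coords, ens$coords, tolerance = 1e-4)  # 0.001 A records
  expect_equal(back$box, ens$box, tolerance = 1e-3)
  md1 <- min_distance_distribution(ens)
  md2 <- min_distance_distribution(back)
  expect_equal(md2$counts, md1$counts)
})

test_that("ground-truth manifests serialize to JSON", {
  gt <- ground_truth(order_profile = plateau_profile(),
                     sigma_true = c(CH3 = 0.02),
                     fcs_params = fcs_params(tau_d1 = 27e-6, tau_d2 = 2.7e-3,
                                             g1 = 1, g2 = 0.5),
                     decay_components = data.frame(tau = 3, amplitude = 1),
                     depth_mean = 1.4, depth_sd = 0.1,
                     ring_angle_mean = 30, ring_angle_sd = 5, seed = 7)
  path <- tempfile(fileext = ".json")
  write_manifest(gt, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 7L)
  expect_equal(back$fcs_params$tau_d2, 2.7e-3)
  expect_equal(back$depth_mean, 1.4)
})
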