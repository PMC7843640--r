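make_noise_traj <- function(n = 12, f = 400, sigma = 0.5, seed = 5,
                            rigid = FALSE) {
  s <- make_reference_structure(n, seed = seed)
  spec <- fluctuation_spec(n, base_sigma = sigma,
                           rigid_max_rot_deg = if (rigid) 6 else 0,
                           rigid_max_trans = if (rigid) 1.5 else 0,
                           seed = seed + 100)
  make_trajectory(s, spec, n_frames = f)
}

test_that("frames that are rigid motions of the reference give zero RMSD", {
  s <- make_reference_structure(10, seed = 3)
  spec <- fluctuation_spec(10, base_sigma = 0, rigid_max_rot_deg = 10,
                           rigid_max_trans = 3, seed = 4)
  tr <- make_trajectory(s, spec, n_frames = 20)
  rs <- trajectory_rmsd(tr)
  expect_equal(rs$rmsd_A, rep(0, 20), tolerance = 1e-9)
  expect_equal(rs$frame_time_ps, (1:20) * 400)
})

test_that("a single frame equal to the reference gives the series [0]", {
  s <- make_reference_structure(5, seed = 6)
  tr <- md_trajectory(s, array(coords(s), dim = c(nrow(s), 3, 1)))
  rs <- trajectory_rmsd(tr)
  expect_equal(rs$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(nrow(rs), 1)
})

test_that("mean RMSD of Gaussian displacements matches the closed form", {
  # E[rmsd^2] = 3 sigma^2 (3N-6)/(3N) for fitting onto the noise-free
  # reference; SE of the mean over F frames ~= sd(rmsd)/sqrt(F)
  n <- 30; f <- 800; sig <- 0.5
  tr <- make_noise_traj(n = n, f = f, sigma = sig, seed = 12)
  rs <- trajectory_rmsd(tr)
  expected <- sqrt(3 * sig^2 * (3 * n - 6) / (3 * n))
  se <- stats::sd(rs$rmsd_A) / sqrt(f)
  expect_lt(abs(mean(rs$rmsd_A) - expected), 3 * se)
})

test_that("identical frames give zero RMSF everywhere", {
  s <- make_reference_structure(6, seed = 7)
  spec <- fluctuation_spec(6, base_sigma = 0, seed = 1)
  tr <- make_trajectory(s, spec, n_frames = 3)
  expect_equal(rmsf(tr)$rmsf_A, rep(0, 6), tolerance = 1e-10)
})

test_that("isotropic sigma = 1 gives RMSF near sqrt(3) per residue", {
  n <- 25; f <- 2000
  tr <- make_noise_traj(n = n, f = f, sigma = 1.0, seed = 13, rigid = TRUE)
  prof <- rmsf(tr)
  expected <- sqrt(3) * sqrt((3 * n - 6) / (3 * n)) * sqrt((f - 1) / f)
  expect_true(all(abs(prof$rmsf_A - expected) < 3 / sqrt(2 * f)))
  expect_equal(mean(prof$rmsf_A), sqrt(3), tolerance = 0.05)
})

test_that("two sigma groups yield the planted 3:1 RMSF ratio", {
  n <- 24; f <- 2500
  s <- make_reference_structure(n, seed = 14)
  spec <- fluctuation_spec(n, base_sigma = 0.3,
                           regions = data.frame(start = 13, end = 24,
                                                sigma = 0.9),
                           seed = 15)
  prof <- rmsf(make_trajectory(s, spec, n_frames = f))
  ratio <- mean(prof$rmsf_A[13:24]) / mean(prof$rmsf_A[1:12])
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("RMSD and RMSF are invariant under a global rigid motion", {
  tr <- make_noise_traj(n = 10, f = 150, seed = 16)
  moved <- rigid_rotate_traj(tr)
  ref_sel <- coords(tr$topology)[select_atoms(tr$topology), ]
  expect_equal(trajectory_rmsd(moved, reference = ref_sel)$rmsd_A,
               trajectory_rmsd(tr)$rmsd_A, tolerance = 1e-6)
  expect_equal(rmsf(moved)$rmsf_A, rmsf(tr)$rmsf_A, tolerance = 1e-6)
})

test_that("RMSF does not depend on frame order", {
  tr <- make_noise_traj(n = 8, f = 120, seed = 17)
  perm <- tr
  set.seed(1)
  perm$coords <- perm$coords[, , sample(n_frames(tr))]
  # the two-pass procedure seeds its mean from the first frame, so order
  # independence is approximate at O(sigma / F), not exact
  expect_equal(rmsf(perm)$rmsf_A, rmsf(tr)$rmsf_A, tolerance = 1e-3)
})

test_that("selection contracts are enforced", {
  tr <- make_noise_traj(n = 6, f = 10, seed = 18)
  expect_error(trajectory_rmsd(tr, atom_selection = "ZZ"), "no atoms")
  # a selection resolving to two atoms in one residue is not per-residue
  tips <- unique(tr$topology$elety[tr$topology$elety != "CA"])
  expect_error(rmsf(tr, atom_selection = c("CA", tips)),
               "more than one atom")
  expect_error(rmsf(md_trajectory(tr$topology,
                                  tr$coords[, , 1, drop = FALSE])),
               "at least 2 frames")
})

test_that("burn-in frames are excluded from the series", {
  tr <- make_noise_traj(n = 6, f = 50, seed = 19)
  rs <- trajectory_rmsd(tr, burn_in_frames = 10)
  expect_equal(nrow(rs), 40)
  expect_equal(rs$frame_time_ps[1], 11 * 400)
})
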