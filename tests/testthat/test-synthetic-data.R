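test_that("reference structures have two atoms per residue on a 3.8 A trace", {
  s <- make_reference_structure(10, seed = 1)
  expect_equal(nrow(s), 20)
  expect_equal(n_residues(s), 10)
  ca <- coords(s)[s$elety == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(d >= 3.7 & d <= 3.9))
  # deterministic
  expect_identical(coords(make_reference_structure(10, seed = 1)), coords(s))
  expect_error(make_reference_structure(1), ">= 2")
})

test_that("frame scheduling matches duration / interval exactly", {
  expect_identical(frames_for_duration(400, 400), 1000L)
  expect_identical(frames_for_duration(2, 400), 5L)
  expect_error(frames_for_duration(1, 400), "whole number")
})

test_that("zero noise with no plans reproduces the reference in every frame", {
  s <- make_reference_structure(6, seed = 2)
  spec <- fluctuation_spec(6, base_sigma = 0, seed = 3)
  tr <- make_trajectory(s, spec, n_frames = 4)
  for (f in 1:4)
    expect_equal(tr$coords[, , f], coords(s), ignore_attr = TRUE)
})

test_that("a plan with occupancy 1 and no jitter pins the pair distance", {
  s <- make_reference_structure(8, seed = 5)
  spec <- fluctuation_spec(8, base_sigma = 0.3, seed = 6)
  plan <- interaction_plan(2, 6, bound_distance = 3.0, occupancy = 1,
                           jitter_sigma = 0)
  tr <- make_trajectory(s, spec, list(plan), n_frames = 50)
  ia <- which(s$resno == 2 & s$elety != "CA")
  ib <- which(s$resno == 6 & s$elety != "CA")
  d <- sqrt(colSums((tr$coords[ia, , ] - tr$coords[ib, , ])^2))
  expect_equal(d, rep(3.0, 50), tolerance = 1e-9)
})

test_that("plans referencing missing atoms or residues fail loudly", {
  s <- make_reference_structure(8, seed = 5)
  spec <- fluctuation_spec(8, seed = 1)
  expect_error(
    make_trajectory(s, spec, list(interaction_plan(2, 6, atom_b = "XX")),
                    n_frames = 2),
    "missing atom XX")
  expect_error(
    make_trajectory(s, spec, list(interaction_plan(2, 99)), n_frames = 2),
    "missing residue 99")
})

test_that("trajectory generation is deterministic given the generator seed", {
  s <- make_reference_structure(6, seed = 2)
  spec <- fluctuation_spec(6, base_sigma = 0.4, rigid_max_rot_deg = 4,
                           rigid_max_trans = 1, seed = 11)
  t1 <- make_trajectory(s, spec, n_frames = 5)
  t2 <- make_trajectory(s, spec, n_frames = 5)
  expect_identical(t1$coords, t2$coords)
})

test_that("sample RMSF converges to sigma * sqrt(3) at planted amplitudes", {
  # closed form for the estimator: sqrt(3) * sigma, shrunk by the rigid-fit
  # degrees of freedom (3N-6)/(3N) and the frame-mean estimate (F-1)/F;
  # per-residue sampling SE ~= sigma / sqrt(2F)
  n <- 20; f <- 1500; sig <- 0.7
  s <- make_reference_structure(n, seed = 8)
  spec <- fluctuation_spec(n, base_sigma = sig, seed = 21)
  prof <- rmsf(make_trajectory(s, spec, n_frames = f))
  expected <- sqrt(3) * sig * sqrt((3 * n - 6) / (3 * n)) * sqrt((f - 1) / f)
  se <- sig / sqrt(2 * f)
  # profile mean at 3.SE of the mean; individual residues are allowed the
  # usual ~5% leakage past their own 3.SE band
  expect_lt(abs(mean(prof$rmsf_A) - expected), 3 * se / sqrt(n))
  expect_gte(mean(abs(prof$rmsf_A - expected) < 3 * se), 0.9)
})

test_that("rigid-body frame noise leaves superposed RMSF unchanged", {
  # paired runs: identical seed, so the thermal displacements are identical
  # and the runs differ only by the per-frame rigid motion
  n <- 15; f <- 300
  s <- make_reference_structure(n, seed = 9)
  quiet <- fluctuation_spec(n, base_sigma = 0.5, seed = 33)
  noisy <- fluctuation_spec(n, base_sigma = 0.5, rigid_max_rot_deg = 8,
                            rigid_max_trans = 2, seed = 33)
  p1 <- rmsf(make_trajectory(s, quiet, n_frames = f))
  p2 <- rmsf(make_trajectory(s, noisy, n_frames = f))
  expect_equal(p2$rmsf_A, p1$rmsf_A, tolerance = 1e-6)
})

test_that("homolog sets honour rates, determinism and correspondence", {
  base <- random_aa(40)
  none <- make_homolog_set(base, 3, substitution_rate = 0,
                           indel_rate = 0, seed = 1)
  expect_true(all(none$sequences == base))
  expect_true(all(vapply(none$correspondence, identical, TRUE,
                         seq_len(nchar(base)))))

  sub_only <- make_homolog_set(base, 3, substitution_rate = 0.3,
                               indel_rate = 0, seed = 2)
  expect_true(all(nchar(sub_only$sequences) == nchar(base)))

  again <- make_homolog_set(base, 3, substitution_rate = 0.3,
                            indel_rate = 0, seed = 2)
  expect_identical(again, sub_only)

  with_indel <- make_homolog_set(base, 2, substitution_rate = 0.1,
                                 indel_rate = 0.1, seed = 3)
  for (id in names(with_indel$sequences)) {
    map <- with_indel$correspondence[[id]]
    v <- strsplit(with_indel$sequences[[id]], "")[[1]]
    expect_true(all(map[!is.na(map)] <= length(v)))
    expect_true(!is.unsorted(map[!is.na(map)], strictly = TRUE))
  }
  expect_error(make_homolog_set("", 2), "empty")
  expect_error(make_homolog_set("ACD", 2, substitution_rate = 1), "rates")
})

test_that("forced residues override the variant at base coordinates", {
  base <- strrep("A", 20)
  hs <- make_homolog_set(base, 1, substitution_rate = 0, indel_rate = 0,
                         seed = 1, ids = "m",
                         forced_residues = list(m = c("5" = "M")))
  expect_equal(substr(hs$sequences[["m"]], 5, 5), "M")
})
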