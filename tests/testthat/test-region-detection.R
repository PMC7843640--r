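delta_obj <- function(delta, cols = seq_along(delta)) {
  out <- data.frame(common_column = cols, delta = delta)
  attr(out, "mean_delta") <- mean(delta)
  attr(out, "mesophile_id") <- "meso"
  attr(out, "thermophile_ids") <- "thermo"
  class(out) <- c("delta_profile", "data.frame")
  out
}

fake_profile <- function(values, resno = seq_along(values), id = "p") {
  out <- data.frame(residue_number = resno, rmsf_A = values)
  attr(out, "protein") <- id
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

test_that("delta profile subtracts the thermophile mean per common column", {
  al <- align_many(c(m = "ACDEF", t1 = "ACDEF", t2 = "ACDEF"))
  m <- build_map(al)
  profs <- list(m = fake_profile(rep(0.9, 5)),
                t1 = fake_profile(rep(0.2, 5)),
                t2 = fake_profile(rep(0.4, 5)))
  dp <- delta_profile(profs, m, "m", c("t1", "t2"))
  expect_equal(dp$delta, rep(0.9 - 0.3, 5))
  expect_equal(attr(dp, "mean_delta"), 0.6)

  same <- delta_profile(list(m = profs$t1, t1 = profs$t1, t2 = profs$t1),
                        m, "m", c("t1", "t2"))
  expect_equal(same$delta, rep(0, 5))

  up <- delta_profile(list(m = fake_profile(rep(0.7, 5)), t1 = profs$t1),
                      m, "m", "t1")
  expect_equal(up$delta, rep(0.5, 5))
  expect_error(delta_profile(profs["m"], m, "m", "t1"), "no RMSF profile")
})

test_that("columns gapped in any contributing protein are dropped", {
  al <- align_pair("ACDEFG", "ACFG", ids = c("m", "t"))
  m <- build_map(al)
  profs <- list(m = fake_profile(rep(1, 6)), t = fake_profile(rep(0.4, 4)))
  dp <- delta_profile(profs, m, "m", "t")
  expect_equal(dp$common_column, c(1, 2, 5, 6))
  expect_equal(dp$delta, rep(0.6, 4))
})

test_that("the worked threshold example yields one region over columns 3-5", {
  dp <- delta_obj(c(0.1, 0.1, 0.5, 0.6, 0.7, 0.1))
  regs <- detect_regions(dp, min_length = 3, gap_tolerance = 0)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start_column, 3)
  expect_equal(regs$end_column, 5)
  expect_equal(regs$label, "I")
  expect_equal(regs$mean_delta_in_region, 0.6)
})

test_that("a flat profile produces no regions (strict inequality)", {
  expect_equal(nrow(detect_regions(delta_obj(rep(0.4, 10)))), 0)
})

test_that("flagged-column count is conserved by merging at zero tolerance", {
  set.seed(60)
  for (k in 1:10) {
    dp <- delta_obj(round(stats::runif(40), 2))
    regs <- detect_regions(dp, min_length = 1, gap_tolerance = 0)
    expect_equal(sum(regs$length),
                 sum(dp$delta > attr(dp, "mean_delta")))
  }
})

test_that("raising min_length never increases the region count", {
  set.seed(61)
  dp <- delta_obj(stats::runif(60))
  counts <- vapply(1:8, function(ml)
    nrow(detect_regions(dp, min_length = ml)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gap tolerance bridges short dips inside a region", {
  dp <- delta_obj(c(0, 0, 1, 1, 0, 1, 1, 0, 0, 0))  # mean 0.4
  bridged <- detect_regions(dp, min_length = 3, gap_tolerance = 1)
  expect_equal(nrow(bridged), 1)
  expect_equal(c(bridged$start_column, bridged$end_column), c(3, 7))
  split <- detect_regions(dp, min_length = 2, gap_tolerance = 0)
  expect_equal(nrow(split), 2)
})

test_that("planted high-sigma regions are recovered from trajectories", {
  n <- 60; f <- 600
  plant <- data.frame(start = c(10, 30, 45), end = c(16, 38, 52),
                      sigma = 0.9)
  s <- make_reference_structure(n, seed = 70)
  meso <- make_trajectory(s, fluctuation_spec(
    n, base_sigma = 0.4, regions = plant, rigid_max_rot_deg = 5,
    rigid_max_trans = 1, seed = 71), n_frames = f)
  th1 <- make_trajectory(s, fluctuation_spec(
    n, base_sigma = 0.4, rigid_max_rot_deg = 5, rigid_max_trans = 1,
    seed = 72), n_frames = f)
  th2 <- make_trajectory(s, fluctuation_spec(
    n, base_sigma = 0.4, rigid_max_rot_deg = 5, rigid_max_trans = 1,
    seed = 73), n_frames = f)
  seq1 <- structure_sequence(s)
  m <- build_map(align_many(c(m = seq1, t1 = seq1, t2 = seq1)))
  dp <- delta_profile(list(m = rmsf(meso), t1 = rmsf(th1), t2 = rmsf(th2)),
                      m, "m", c("t1", "t2"))
  regs <- detect_regions(dp)
  expect_equal(nrow(regs), nrow(plant))
  expect_true(all(abs(regs$start_column - plant$start) <= 2))
  expect_true(all(abs(regs$end_column - plant$end) <= 2))
})

test_that("regions translate into per-protein residue spans", {
  al <- align_pair("ACDEFGHI", "ACFGHI", ids = c("full", "del"))
  m <- build_map(al)
  regs <- data.frame(label = "I", start_column = 2, end_column = 6,
                     length = 5, mean_delta_in_region = 1)
  spans <- map_regions_to_proteins(regs, m)
  full <- spans[spans$protein == "full", ]
  del <- spans[spans$protein == "del", ]
  expect_equal(c(full$start_residue, full$end_residue), c(2, 6))
  # the deletion removes 2 residues from the span
  expect_equal(del$n_residues, full$n_residues - 2)
  # a region entirely inside the other protein's gap is flagged empty
  gap_reg <- data.frame(label = "II", start_column = 3, end_column = 4,
                        length = 2, mean_delta_in_region = 1)
  gs <- map_regions_to_proteins(gap_reg, m)
  expect_true(gs$empty[gs$protein == "del"])
  expect_false(gs$empty[gs$protein == "full"])
})
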