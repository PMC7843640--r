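test_that("salt-bridge candidates obey chemistry and the search cutoff", {
  close_pair <- lys_asp_structure(3.0)
  cands <- candidate_pairs(close_pair, "salt_bridge")
  expect_length(cands, 1)
  expect_equal(cands[[1]]$res_a$resid, "LYS")
  expect_equal(cands[[1]]$res_b$resid, "ASP")
  expect_equal(cands[[1]]$ref_distance, 3.0, tolerance = 1e-9)

  far_pair <- lys_asp_structure(7.5)
  expect_length(candidate_pairs(far_pair, "salt_bridge"), 0)
})

test_that("candidate residue order is canonical regardless of file order", {
  # Asp first in the file; the reported pair still starts at the lower resno
  s <- md_structure(data.frame(
    chain = "A", resno = c(10, 10, 1, 1),
    resid = c("ASP", "ASP", "LYS", "LYS"),
    elety = c("CA", "OD1", "CA", "NZ"),
    x = c(30, 5, 0, 2), y = 0, z = 0))
  cands <- candidate_pairs(s, "salt_bridge")
  expect_length(cands, 1)
  expect_equal(cands[[1]]$res_a$resno, 1)
  expect_equal(cands[[1]]$res_b$resno, 10)
})

test_that("threonine tips at 3.2 A form a hydrogen-bond candidate", {
  s <- md_structure(data.frame(
    chain = "A", resno = c(1, 1, 5, 5),
    resid = "THR", elety = c("CA", "OG1", "CA", "OG1"),
    x = c(0, 1.5, 30, 1.5 + 3.2), y = 0, z = 0))
  cands <- candidate_pairs(s, "hydrogen_bond")
  expect_length(cands, 1)
  expect_equal(cands[[1]]$atoms_a, "OG1")
  expect_equal(cands[[1]]$cutoff, 3.5)
})

test_that("unknown residue chemistry is skipped with a warning", {
  s <- md_structure(data.frame(
    chain = "A", resno = c(1, 1, 2, 2),
    resid = c("LYS", "LYS", "XXX", "XXX"),
    elety = c("CA", "NZ", "CA", "OD1"),
    x = c(0, 2, 4, 3), y = 0, z = 0))
  expect_warning(cands <- candidate_pairs(s, "salt_bridge"),
                 "unknown chemistry")
  expect_length(cands, 0)
})

test_that("distance series recover planted occupancies", {
  n <- 12
  s <- make_reference_structure(n, seed = 80)
  plan <- interaction_plan(2, 8, bound_distance = 2.8, unbound_distance = 8,
                           occupancy = 1, jitter_sigma = 0)
  s2 <- plant_reference_contacts(s, list(plan))
  spec <- fluctuation_spec(n, base_sigma = 0.3, seed = 81)
  tr <- make_trajectory(s2, spec, list(plan), n_frames = 200)
  pair <- candidate_pairs(s2, "salt_bridge")
  pair <- Filter(function(p) p$res_a$resno == 2 && p$res_b$resno == 8, pair)
  if (!length(pair)) {
    # the sampled sequence may not put a basic/acidic pair at 2/8; build the
    # pair record directly from the topology tips
    tip <- function(r) s2$elety[s2$resno == r & s2$elety != "CA"]
    pair <- list(mdfluct:::.new_pair(
      "salt_bridge",
      list(chain = "A", resno = 2, resid = s2$resid[s2$resno == 2][1]),
      tip(2),
      list(chain = "A", resno = 8, resid = s2$resid[s2$resno == 8][1]),
      tip(8)))
  }
  ser <- distance_series(tr, pair[[1]], cutoff = 4.0)
  expect_equal(ser$occupancy, 1.0)
  expect_equal(length(ser$distances), 200)

  # two-state plan at 0.7 over 1000 frames: binomial 3.SE recovery
  plan7 <- interaction_plan(2, 8, bound_distance = 2.8, occupancy = 0.7,
                            jitter_sigma = 0.1)
  tr7 <- make_trajectory(s2, fluctuation_spec(n, base_sigma = 0.3,
                                              seed = 82),
                         list(plan7), n_frames = 1000)
  ser7 <- distance_series(tr7, pair[[1]], cutoff = 4.0)
  expect_lt(abs(ser7$occupancy - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  # and the estimate agrees with the generator's recorded bound states
  truth <- attr(tr7, "ground_truth")$bound_states[, 1]
  expect_equal(ser7$occupancy, mean(truth))
})

test_that("a one-frame static trajectory reports the reference distance", {
  s <- lys_asp_structure(3.4)
  tr <- md_trajectory(s, array(coords(s), dim = c(nrow(s), 3, 1)))
  pair <- candidate_pairs(s, "salt_bridge")[[1]]
  ser <- distance_series(tr, pair)
  expect_equal(ser$distances, 3.4, tolerance = 1e-9)
  expect_equal(ser$occupancy, 1)
  bad <- pair; bad$atoms_b <- "NE2"
  expect_error(distance_series(tr, bad), "not in topology")
})

test_that("distances ignore rigid motion and frame order", {
  n <- 10
  s <- make_reference_structure(n, seed = 83)
  plan <- interaction_plan(1, 6, occupancy = 0.5, jitter_sigma = 0.2)
  s <- plant_reference_contacts(s, list(plan))
  quiet <- fluctuation_spec(n, base_sigma = 0.4, seed = 84)
  noisy <- fluctuation_spec(n, base_sigma = 0.4, rigid_max_rot_deg = 10,
                            rigid_max_trans = 3, seed = 84)
  tip <- function(r) s$elety[s$resno == r & s$elety != "CA"]
  pair <- mdfluct:::.new_pair(
    "salt_bridge",
    list(chain = "A", resno = 1, resid = s$resid[s$resno == 1][1]), tip(1),
    list(chain = "A", resno = 6, resid = s$resid[s$resno == 6][1]), tip(6))
  t1 <- make_trajectory(s, quiet, list(plan), n_frames = 100)
  t2 <- make_trajectory(s, noisy, list(plan), n_frames = 100)
  d1 <- distance_series(t1, pair)
  d2 <- distance_series(t2, pair)
  expect_equal(d2$distances, d1$distances, tolerance = 1e-9)

  perm <- t1
  set.seed(2)
  perm$coords <- perm$coords[, , sample(100)]
  expect_equal(distance_series(perm, pair)$occupancy, d1$occupancy)
})

test_that("cross-homolog comparison classifies SB, HB and NI correctly", {
  seqs <- c(p1 = "KADTE", p2 = "KADTE", p3 = "MADTE")
  amap <- build_map(align_many(seqs))
  mk_struct <- function(seq, id) {
    s <- make_reference_structure(sequence = seq, name = id)
    plant_reference_contacts(s, list(interaction_plan(1, 3)))
  }
  structs <- Map(mk_struct, seqs, names(seqs))
  mk_series <- function(id, occ) {
    s <- structs[[id]]
    plan <- interaction_plan(1, 3, occupancy = occ, jitter_sigma = 0)
    tr <- make_trajectory(s, fluctuation_spec(5, base_sigma = 0, seed = 90),
                          list(plan), n_frames = 40)
    pair <- candidate_pairs(s, "salt_bridge")[[1]]
    distance_series(tr, pair)
  }
  series <- list(p1 = list(mk_series("p1", 1.0)),
                 p2 = list(mk_series("p2", 0.0)),
                 p3 = list())
  tab <- compare_across_homologs(series, amap, structures = structs)
  expect_equal(nrow(tab), 3)
  get <- function(id) tab[tab$protein == id, ]
  expect_equal(get("p1")$classification, "SB")
  expect_equal(get("p1")$occupancy, 1.0)
  # occupancy 0 falls below the presence threshold
  expect_equal(get("p2")$classification, "NI")
  # the basic partner is a methionine: NI by chemistry, whatever the distance
  expect_equal(get("p3")$classification, "NI")
  expect_equal(get("p3")$note, "incompatible_residue")
  expect_equal(get("p3")$resid_a, "MET")
})
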