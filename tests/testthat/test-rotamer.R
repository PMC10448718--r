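test_that("the 3-degree grid enumerates exactly 120^n conformations", {
  m <- build_monomer("methane")
  b1 <- rotatable_bond(c(1L, 2L), 3:5)
  r1 <- enumerate_rotamers(m, list(b1))
  expect_equal(nrow(r1$angles), 120L)
  expect_equal(r1$angles[1:3, 1], c(0, 3, 6), ignore_attr = TRUE)
  b2 <- rotatable_bond(c(1L, 3L), c(4L, 5L))
  r2 <- enumerate_rotamers(m, list(b1, b2))
  expect_equal(nrow(r2$angles), 14400L)
  expect_error(enumerate_rotamers(m, list()), "between 1 and 2")
  expect_error(enumerate_rotamers(m, list(b1, b2, b2)), "between 1 and 2")
})

test_that("the zero-angle conformation reproduces the input coordinates", {
  site <- rotor_site()
  rot <- enumerate_rotamers(site$ligand, list(site$bond))
  i0 <- which(rot$angles[, 1] == 0)
  expect_identical(coords(rot$conformation(i0)), coords(site$ligand))
})

test_that("rotation preserves internal geometry of the moving set", {
  site <- rotor_site()
  rot <- enumerate_rotamers(site$ligand, list(site$bond))
  d0 <- stats::dist(coords(site$ligand))
  for (i in c(10, 47, 100)) {
    di <- stats::dist(coords(rot$conformation(i))[3:6, ])
    expect_equal(as.numeric(di), as.numeric(stats::dist(coords(site$ligand)[3:6, ])),
                 tolerance = 1e-6)
  }
})

test_that("clash thresholds are inclusive at 2.0, 1.75 and 1.40 angstrom", {
  pair <- function(els, d) chpi_structure(atoms_df(
    paste0(els, 1:2), els, rbind(c(0, 0, 0), c(d, 0, 0))))
  expect_true(clash_filter(pair(c("C", "C"), 2.0)))
  expect_true(clash_filter(pair(c("C", "C"), 1.9)))
  expect_false(clash_filter(pair(c("C", "C"), 2.05)))
  expect_true(clash_filter(pair(c("C", "H"), 1.75)))
  expect_false(clash_filter(pair(c("C", "H"), 1.8)))
  expect_true(clash_filter(pair(c("H", "H"), 1.40)))
  expect_false(clash_filter(pair(c("H", "H"), 1.45)))
})

test_that("1-2 and 1-3 pairs are exempt from clashing but 1-4 pairs count", {
  # linear chain with short 1-4 distance
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.25, 1.3, 0), c(1.5, 2.6, 0))
  s <- chpi_structure(atoms_df(paste0("C", 1:4), rep("C", 4), xyz),
                      bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  # 1-2 at 1.5 and 1-3 at ~2.6 do not clash by exemption;
  # 1-4 at ~3.0 is fine, but pulling atom 4 near atom 1 must reject
  expect_false(clash_filter(s))
  s$atoms$x[4] <- 1.8; s$atoms$y[4] <- 0.4   # 1-4 distance ~1.84
  expect_true(clash_filter(s))
})

test_that("a pose rebuilt at its own optimum is re-found at zero deviation", {
  site <- rotor_site()
  first <- best_rotamer(site$receptor, site$ligand, list(site$bond),
                        w = 1, mode = "hdep")
  rot <- enumerate_rotamers(site$ligand, list(site$bond))
  iopt <- which(rot$angles[, 1] == first$best_angles[1])
  relaxed <- rot$conformation(iopt)
  second <- best_rotamer(site$receptor, relaxed, list(site$bond),
                         w = 1, mode = "hdep")
  expect_equal(unname(second$best_angles), 0)
  expect_equal(unname(second$angle_deviation), 0)
  expect_equal(second$rmsd_to_reference, 0, tolerance = 1e-12)
})

test_that("the winner flips from the H-bond decoy to the CH-pi rotamer", {
  site <- rotor_site()
  res0 <- best_rotamer(site$receptor, site$ligand, list(site$bond),
                       w = 0, mode = "hdep")
  res7 <- best_rotamer(site$receptor, site$ligand, list(site$bond),
                       w = 0.7, mode = "hdep")
  # decoy rotamer: no CH-pi contribution at all
  expect_equal(res0$best_breakdown$e_chpi * 0, 0)
  expect_gt(abs(chpi:::.wrap180(res0$best_angles[1] - res7$best_angles[1])), 90)
  expect_lt(res7$best_breakdown$e_chpi, -0.5)
  expect_gt(res0$best_breakdown$e_chpi, -1e-6)
  expect_lt(res0$best_breakdown$e_vina, res7$best_breakdown$e_vina)
})

test_that("the winner is the exhaustive minimum over surviving rotamers", {
  site <- rotor_site()
  res <- best_rotamer(site$receptor, site$ligand, list(site$bond),
                      w = 0.7, mode = "hdep")
  rot <- enumerate_rotamers(site$ligand, list(site$bond))
  totals <- vapply(seq_len(nrow(rot$angles)), function(i) {
    cand <- rot$conformation(i)
    if (clash_filter(cand)) return(NA_real_)
    total_energy(site$receptor, cand, w = 0.7, mode = "hdep")$total
  }, numeric(1))
  expect_equal(res$n_scored, sum(!is.na(totals)))
  expect_equal(res$best_breakdown$total, min(totals, na.rm = TRUE))
  expect_equal(unname(res$best_angles[1]),
               rot$angles[which.min(totals), 1], ignore_attr = TRUE)
})

test_that("with w = 0 the result ignores the CH-pi parameters", {
  site <- rotor_site()
  a <- best_rotamer(site$receptor, site$ligand, list(site$bond), w = 0)
  b <- best_rotamer(site$receptor, site$ligand, list(site$bond), w = 0,
                    params_h = chpi_params_h(0.5, 3.0, 1.5))
  expect_identical(a$best_angles, b$best_angles)
  expect_identical(a$best_breakdown$total, b$best_breakdown$total)
})

test_that("an always-clashing subject raises a no-valid-rotamer error", {
  # two non-bonded hydrogens riveted at 1.0 angstrom in the static part
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0),
               c(0.2, 1.0, 0), c(0.2, 1.9, 0))
  s <- chpi_structure(atoms_df(c("C1", "C2", "C3", "H1", "H2"),
                               c("C", "C", "C", "H", "H"), xyz),
                      bonds = rbind(c(1, 2), c(2, 3), c(1, 4), c(3, 5)))
  rec <- assign_atom_types(build_monomer("benzene"))
  bond <- rotatable_bond(c(1L, 2L), 3L)
  expect_error(best_rotamer(rec, assign_atom_types(s), list(bond)),
               "no valid rotamer")
})
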