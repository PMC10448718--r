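# minimal one-carbon "ring" for isolated pair checks
lone_carbon_ring <- function(pos = c(3.58, 0, 0)) {
  structure(list(atom_indices = 1L,
                 ring_xyz = matrix(pos, 1, 3),
                 centroid = pos, normal = c(0, 0, 1),
                 ring_carbons = 1L,
                 carbon_xyz = matrix(pos, 1, 3), parent = "ligand"),
            class = "chpi_ring")
}

ch_probe <- function(hpos = c(0, 0, 0), cpos = c(0, 0, 1.09)) {
  infer_bonds(chpi_structure(atoms_df(c("C1", "H1"), c("C", "H"),
                                      rbind(cpos, hpos))))
}

test_that("the angular decay is 1 at 0, 0.5 at 60, 0 from 90 on, and monotone", {
  expect_equal(f_theta(0), 1)
  expect_equal(f_theta(60), 0.5)
  expect_equal(f_theta(90), 0)
  expect_equal(f_theta(135), 0)
  th <- seq(0, 90, by = 1)
  expect_true(all(diff(f_theta(th)) < 0))
  expect_error(f_theta(-1), "0, 180")
  expect_error(f_theta(181), "0, 180")
})

test_that("an aligned H at the optimal separation scores the kernel depth", {
  p <- chpi_params_h()
  ring <- lone_carbon_ring(c(p$r0, 0, 0))
  e <- e_chpi_h(ch_probe(), ring, p)
  # kernel depth at the optimum is the documented fraction of e
  expect_equal(e, -p$e * 0.45, tolerance = 1e-12)
  # perpendicular C-H: zero angular factor
  probe90 <- ch_probe(cpos = c(-1.09, 0, 0))
  expect_equal(e_chpi_h(probe90, ring, p), 0)
})

test_that("the carbon-only term has its well at r0 and vanishes at 10 A", {
  p <- chpi_params_c()
  ring <- lone_carbon_ring(c(p$r0, 0, 0))
  s <- chpi_structure(atoms_df("C1", "C", matrix(0, 1, 3)))
  expect_equal(e_chpi_c(s, ring, p), -p$e * 0.45, tolerance = 1e-12)
  far <- lone_carbon_ring(c(10, 0, 0))
  expect_equal(e_chpi_c(s, far, p), 0)
})

test_that("methane over benzene scores the same under any axial rotation", {
  base <- build_dimer(dimer_spec("A", r_v = 3.6))
  rings <- perceive_aromatic_rings(base$receptor)
  e0c <- e_chpi_c(base$ligand, rings)
  e0h <- e_chpi_h(base$ligand, rings)
  for (ang in c(17, 60, 121, 270)) {
    rot <- base$ligand
    xyz <- coords(rot) %*% t(rot_matrix(c(0, 0, 1), ang))
    rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
    expect_equal(e_chpi_c(rot, rings), e0c, tolerance = 1e-9)
    expect_equal(e_chpi_h(rot, rings), e0h, tolerance = 1e-9)
  }
})

test_that("base-score terms match their definitions for simple pairs", {
  ct <- vina_constants()
  mk <- function(x) assign_atom_types(chpi_structure(
    atoms_df("C1", "C", matrix(c(x, 0, 0), 1, 3))))
  # surface distance zero: both gaussians at their values, no repulsion
  e0 <- vina_base_energy(mk(0), mk(3.8))
  expected <- ct$weights[["gauss1"]] +
    ct$weights[["gauss2"]] * exp(-((0 - 3) / 2)^2) +
    ct$weights[["hydrophobic"]]
  expect_equal(e0, expected, tolerance = 1e-12)
  # beyond the 8 A cutoff
  expect_equal(vina_base_energy(mk(0), mk(9)), 0)
})

test_that("the base score matches a brute-force all-pairs oracle", {
  site <- make_synthetic_site(3, list(R = function(n) stats::runif(n, 2.8, 3.4),
                                      theta2 = function(n) stats::runif(n, 0, 50)),
                              seed = 21)
  expect_equal(vina_base_energy(site$receptor, site$ligand),
               brute_force_vina(site$receptor, site$ligand),
               tolerance = 1e-9)
  dm <- build_dimer(dimer_spec("C", r_v = 3.4))
  expect_equal(vina_base_energy(dm$receptor, dm$ligand),
               brute_force_vina(dm$receptor, dm$ligand), tolerance = 1e-9)
})

test_that("zero weighting reproduces the base score bit for bit", {
  dm <- build_dimer(dimer_spec("B", r_v = 3.7))
  br <- total_energy(dm$receptor, dm$ligand, w = 0, mode = "hdep")
  expect_identical(br$total, vina_base_energy(dm$receptor, dm$ligand))
  expect_identical(br$total, br$e_vina)
})

test_that("the breakdown is exact and the weighting domain is enforced", {
  dm <- build_dimer(dimer_spec("A", r_v = 3.8))
  for (w in c(0.3, 0.7, 1)) {
    br <- total_energy(dm$receptor, dm$ligand, w = w, mode = "hdep")
    expect_equal(br$total, br$e_vina + w * br$e_chpi, tolerance = 1e-9)
    expect_lte(br$e_chpi, 0)
  }
  expect_error(total_energy(dm$receptor, dm$ligand, w = 1.2), "\\[0, 1\\]")
  expect_error(total_energy(dm$receptor, dm$ligand, w = -0.1), "\\[0, 1\\]")
})

test_that("a dimer at large separation scores zero at unit weighting", {
  dm <- build_dimer(dimer_spec("A", r_v = 60))
  br <- total_energy(dm$receptor, dm$ligand, w = 1, mode = "hdep")
  expect_equal(br$total, 0)
})

test_that("energies are invariant under rigid motion of the complex", {
  dm <- build_dimer(dimer_spec("C", r_v = 3.6, r_h = 0.5))
  ref <- total_energy(dm$receptor, dm$ligand, w = 1, mode = "hdep")$total
  refc <- total_energy(dm$receptor, dm$ligand, w = 1, mode = "hindep")$total
  for (k in 1:3) {
    ax <- c(k, 1 - k, 0.5)
    rec <- rigid_move(dm$receptor, ax, 31 * k, c(-k, k, 2))
    lig <- rigid_move(dm$ligand, ax, 31 * k, c(-k, k, 2))
    expect_equal(total_energy(rec, lig, w = 1, mode = "hdep")$total, ref,
                 tolerance = 1e-6)
    expect_equal(total_energy(rec, lig, w = 1, mode = "hindep")$total, refc,
                 tolerance = 1e-6)
  }
})

test_that("CH-pi energies are never positive and fade monotonically outward", {
  set.seed(31)
  for (k in 1:10) {
    g <- sample(names(chpi:::.dimer_orientations), 1)
    dm <- build_dimer(dimer_spec(g, r_v = stats::runif(1, 3, 6),
                                 r_h = stats::runif(1, 0, 1.2)))
    rings <- perceive_aromatic_rings(dm$receptor)
    expect_lte(e_chpi_h(dm$ligand, rings), 0)
    expect_lte(e_chpi_c(dm$ligand, rings), 0)
  }
  # beyond the well the magnitude decreases monotonically with distance
  rv <- seq(4.6, 7.8, by = 0.2)
  eh <- vapply(rv, function(v) {
    dm <- build_dimer(dimer_spec("A", r_v = v))
    e_chpi_h(dm$ligand, perceive_aromatic_rings(dm$receptor))
  }, numeric(1))
  expect_true(all(diff(eh) > 0))
  expect_equal(eh[length(eh)], 0, tolerance = 1e-3)
})

test_that("hydrogen-dependent and carbon-only forms agree for the axial family", {
  # for A, D, E the interacting H has unit angular factor and the two
  # functional forms should track each other over the attractive range
  sc_h <- chpi_scorer(w = 1, mode = "hdep")
  sc_c <- chpi_scorer(w = 1, mode = "hindep")
  for (g in c("A", "D", "E")) {
    cvh <- scan_curve(dimer_spec(g), "vertical", sc_h)
    cvc <- scan_curve(dimer_spec(g), "vertical", sc_c)
    keep <- cvh$abscissa >= 3.5
    expect_lt(max(abs(cvh$energy[keep] - cvc$energy[keep])), 0.25)
    expect_gt(stats::cor(cvh$energy[keep], cvc$energy[keep]), 0.97)
  }
})

test_that("HIS ring nitrogens do not contribute to the energy sum", {
  his <- make_his()
  rings <- perceive_aromatic_rings(his)
  expect_length(rings[[1]]$ring_carbons, 3L)
  expect_equal(nrow(rings[[1]]$carbon_xyz), 3L)
  # a probe at fixed distance: HIS (3 C) scores 3/6 of a benzene ring
  p <- chpi_params_c()
  s <- chpi_structure(atoms_df("C1", "C", matrix(c(0, 0, p$r0), 1, 3)))
  eh <- e_chpi_c(s, rings, p)
  expect_gt(eh, 6 / 3 * eh - 1e-12)   # strictly weaker than a 6-carbon ring
})

test_that("untyped structures are rejected by the base score", {
  b <- build_monomer("benzene"); m <- build_monomer("methane")
  b$atoms$docking_type <- NULL
  expect_error(vina_base_energy(b, m), "untyped")
})
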