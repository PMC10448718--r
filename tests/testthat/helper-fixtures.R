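# Shared fixture builders and independent oracles. Everything is built in
# code; no binary fixtures.

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1, b = 0, element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resid, x, y, z, occ, b, element)
}

write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

atoms_df <- function(name, element, xyz, resname = "LIG", resid = 1L,
                     chain = "A", occ = 1, b = 0) {
  data.frame(serial = seq_along(name), name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = occ, b_factor = b, resname = resname,
             resid = resid, chain = chain, stringsAsFactors = FALSE)
}

rot_matrix <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

rigid_move <- function(s, axis = c(1, 2, 3), angle_deg = 37,
                       shift = c(5, -3, 2)) {
  R <- rot_matrix(axis, angle_deg)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# independent brute-force detection oracle: every (H, ring) pair with
# H-centroid distance <= max_r, methyl and residue filters applied naively
brute_force_contacts <- function(receptor, ligand, max_r = 3.5, max_b = 40,
                                 exclude_methyl = TRUE) {
  count_side <- function(donor, acceptor, donor_one, acc_one) {
    rings <- perceive_aromatic_rings(acceptor)
    akey <- if (acc_one) rep("ALL", nrow(acceptor$atoms))
            else paste(acceptor$atoms$chain, acceptor$atoms$resid)
    dkey <- if (donor_one) rep("ALL", nrow(donor$atoms))
            else paste(donor$atoms$chain, donor$atoms$resid)
    bad_of <- function(s, key) {
      unlist(lapply(split(seq_len(nrow(s$atoms)), key), function(ix)
        if (any(s$atoms$occupancy[ix] < 1) ||
            mean(s$atoms$b_factor[ix]) > max_b) key[ix[1]] else NULL))
    }
    bad_a <- bad_of(acceptor, akey); bad_d <- bad_of(donor, dkey)
    cp <- chpi:::.ch_pairs(donor, exclude_methyl)
    if (is.null(cp$pairs)) return(NULL)
    hits <- NULL
    for (ring in rings) {
      if (any(akey[ring$atom_indices] %in% bad_a)) next
      for (k in seq_len(nrow(cp$pairs))) {
        h <- cp$pairs[k, 2]
        if (dkey[h] %in% bad_d) next
        hp <- as.numeric(donor$atoms[h, c("x", "y", "z")])
        if (sqrt(sum((hp - ring$centroid)^2)) <= max_r)
          hits <- rbind(hits, data.frame(h = h, ring = ring$parent))
      }
    }
    hits
  }
  rbind(count_side(ligand, receptor, TRUE, FALSE),
        count_side(receptor, ligand, FALSE, TRUE))
}

# independent naive base-score oracle (plain double loop)
brute_force_vina <- function(receptor, ligand) {
  ct <- vina_constants()
  e <- 0
  ra <- receptor$atoms[receptor$atoms$element != "H", ]
  la <- ligand$atoms[ligand$atoms$element != "H", ]
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
    r <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                     as.numeric(la[j, c("x", "y", "z")]))^2))
    if (r > ct$cutoff) next
    ri <- ct$radii[ra$element[i]]; if (is.na(ri)) ri <- 1.9
    rj <- ct$radii[la$element[j]]; if (is.na(rj)) rj <- 1.9
    d <- r - ri - rj
    e <- e + ct$weights["gauss1"] * exp(-(d / 0.5)^2) +
      ct$weights["gauss2"] * exp(-((d - 3) / 2)^2) +
      ct$weights["repulsion"] * if (d < 0) d^2 else 0
    if (isTRUE(ra$hydrophobic[i]) && isTRUE(la$hydrophobic[j]))
      e <- e + ct$weights["hydrophobic"] * min(max((1.5 - d) / 1, 0), 1)
    if ((isTRUE(ra$donor[i]) && isTRUE(la$acceptor[j])) ||
        (isTRUE(ra$acceptor[i]) && isTRUE(la$donor[j])))
      e <- e + ct$weights["hbond"] * min(max((0 - d) / 0.7, 0), 1)
  }
  unname(e)
}

# idealized TRP side-chain fragment (indole as fused 5- and 6-ring)
make_trp <- function(resid = 1L, chain = "A") {
  ang <- (0:5) * pi / 3
  hexn <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
  hx <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  cd2 <- hx[1, ]; ce2 <- hx[6, ]
  mid <- (cd2 + ce2) / 2
  out <- mid / sqrt(sum(mid^2))            # outward from hexagon center
  side <- sqrt(sum((cd2 - ce2)^2))
  apo <- side / (2 * tan(pi / 5)); circ <- side / (2 * sin(pi / 5))
  ctr5 <- mid + apo * out
  a0 <- atan2(cd2[2] - ctr5[2], cd2[1] - ctr5[1])
  # pentagon vertices from CD2 moving away from CE2: CG, CD1, NE1
  sgn <- if (sin(atan2(ce2[2] - ctr5[2], ce2[1] - ctr5[1]) - a0) > 0) -1 else 1
  pent <- t(vapply(0:4, function(k)
    ctr5 + circ * c(cos(a0 + sgn * k * 2 * pi / 5),
                    sin(a0 + sgn * k * 2 * pi / 5), 0), numeric(3)))
  pname <- c("CD2", "CG", "CD1", "NE1", "CE2")
  nm <- c(hexn, pname[2:4])
  xyz <- rbind(hx, pent[2:4, ])
  el <- ifelse(substr(nm, 1, 1) == "N", "N", "C")
  s <- chpi_structure(atoms_df(nm, el, xyz, resname = "TRP", resid = resid,
                               chain = chain))
  infer_bonds(s)
}

# idealized HIS side-chain ring (regular pentagon, side 1.37)
make_his <- function(resid = 1L, chain = "A") {
  circ <- 1.37 / (2 * sin(pi / 5))
  nm <- c("CG", "ND1", "CE1", "NE2", "CD2")
  xyz <- t(vapply(0:4, function(k)
    circ * c(cos(k * 2 * pi / 5), sin(k * 2 * pi / 5), 0), numeric(3)))
  el <- ifelse(substr(nm, 1, 1) == "N", "N", "C")
  infer_bonds(chpi_structure(atoms_df(nm, el, xyz, resname = "HIS",
                                      resid = resid, chain = chain)))
}

dir_az <- function(az_deg, tet = 109.4712206 * pi / 180) {
  a <- az_deg * pi / 180
  c(sin(tet) * cos(a), sin(tet) * sin(a), cos(tet))
}

# Competition fixture: a one-bond rotor whose C-H can stack on a vertical
# aromatic ring (azimuth 120) while its hydroxyl can instead reach a weak
# acceptor (azimuth 200). With no CH-pi weighting the H-bond rotamer wins;
# at w = 0.7 the CH-pi rotamer takes over.
rotor_site <- function() {
  C1 <- c(0, 0, 1.54); C2 <- c(0, 0, 0)
  O <- C2 + 1.43 * dir_az(0)
  HO <- O + 0.96 * c(sin(109.4712206 * pi / 180), 0,
                     cos(109.4712206 * pi / 180))
  H2 <- C2 + 1.09 * dir_az(120)
  F3 <- C2 + 1.42 * dir_az(240)
  lig <- chpi_structure(atoms_df(
    c("C1", "C2", "O1", "HO1", "H21", "F31"),
    c("C", "C", "O", "H", "H", "F"),
    rbind(C1, C2, O, HO, H2, F3), resname = "LIG", chain = "L"))
  lig <- assign_atom_types(infer_bonds(lig))
  u <- (H2 - C2) / sqrt(sum((H2 - C2)^2))
  ctr <- C2 + (1.09 + 3.3) * u
  nrm <- c(cos(120 * pi / 180), sin(120 * pi / 180), 0)
  pf <- chpi:::.perp_frame(nrm)
  ang <- (0:5) * pi / 3
  ringC <- t(vapply(ang, function(a)
    ctr + 1.391 * (cos(a) * pf$e1 + sin(a) * pf$e2), numeric(3)))
  Orec <- c(4.55 * cos(200 * pi / 180), 4.55 * sin(200 * pi / 180), -0.477)
  rec <- chpi_structure(atoms_df(
    c(paste0("C", 1:6), "O1"), c(rep("C", 6), "O"),
    rbind(ringC, Orec), resname = c(rep("BNZ", 6), "HOH"),
    resid = c(rep(1L, 6), 2L)))
  rec <- assign_atom_types(infer_bonds(rec))
  list(receptor = rec, ligand = lig,
       bond = rotatable_bond(c(1L, 2L), 3:6))
}

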