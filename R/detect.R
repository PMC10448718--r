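.sp3_carbon_flags <- function(s) {
  xyz <- coords(s)
  arom <- .aromatic_flags(s)
  el <- s$atoms$element
  out <- rep(FALSE, length(el))
  for (i in which(el == "C")) {
    if (arom[i]) next
    nb <- .neighbors(s, i)
    heavy <- nb[el[nb] != "H"]
    if (length(heavy)) {
      dmin <- min(sqrt(rowSums((xyz[heavy, , drop = FALSE] -
                                  matrix(xyz[i, ], length(heavy), 3, byrow = TRUE))^2)))
      if (dmin < 1.38) next
    }
    if (length(nb) == 3 && length(heavy) == 3) {
      u <- .unit_bond_vectors(xyz, i, nb)
      if (sqrt(sum(colSums(u)^2)) < 0.35) next
    }
    out[i] <- TRUE
  }
  out
}

.methyl_hydrogens <- function(s) {
  el <- s$atoms$element
  sp3 <- .sp3_carbon_flags(s)
  hs <- integer(0)
  for (i in which(sp3)) {
    nb <- .neighbors(s, i)
    hnb <- nb[el[nb] == "H"]
    if (length(hnb) == 3) hs <- c(hs, hnb)
  }
  hs
}

.excluded_residues <- function(s, max_b, as_one = FALSE) {
  a <- s$atoms
  key <- if (as_one) rep("ALL", nrow(a)) else paste(a$chain, a$resid)
  bad <- vapply(split(seq_len(nrow(a)), key), function(idx) {
    any(a$occupancy[idx] < 1) || mean(a$b_factor[idx]) > max_b
  }, logical(1))
  names(bad)[bad]
}

.ch_pairs <- function(s, exclude_methyl) {
  el <- s$atoms$element
  sp3 <- .sp3_carbon_flags(s)
  meth <- if (exclude_methyl) .methyl_hydrogens(s) else integer(0)
  out <- NULL
  for (i in which(sp3)) {
    nb <- .neighbors(s, i)
    hs <- setdiff(nb[el[nb] == "H"], meth)
    if (length(hs)) out <- rbind(out, cbind(i, hs))
  }
  unprot <- which(sp3 & vapply(seq_along(el), function(i) {
    nb <- .neighbors(s, i)
    sum(el[nb] == "H") == 0 && length(nb) < 4
  }, logical(1)))
  list(pairs = out, unprotonated = unprot)
}

#' Detect CH-pi contacts between a receptor and a ligand
#'
#' A CH-pi contact exists when an aliphatic (sp3) C-H hydrogen lies within
#' `max_r` of an aromatic ring centroid of the binding partner. Both
#' directions are examined (ligand C-H against receptor rings and receptor
#' C-H against ligand rings). Residues containing any partial-occupancy
#' atom or with average B-factor above `max_b` are excluded (the ligand is
#' treated as a single residue); methyl hydrogens are excluded by default
#' because their rotational positions are not experimentally determined.
#' Contacts with theta1 < 35 and theta2 < 35 degrees are flagged as strong.
#'
#' @param receptor,ligand typed, protonated [chpi_structure()]s
#' @param max_r H-centroid cutoff, angstrom (default 3.5)
#' @param max_b B-factor exclusion threshold, angstrom^2 (default 40)
#' @param exclude_methyl drop methyl hydrogens from detection (default TRUE)
#' @return a `chpi_contacts` data.frame, one row per contact, with the
#'   descriptor columns of [chpi_geometry()] plus `passed_strong`
#' @export
detect_contacts <- function(receptor, ligand, max_r = 3.5, max_b = 40,
                            exclude_methyl = TRUE) {
  sides <- list(
    list(donor = ligand, donor_label = "ligand", acceptor = receptor,
         acceptor_label = "receptor", donor_one = TRUE, acc_one = FALSE),
    list(donor = receptor, donor_label = "receptor", acceptor = ligand,
         acceptor_label = "ligand", donor_one = FALSE, acc_one = TRUE))
  rows <- list()
  for (sd in sides) {
    donor <- sd$donor; acceptor <- sd$acceptor
    cp <- .ch_pairs(donor, exclude_methyl)
    if (length(cp$unprotonated) && is.null(cp$pairs))
      stop("unprotonated aliphatic carbons in ", sd$donor_label, ": serial ",
           paste(donor$atoms$serial[cp$unprotonated], collapse = ", "),
           " (run add_aliphatic_hydrogens first)")
    if (is.null(cp$pairs)) next
    bad_d <- .excluded_residues(donor, max_b, as_one = sd$donor_one)
    bad_a <- .excluded_residues(acceptor, max_b, as_one = sd$acc_one)
    dkey <- if (sd$donor_one) rep("ALL", nrow(donor$atoms))
            else paste(donor$atoms$chain, donor$atoms$resid)
    akey <- if (sd$acc_one) rep("ALL", nrow(acceptor$atoms))
            else paste(acceptor$atoms$chain, acceptor$atoms$resid)
    rings <- perceive_aromatic_rings(acceptor)
    rings <- Filter(function(r) !any(akey[r$atom_indices] %in% bad_a), rings)
    if (!length(rings)) next
    keep <- !dkey[cp$pairs[, 1]] %in% bad_d
    pairs <- cp$pairs[keep, , drop = FALSE]
    xyz_d <- coords(donor)
    for (ri in seq_along(rings)) {
      ring <- rings[[ri]]
      for (k in seq_len(nrow(pairs))) {
        hpos <- xyz_d[pairs[k, 2], ]
        if (sqrt(sum((hpos - ring$centroid)^2)) > max_r) next
        g <- .chpi_geometry_xyz(xyz_d[pairs[k, 1], ], hpos, ring)
        rows[[length(rows) + 1]] <- data.frame(
          donor = sd$donor_label, ch_carbon = pairs[k, 1],
          ch_hydrogen = pairs[k, 2], ring_parent = ring$parent,
          ring_index = ri, R = g$R, theta = g$theta, omega = g$omega,
          theta1 = g$theta1, theta2 = g$theta2, r_h = g$r_h, r_v = g$r_v,
          c_centroid = g$c_centroid, theta2_directed = g$theta2_directed,
          passed_strong = g$theta1 < 35 && g$theta2 < 35,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = character(0), ch_carbon = integer(0),
               ch_hydrogen = integer(0), ring_parent = character(0),
               ring_index = integer(0), R = numeric(0), theta = numeric(0),
               omega = numeric(0), theta1 = numeric(0), theta2 = numeric(0),
               r_h = numeric(0), r_v = numeric(0), c_centroid = numeric(0),
               theta2_directed = numeric(0), passed_strong = logical(0))
  class(out) <- c("chpi_contacts", "data.frame")
  out
}

#' Summary statistics of a contact set
#'
#' Mean and standard deviation for each geometric descriptor, counts per
#' ring parent type, and histogram tabulations of theta, omega, theta2 and
#' the C-centroid distance. All descriptors are already folded to one ring
#' face, so mirror-image contacts aggregate identically.
#'
#' @param contacts a `chpi_contacts` table from [detect_contacts()]
#' @return list with elements `n`, `stats` (descriptor mean/sd), `by_parent`
#'   and `histograms`; `empty = TRUE` when no contacts were supplied
#' @export
summarize_contacts <- function(contacts) {
  desc <- c("R", "theta", "omega", "theta1", "theta2", "r_h", "r_v",
            "c_centroid")
  if (!nrow(contacts))
    return(list(empty = TRUE, n = 0L, stats = NULL, by_parent = NULL,
                histograms = NULL))
  stats_df <- data.frame(
    descriptor = desc,
    mean = vapply(desc, function(d) mean(contacts[[d]]), numeric(1)),
    sd = vapply(desc, function(d) stats::sd(contacts[[d]]), numeric(1)),
    row.names = NULL)
  stats_df$sd[is.na(stats_df$sd)] <- 0
  parent_type <- sub(" .*", "", contacts$ring_parent)
  hists <- lapply(c("theta", "omega", "theta2", "c_centroid"), function(d)
    graphics::hist(contacts[[d]], plot = FALSE))
  names(hists) <- c("theta", "omega", "theta2", "c_centroid")
  list(empty = FALSE, n = nrow(contacts), stats = stats_df,
       by_parent = table(parent_type), histograms = hists)
}
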