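# Structural constants of the CH-pi radial kernel. The kernel is a
# single-well Gaussian in the pair distance,
#   e(R) = -E * DEPTH_FRACTION * exp(-((R - R0) / (BREADTH_FACTOR * C))^2),
# whose depth fraction and breadth factor were fixed once against the
# methane-benzene dimer calibration anchors (base score ~ -0.4 and
# combined score ~ -1.0 kcal/mol over the ring face at 3.8 A vertical
# separation; average vertical-scan optimum 3.7 +/- 0.2 A at
# -1.2 +/- 0.2 kcal/mol) using the default parameter triples below.
# They are implementation constants, not user parameters.
.chpi_depth_fraction <- 0.45
.chpi_breadth_factor <- 4 / 3
.chpi_cutoff <- 8.0   # same neighbor cutoff as the base score, angstrom

#' Parameters of the hydrogen-dependent CH-pi energy
#'
#' @param e well-depth scale per H/ring-carbon pair, kcal/mol (default 0.29)
#' @param r0 optimal pair separation, angstrom (default 3.58)
#' @param c breadth parameter, angstrom (default 0.85)
#' @return a `chpi_params_h` object
#' @export
chpi_params_h <- function(e = 0.29, r0 = 3.58, c = 0.85) {
  if (any(c(e, r0, c) <= 0)) stop("CH-pi parameters must be positive")
  structure(list(e = e, r0 = r0, c = c), class = "chpi_params_h")
}

#' Parameters of the hydrogen-independent CH-pi energy
#'
#' @param e well-depth scale per C/ring-carbon pair, kcal/mol (default 0.26)
#' @param r0 optimal pair separation, angstrom (default 4.49)
#' @param c breadth parameter, angstrom (default 0.75)
#' @return a `chpi_params_c` object
#' @export
chpi_params_c <- function(e = 0.26, r0 = 4.49, c = 0.75) {
  if (any(c(e, r0, c) <= 0)) stop("CH-pi parameters must be positive")
  structure(list(e = e, r0 = r0, c = c), class = "chpi_params_c")
}

.chpi_kernel <- function(R, e, r0, c) {
  out <- -e * .chpi_depth_fraction *
    exp(-((R - r0) / (.chpi_breadth_factor * c))^2)
  out[R > .chpi_cutoff] <- 0
  out
}

#' Angular decay factor of the hydrogen-dependent CH-pi term
#'
#' Cosine decay in the tilt angle between the C-H vector and the ring
#' normal: 1 when they are parallel, 0 at and beyond perpendicular.
#'
#' @param theta2 tilt angle in degrees, in [0, 180]
#' @return scalar (vector) in [0, 1]
#' @export
f_theta <- function(theta2) {
  if (any(theta2 < 0 | theta2 > 180)) stop("theta2 must lie in [0, 180] degrees")
  out <- pmax(cos(theta2 * pi / 180), 0)
  out[theta2 >= 90] <- 0
  out
}

# pair decomposition used by both the energy and the grid fit:
# for every aliphatic C-H and every aromatic ring carbon, the H-carbon
# distance and the angular factor of that C-H against that ring
.chpi_pairs_h <- function(s, rings, ch_pairs = NULL) {
  if (is.null(ch_pairs)) {
    cp <- .ch_pairs(s, exclude_methyl = FALSE)
    ch_pairs <- cp$pairs
    if (is.null(ch_pairs)) {
      if (length(cp$unprotonated))
        stop("aliphatic carbons without hydrogens: serial ",
             paste(s$atoms$serial[cp$unprotonated], collapse = ", "),
             " (hydrogen-dependent mode needs explicit hydrogens)")
      return(list(R = numeric(0), f = numeric(0)))
    }
  }
  xyz <- coords(s)
  Rs <- numeric(0); fs <- numeric(0)
  for (k in seq_len(nrow(ch_pairs))) {
    cpos <- xyz[ch_pairs[k, 1], ]; hpos <- xyz[ch_pairs[k, 2], ]
    u <- hpos - cpos; u <- u / sqrt(sum(u^2))
    for (ring in rings) {
      ringward <- if (sum((ring$centroid - cpos) * ring$normal) >= 0)
        ring$normal else -ring$normal
      f <- max(sum(u * ringward), 0)
      if (f <= 0) next
      R <- sqrt(rowSums(sweep(ring$carbon_xyz, 2, hpos)^2))
      Rs <- c(Rs, R); fs <- c(fs, rep(f, length(R)))
    }
  }
  list(R = Rs, f = fs)
}

.chpi_pairs_c <- function(s, rings, carbons = NULL) {
  if (is.null(carbons)) carbons <- which(.sp3_carbon_flags(s))
  xyz <- coords(s)
  Rs <- numeric(0)
  for (i in carbons)
    for (ring in rings)
      Rs <- c(Rs, sqrt(rowSums(sweep(ring$carbon_xyz, 2, xyz[i, ])^2)))
  list(R = Rs)
}

#' Hydrogen-dependent CH-pi energy
#'
#' Sum over every (aliphatic H, aromatic ring carbon) pair of the radial
#' kernel scaled by the angular factor [f_theta()] of that C-H against the
#' ring normal. Hydrogens whose C-H vector points away from the ring have
#' zero angular factor and contribute nothing; ring heteroatoms are
#' excluded from the sum. The result is never positive.
#'
#' @param s the [chpi_structure()] bearing the aliphatic C-H groups
#' @param rings list of `chpi_ring` of the binding partner
#' @param params a [chpi_params_h()]
#' @param ch_pairs optional two-column matrix of (carbon, hydrogen) atom
#'   indices; by default every sp3 C-H in `s`
#' @return energy in kcal/mol (<= 0)
#' @export
e_chpi_h <- function(s, rings, params = chpi_params_h(), ch_pairs = NULL) {
  if (inherits(rings, "chpi_ring")) rings <- list(rings)
  pr <- .chpi_pairs_h(s, rings, ch_pairs)
  if (!length(pr$R)) return(0)
  sum(.chpi_kernel(pr$R, params$e, params$r0, params$c) * pr$f)
}

#' Hydrogen-independent CH-pi energy
#'
#' Same radial kernel as [e_chpi_h()] but with no angular factor, summed
#' over (aliphatic carbon, aromatic ring carbon) pairs; hydrogens are
#' ignored entirely.
#'
#' @param s the [chpi_structure()] bearing the aliphatic carbons
#' @param rings list of `chpi_ring` of the binding partner
#' @param params a [chpi_params_c()]
#' @param carbons optional indices of the aliphatic carbons to use
#' @return energy in kcal/mol (<= 0)
#' @export
e_chpi_c <- function(s, rings, params = chpi_params_c(), carbons = NULL) {
  if (inherits(rings, "chpi_ring")) rings <- list(rings)
  pr <- .chpi_pairs_c(s, rings, carbons)
  if (!length(pr$R)) return(0)
  sum(.chpi_kernel(pr$R, params$e, params$r0, params$c))
}

#' Base docking score constants
#'
#' Term weights and van der Waals radii of the re-implemented empirical
#' base scoring function (two attractive gaussians, quadratic soft
#' repulsion, hydrophobic and H-bond ramps, 8 angstrom cutoff), as
#' published for the original docking engine. Shipped unchanged in
#' `inst/extdata/base_score_constants.json` for auditability.
#'
#' @return named list of weights, radii and ramp limits
#' @export
vina_constants <- function() {
  list(weights = c(gauss1 = -0.035579, gauss2 = -0.005156,
                   repulsion = 0.840245, hydrophobic = -0.035069,
                   hbond = -0.587439),
       radii = c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5,
                 Cl = 1.8, Br = 2.0, I = 2.2),
       gauss1_width = 0.5, gauss2_offset = 3.0, gauss2_width = 2.0,
       hydrophobic_good = 0.5, hydrophobic_bad = 1.5,
       hbond_good = -0.7, hbond_bad = 0.0,
       cutoff = 8.0)
}

#' Base pairwise docking score
#'
#' Re-implementation of the published empirical docking score over
#' intermolecular heavy-atom pairs within the 8 angstrom cutoff: two
#' attractive gaussians and a quadratic soft repulsion in the surface
#' distance, a hydrophobic ramp between hydrophobic atoms and an H-bond
#' ramp between donor/acceptor pairs. Conformation-independent terms are
#' omitted, so two molecules at infinite separation score exactly zero.
#'
#' @param receptor,ligand typed [chpi_structure()]s (see [assign_atom_types()])
#' @return energy in kcal/mol
#' @export
vina_base_energy <- function(receptor, ligand) {
  for (s in list(receptor, ligand))
    if (!"docking_type" %in% names(s$atoms))
      stop("structure is untyped: run assign_atom_types first")
  ct <- vina_constants()
  hr <- .vina_heavy(receptor); hl <- .vina_heavy(ligand)
  if (!nrow(hr$xyz) || !nrow(hl$xyz)) return(0)
  dx <- outer(hr$xyz[, 1], hl$xyz[, 1], "-")
  dy <- outer(hr$xyz[, 2], hl$xyz[, 2], "-")
  dz <- outer(hr$xyz[, 3], hl$xyz[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  within <- r <= ct$cutoff
  if (!any(within)) return(0)
  d <- r - outer(hr$radius, hl$radius, "+")
  w <- ct$weights
  e <- w["gauss1"] * exp(-(d / ct$gauss1_width)^2) +
    w["gauss2"] * exp(-((d - ct$gauss2_offset) / ct$gauss2_width)^2) +
    w["repulsion"] * ifelse(d < 0, d^2, 0)
  hyd <- outer(hr$hydrophobic, hl$hydrophobic, "&")
  ramp_h <- pmin(pmax((ct$hydrophobic_bad - d) /
                        (ct$hydrophobic_bad - ct$hydrophobic_good), 0), 1)
  e <- e + w["hydrophobic"] * ifelse(hyd, ramp_h, 0)
  hb <- outer(hr$donor, hl$acceptor, "&") | outer(hr$acceptor, hl$donor, "&")
  ramp_b <- pmin(pmax((ct$hbond_bad - d) / (ct$hbond_bad - ct$hbond_good), 0), 1)
  e <- e + w["hbond"] * ifelse(hb, ramp_b, 0)
  sum(e[within])
}

.vina_heavy <- function(s) {
  ct <- vina_constants()
  keep <- s$atoms$element != "H"
  el <- s$atoms$element[keep]
  rad <- ct$radii[el]
  rad[is.na(rad)] <- 1.9
  list(xyz = coords(s)[keep, , drop = FALSE],
       radius = unname(rad),
       hydrophobic = s$atoms$hydrophobic[keep] %in% TRUE,
       donor = s$atoms$donor[keep] %in% TRUE,
       acceptor = s$atoms$acceptor[keep] %in% TRUE)
}

#' Combined interaction energy (base score plus weighted CH-pi term)
#'
#' `total = e_vina + w * e_chpi`, where the CH-pi term sums both
#' directions: ligand C-H groups against receptor rings and receptor C-H
#' groups against ligand rings. `w = 0.3` is the recommended general
#' weighting; parameter fitting uses `w = 1`.
#'
#' @param receptor,ligand typed [chpi_structure()]s; hydrogen-dependent
#'   mode additionally needs explicit aliphatic hydrogens
#' @param w CH-pi weighting factor in [0, 1]
#' @param mode `"hdep"` (hydrogen-dependent) or `"hindep"`
#' @param params_h,params_c parameter sets for the two modes
#' @return a `chpi_energy` breakdown with fields `e_vina`, `e_chpi`, `w`,
#'   `total`, `mode`
#' @export
total_energy <- function(receptor, ligand, w = 0.3,
                         mode = c("hdep", "hindep"),
                         params_h = chpi_params_h(),
                         params_c = chpi_params_c()) {
  mode <- match.arg(mode)
  if (!is.finite(w) || w < 0 || w > 1)
    stop("weighting factor w must lie in [0, 1]")
  ev <- vina_base_energy(receptor, ligand)
  rings_r <- perceive_aromatic_rings(receptor)
  rings_l <- perceive_aromatic_rings(ligand)
  ec <- if (mode == "hdep")
    e_chpi_h(ligand, rings_r, params_h) + e_chpi_h(receptor, rings_l, params_h)
  else
    e_chpi_c(ligand, rings_r, params_c) + e_chpi_c(receptor, rings_l, params_c)
  structure(list(e_vina = ev, e_chpi = ec, w = w, total = ev + w * ec,
                 mode = mode),
            class = "chpi_energy")
}

#' @export
print.chpi_energy <- function(x, ...) {
  cat(sprintf("E_vina  = %8.4f kcal/mol\n", x$e_vina))
  cat(sprintf("E_chpi  = %8.4f kcal/mol (%s)\n", x$e_chpi, x$mode))
  cat(sprintf("w       = %8.4f\n", x$w))
  cat(sprintf("total   = %8.4f kcal/mol\n", x$total))
  invisible(x)
}
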