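#' Idealized monomers
#'
#' Benzene is a planar D6h hexagon (C-C 1.391, C-H 1.087 angstrom) in the
#' xy-plane centered at the origin; methane is a regular tetrahedron
#' (C-H 1.091 angstrom) centered at the origin. Both are returned typed
#' and with bonds assigned.
#'
#' @param kind `"benzene"` or `"methane"`
#' @return a [chpi_structure()]
#' @export
build_monomer <- function(kind = c("benzene", "methane")) {
  kind <- match.arg(kind)
  if (kind == "benzene") {
    ang <- (0:5) * pi / 3
    cxy <- cbind(1.391 * cos(ang), 1.391 * sin(ang), 0)
    hxy <- cbind(2.478 * cos(ang), 2.478 * sin(ang), 0)
    atoms <- data.frame(
      serial = 1:12,
      name = c(paste0("C", 1:6), paste0("H", 1:6)),
      element = rep(c("C", "H"), each = 6),
      x = c(cxy[, 1], hxy[, 1]), y = c(cxy[, 2], hxy[, 2]),
      z = c(cxy[, 3], hxy[, 3]),
      occupancy = 1, b_factor = 0, resname = "BNZ", resid = 1L, chain = "A",
      stringsAsFactors = FALSE)
  } else {
    d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    atoms <- data.frame(
      serial = 1:5,
      name = c("C1", paste0("H", 1:4)),
      element = c("C", rep("H", 4)),
      x = c(0, 1.091 * d[, 1]), y = c(0, 1.091 * d[, 2]),
      z = c(0, 1.091 * d[, 3]),
      occupancy = 1, b_factor = 0, resname = "CH4", resid = 1L, chain = "L",
      stringsAsFactors = FALSE)
  }
  s <- chpi_structure(atoms, source_format = "internal")
  assign_atom_types(infer_bonds(s))
}

# Methane orientations of the six labeled dimer geometries, encoded as
# (orientation family, azimuth about the ring normal). A/D/E: vertex-down,
# one C-H on the ring axis pointing at the centroid (the unit-angular-factor
# family); B/F: edge-down, two hydrogens toward the ring; C: face-down
# tripod, three hydrogens toward the ring. Azimuths in degrees.
.dimer_orientations <- list(
  A = list(family = "vertex", azimuth = 0),
  B = list(family = "edge",   azimuth = 0),
  C = list(family = "face",   azimuth = 0),
  D = list(family = "vertex", azimuth = 30),
  E = list(family = "vertex", azimuth = 15),
  F = list(family = "edge",   azimuth = 30))

.methane_orient_dirs <- function(family, azimuth) {
  az <- azimuth * pi / 180
  rotz <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                           sin(a) * v[1] + cos(a) * v[2], v[3])
  tet <- .tetra * pi / 180
  if (family == "vertex") {
    pol <- pi - tet   # polar angle of the three up hydrogens, from +z
    d <- rbind(c(0, 0, -1),
               t(vapply(c(0, 2, 4) * pi / 3 + az, function(p)
                 c(sin(pol) * cos(p), sin(pol) * sin(p), cos(pol)), numeric(3))))
  } else if (family == "edge") {
    h <- tet / 2
    d <- rbind(c(sin(h), 0, -cos(h)), c(-sin(h), 0, -cos(h)),
               c(0, sin(h), cos(h)), c(0, -sin(h), cos(h)))
    d <- t(apply(d, 1, rotz, a = az))
  } else {  # face-down tripod
    pol <- tet        # polar angle of the three down hydrogens, from +z
    d <- rbind(c(0, 0, 1),
               t(vapply(c(0, 2, 4) * pi / 3 + az, function(p)
                 c(sin(pol) * cos(p), sin(pol) * sin(p), cos(pol)), numeric(3))))
  }
  1.091 * d
}

#' Specify a methane-benzene dimer geometry
#'
#' @param geometry label `"A"`-`"F"` selecting the methane orientation
#' @param r_v vertical methane-carbon-to-centroid distance, angstrom (> 0)
#' @param r_h horizontal offset, angstrom (>= 0)
#' @param offset_direction `"carbon"` (toward a ring carbon) or `"mid"`
#'   (toward a C-C bond midpoint)
#' @return a `chpi_dimer_spec`
#' @export
dimer_spec <- function(geometry, r_v = 3.8, r_h = 0,
                       offset_direction = c("mid", "carbon")) {
  offset_direction <- match.arg(offset_direction)
  if (!geometry %in% names(.dimer_orientations))
    stop("geometry must be one of ", paste(names(.dimer_orientations),
                                           collapse = ", "))
  if (r_v <= 0) stop("r_v must be positive")
  if (r_h < 0) stop("r_h must be non-negative")
  structure(list(geometry = geometry, r_v = r_v, r_h = r_h,
                 offset_direction = offset_direction),
            class = "chpi_dimer_spec")
}

#' Build a methane-benzene dimer
#'
#' Benzene sits in the xy-plane at the origin; methane is oriented per the
#' geometry label, then translated `r_v` along the ring normal and `r_h`
#' in-plane toward a ring carbon or a bond midpoint.
#'
#' @param spec a [dimer_spec()]
#' @return list with elements `receptor` (benzene) and `ligand` (methane)
#' @export
build_dimer <- function(spec) {
  stopifnot(inherits(spec, "chpi_dimer_spec"))
  benz <- build_monomer("benzene")
  met <- build_monomer("methane")
  ori <- .dimer_orientations[[spec$geometry]]
  dirs <- .methane_orient_dirs(ori$family, ori$azimuth)
  off_az <- if (spec$offset_direction == "carbon") 0 else pi / 6
  cpos <- c(spec$r_h * cos(off_az), spec$r_h * sin(off_az), spec$r_v)
  xyz <- rbind(cpos,
               sweep(dirs, 2, cpos, "+"))
  met$atoms$x <- xyz[, 1]; met$atoms$y <- xyz[, 2]; met$atoms$z <- xyz[, 3]
  list(receptor = benz, ligand = met)
}

#' Energy scorer factory for dimer scans
#'
#' @param w CH-pi weighting factor
#' @param mode `"hdep"`, `"hindep"` or `"base"` (base score only)
#' @param params_h,params_c CH-pi parameter sets
#' @return function(receptor, ligand) returning kcal/mol
#' @export
chpi_scorer <- function(w = 1, mode = c("hdep", "hindep", "base"),
                        params_h = chpi_params_h(), params_c = chpi_params_c()) {
  mode <- match.arg(mode)
  if (mode == "base")
    return(function(receptor, ligand) vina_base_energy(receptor, ligand))
  function(receptor, ligand)
    total_energy(receptor, ligand, w = w, mode = mode,
                 params_h = params_h, params_c = params_c)$total
}

.vertical_grid <- function() c(seq(3.0, 4.2, by = 0.1), seq(4.4, 6.0, by = 0.2))

.horizontal_grid <- function(direction)
  if (direction == "carbon") seq(0, 1.4, by = 0.1) else seq(0, 1.2, by = 0.1)

#' Scan a dimer energy curve
#'
#' Vertical scans use the grid 3.0-4.2 angstrom in 0.1 steps then 4.4-6.0
#' in 0.2 steps (22 points). Horizontal scans run 0.0-1.4 toward a ring
#' carbon (15 points) or 0.0-1.2 toward a bond midpoint (13 points).
#'
#' @param base a [dimer_spec()] giving the fixed coordinates of the scan
#' @param axis `"vertical"` or `"horizontal"`
#' @param scorer function(receptor, ligand) -> kcal/mol, e.g. [chpi_scorer()]
#' @param label free-text scorer label stored in the curve metadata
#' @return a `chpi_curve` data.frame with columns `abscissa`, `energy`
#' @export
scan_curve <- function(base, axis = c("vertical", "horizontal"), scorer,
                       label = "") {
  axis <- match.arg(axis)
  xs <- if (axis == "vertical") .vertical_grid()
        else .horizontal_grid(base$offset_direction)
  es <- vapply(xs, function(v) {
    sp <- base
    if (axis == "vertical") sp$r_v <- v else sp$r_h <- v
    dm <- build_dimer(sp)
    scorer(dm$receptor, dm$ligand)
  }, numeric(1))
  chpi_curve(xs, es, meta = list(spec = base, axis = axis, label = label))
}

#' Construct an energy curve
#'
#' @param abscissa strictly increasing distances, angstrom
#' @param energy energies, kcal/mol
#' @param meta metadata list (dimer spec, axis, scorer label)
#' @return a `chpi_curve`
#' @export
chpi_curve <- function(abscissa, energy, meta = list()) {
  if (length(abscissa) != length(energy)) stop("length mismatch")
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  out <- data.frame(abscissa = abscissa, energy = energy)
  attr(out, "meta") <- meta
  class(out) <- c("chpi_curve", "data.frame")
  out
}

#' Locate the minimum of an energy curve
#'
#' Finds the discrete minimum (ties resolved to the smallest abscissa) and
#' refines it with a parabola through the three bracketing points. A curve
#' whose discrete minimum sits on an endpoint carries no interior minimum
#' and is flagged.
#'
#' @param curve a `chpi_curve`
#' @return list with `abscissa`, `energy`, `no_minimum`
#' @export
find_minimum <- function(curve) {
  if (!nrow(curve)) stop("empty curve")
  x <- curve$abscissa; y <- curve$energy
  i <- which.min(y)
  if (i == 1L || i == length(y))
    return(list(abscissa = NA_real_, energy = NA_real_, no_minimum = TRUE))
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  den <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  A <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / den
  B <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / den
  if (A <= 0) return(list(abscissa = x1, energy = y1, no_minimum = FALSE))
  C0 <- (x1 * x2 * (x1 - x2) * y0 + x2 * x0 * (x2 - x0) * y1 +
           x0 * x1 * (x0 - x1) * y2) / den
  xm <- -B / (2 * A)
  list(abscissa = xm, energy = A * xm^2 + B * xm + C0, no_minimum = FALSE)
}

#' Synthetic CH-pi binding-site fixture
#'
#' Builds a receptor made of isolated PHE-like aromatic ring fragments and
#' a methane-probe ligand posed to realize sampled descriptor values, and
#' returns the ground-truth contact geometry. Each contact places the
#' interacting hydrogen on the ring axis at height `R` with the C-H axis
#' tilted by `theta2` from the normal; rings are spaced 12 angstrom apart
#' so contacts never interfere.
#'
#' @param n_contacts number of contacts (0 allowed)
#' @param descriptor_targets list with entries `R` (H-centroid distance,
#'   angstrom) and `theta2` (degrees), each either a numeric vector
#'   (recycled) or a function(n) sampling n values
#' @param seed integer seed; fixed seed gives identical output
#' @return list with `receptor`, `ligand`, `expected` (data.frame of
#'   ground-truth descriptors per contact)
#' @export
make_synthetic_site <- function(n_contacts,
                                descriptor_targets = list(R = 3.0, theta2 = 0),
                                seed = 1L) {
  set.seed(seed)
  draw <- function(entry, n, default) {
    if (is.null(entry)) rep(default, n)
    else if (is.function(entry)) entry(n)
    else rep(entry, length.out = n)
  }
  n <- n_contacts
  Rv <- draw(descriptor_targets$R, max(n, 1), 3.0)
  t2 <- draw(descriptor_targets$theta2, max(n, 1), 0)
  if (n > 0 && (any(Rv <= 1.2) || any(t2 < 0 | t2 >= 90)))
    stop("infeasible descriptor spec: need R > 1.2 and theta2 in [0, 90)")
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  rec_rows <- list(); lig_rows <- list(); expected <- list()
  centers <- if (n > 0) 12 * seq_len(n) else 0
  for (i in seq_len(max(n, 1))) {
    ctr <- c(centers[min(i, length(centers))], 0, 0)
    ang <- (0:5) * pi / 3
    rec_rows[[i]] <- data.frame(
      serial = (i - 1) * 6 + 1:6, name = ring_names, element = "C",
      x = ctr[1] + 1.39 * cos(ang), y = ctr[2] + 1.39 * sin(ang), z = ctr[3],
      occupancy = 1, b_factor = 20, resname = "PHE", resid = i, chain = "A",
      stringsAsFactors = FALSE)
    if (n == 0) break
    th <- t2[i] * pi / 180
    v <- c(sin(th), 0, cos(th))          # H -> C direction
    hpos <- ctr + c(0, 0, Rv[i])
    cpos <- hpos + 1.09 * v
    fr <- .perp_frame(v)   # v points from the interacting H to the carbon
    pol <- (180 - .tetra) * pi / 180
    others <- t(vapply(c(0, 2, 4) * pi / 3, function(a)
      cpos + 1.09 * (cos(pol) * v + sin(pol) *
                       (cos(a) * fr$e1 + sin(a) * fr$e2)), numeric(3)))
    xyz <- rbind(cpos, hpos, others)
    lig_rows[[i]] <- data.frame(
      serial = (i - 1) * 5 + 1:5,
      name = paste0(c("C", "H", "H", "H", "H"), i, c("", letters[1:4])),
      element = c("C", rep("H", 4)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 20, resname = "LIG", resid = 1L, chain = "L",
      stringsAsFactors = FALSE)
  }
  receptor <- assign_atom_types(infer_bonds(chpi_structure(
    do.call(rbind, rec_rows), source_format = "internal")))
  if (n == 0) {
    lig <- build_monomer("methane")
    lig$atoms$x <- lig$atoms$x + 100
    return(list(receptor = receptor, ligand = lig,
                expected = data.frame(R = numeric(0), theta2 = numeric(0))))
  }
  ligand <- assign_atom_types(infer_bonds(chpi_structure(
    do.call(rbind, lig_rows), source_format = "internal")))
  rings <- perceive_aromatic_rings(receptor)
  for (i in seq_len(n)) {
    g <- chpi_geometry(ligand, c_idx = (i - 1) * 5 + 1,
                       h_idx = (i - 1) * 5 + 2, ring = rings[[i]])
    expected[[i]] <- data.frame(contact = i, R = g$R, theta = g$theta,
                                theta1 = g$theta1, theta2 = g$theta2,
                                c_centroid = g$c_centroid)
  }
  list(receptor = receptor, ligand = ligand,
       expected = do.call(rbind, expected))
}
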