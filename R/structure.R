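#' Molecular structure container
#'
#' A `chpi_structure` holds an ordered atom table, a bond list and the
#' source format. Atoms carry the fields needed by the contact filters
#' (occupancy, B-factor) and by the scoring functions (docking type,
#' hydrophobicity and H-bond flags).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `b_factor`, `resname`, `resid`, `chain`.
#'   A `docking_type` column is added by [assign_atom_types()].
#' @param bonds two-column integer matrix of atom indices (row indices into
#'   `atoms`, not serials). May have zero rows.
#' @param source_format one of `"pdb"`, `"pdbqt"`, `"internal"`.
#' @return an object of class `chpi_structure`.
#' @export
chpi_structure <- function(atoms, bonds = NULL, source_format = "internal") {
  need <- c("serial", "name", "element", "x", "y", "z",
            "occupancy", "b_factor", "resname", "resid", "chain")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]")
  if (any(atoms$b_factor < 0)) stop("negative B-factor")
  bad <- !atoms$element %in% .periodic_symbols
  if (any(bad))
    stop("unknown element symbol: ", paste(unique(atoms$element[bad]), collapse = ", "))
  if (nrow(bonds)) {
    if (any(bonds < 1L) || any(bonds > nrow(atoms)))
      stop("bond indices reference non-existent atoms")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
  }
  structure(list(atoms = atoms, bonds = bonds, source_format = source_format,
                 annotations = list()),
            class = "chpi_structure")
}

.periodic_symbols <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","U")

#' @export
print.chpi_structure <- function(x, ...) {
  cat(sprintf("chpi_structure: %d atoms (%d H), %d bonds, source %s\n",
              nrow(x$atoms), sum(x$atoms$element == "H"),
              nrow(x$bonds), x$source_format))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param s a [chpi_structure()]
#' @return numeric matrix, one row per atom
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

`coords<-` <- function(s, value) {
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

.guess_element <- function(name, elesy = NULL) {
  if (!is.null(elesy) && nzchar(trimws(elesy))) {
    e <- trimws(elesy)
    e <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
    if (e %in% .periodic_symbols) return(e)
  }
  nm <- gsub("[0-9'\"]", "", trimws(name))
  two <- paste0(toupper(substr(nm, 1, 1)), tolower(substr(nm, 2, 2)))
  if (nchar(nm) >= 2 && two %in% c("Cl", "Br", "Fe", "Zn", "Mg", "Mn", "Na", "Ca", "Se"))
    return(two)
  one <- toupper(substr(nm, 1, 1))
  if (one %in% .periodic_symbols) return(one)
  stop("cannot assign an element to atom name '", name, "'")
}

#' Read a molecular structure from PDB or PDBQT
#'
#' PDB files are parsed with bio3d; PDBQT files (AutoDock dialect) are
#' parsed with a fixed-column reader. PDBQT torsion-tree records
#' (ROOT/BRANCH/TORSDOF) are tolerated and kept as annotations only.
#' When the file carries no CONECT records, bonds are inferred from
#' distance criteria (see [infer_bonds()]).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"` or `"pdbqt"`
#' @return a [chpi_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  s <- if (format == "pdbqt") .read_pdbqt(path) else .read_pdb(path)
  infer_bonds(s)
}

.read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  elements <- mapply(.guess_element, a$elety, a$elesy)
  atoms <- data.frame(
    serial = as.integer(a$eleno), name = trimws(a$elety),
    element = unname(elements),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    resname = trimws(a$resid), resid = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    stringsAsFactors = FALSE)
  chpi_structure(atoms, source_format = "pdb")
}

.read_pdbqt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  tree <- lines[grepl("^(ROOT|ENDROOT|BRANCH|ENDBRANCH|TORSDOF)", lines)]
  al <- lines[keep]
  if (!length(al)) stop("no ATOM/HETATM records in ", path)
  num <- function(str, a, b) {
    v <- suppressWarnings(as.numeric(substr(str, a, b)))
    v
  }
  x <- num(al, 31, 38); y <- num(al, 39, 46); z <- num(al, 47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("malformed PDBQT coordinates at line: ", al[bad[1]])
  adtype <- trimws(substr(al, 78, 79))
  elem <- vapply(seq_along(al), function(i) {
    t <- adtype[i]
    map <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
             SA = "S", S = "S", HD = "H", H = "H", HS = "H", P = "P",
             F = "F", Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I")
    if (t %in% names(map)) unname(map[t])
    else .guess_element(substr(al[i], 13, 16))
  }, character(1))
  occ <- num(al, 55, 60); b <- num(al, 61, 66)
  atoms <- data.frame(
    serial = as.integer(num(al, 7, 11)),
    name = trimws(substr(al, 13, 16)),
    element = elem, x = x, y = y, z = z,
    occupancy = ifelse(is.finite(occ), occ, 1),
    b_factor = ifelse(is.finite(b), b, 0),
    resname = trimws(substr(al, 18, 20)),
    resid = as.integer(num(al, 23, 26)),
    chain = ifelse(nzchar(trimws(substr(al, 22, 22))), trimws(substr(al, 22, 22)), "A"),
    stringsAsFactors = FALSE)
  s <- chpi_structure(atoms, source_format = "pdbqt")
  s$annotations$ad_types <- adtype
  s$annotations$torsion_tree <- tree
  s
}

#' Write a structure as PDB
#'
#' @param s a [chpi_structure()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(s))),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, o = a$occupancy,
                   b = a$b_factor, elesy = a$element)
  invisible(path)
}

#' Infer covalent bonds from interatomic distances
#'
#' Heavy-atom pairs closer than 1.9 angstrom (2.2 when sulfur is involved)
#' and hydrogen-heavy pairs closer than 1.2 angstrom are bonded. For the
#' standard amino acids these criteria reproduce template connectivity.
#' Existing bonds are kept.
#'
#' @param s a [chpi_structure()]
#' @return the structure with its bond list filled in
#' @export
infer_bonds <- function(s) {
  n <- nrow(s$atoms)
  if (n < 2) return(s)
  xyz <- coords(s)
  d <- as.matrix(stats::dist(xyz))
  isH <- s$atoms$element == "H"
  isS <- s$atoms$element %in% c("S", "Se")
  cut <- matrix(1.9, n, n)
  cut[isS, ] <- 2.2; cut[, isS] <- 2.2
  cut[isH, ] <- 1.2; cut[, isH] <- 1.2
  cut[isH, isH] <- 0          # H never bonds H
  adj <- d > 0.1 & d < cut
  # different residues only bond through heavy atoms (peptide/backbone links)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(s$bonds)) {
    old <- s$bonds
    key <- paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
    keyo <- paste(pmin(old[, 1], old[, 2]), pmax(old[, 1], old[, 2]))
    idx <- rbind(old, idx[!key %in% keyo, , drop = FALSE])
  }
  s$bonds <- matrix(as.integer(idx), ncol = 2)
  s
}

.neighbors <- function(s, i) {
  b <- s$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Add ideal aliphatic hydrogens
#'
#' Every sp3 CH/CH2/CH3 carbon is completed to four substituents with
#' ideal tetrahedral hydrogens at the chosen C-H bond length. Existing
#' hydrogens are never moved; the operation is idempotent. Carbons are
#' taken as sp3 unless they sit in an aromatic ring, have a double-bond
#' length neighbor (< 1.38 angstrom) or are planar three-coordinate.
#' Methyl hydrogens are built staggered to the heaviest vicinal
#' substituent (the contact detector excludes them separately).
#'
#' @param s a [chpi_structure()] with connectivity available
#' @param bond_length C-H bond length in angstrom (default 1.09, typical sp3)
#' @return a new structure with hydrogens appended
#' @export
add_aliphatic_hydrogens <- function(s, bond_length = 1.09) {
  if (!nrow(s$bonds) && nrow(s$atoms) > 1) s <- infer_bonds(s)
  xyz <- coords(s)
  arom <- .aromatic_flags(s)
  newH <- list()
  for (i in which(s$atoms$element == "C")) {
    nb <- .neighbors(s, i)
    if (length(nb) > 4) stop("carbon (serial ", s$atoms$serial[i],
                             ") has more than 4 bonds")
    if (length(nb) == 4 || arom[i]) next
    heavy <- nb[s$atoms$element[nb] != "H"]
    if (length(heavy)) {
      dmin <- min(sqrt(rowSums((xyz[heavy, , drop = FALSE] -
                                  matrix(xyz[i, ], length(heavy), 3, byrow = TRUE))^2)))
      if (dmin < 1.38) next   # sp2: double-bonded partner
    }
    u <- .unit_bond_vectors(xyz, i, nb)
    if (length(nb) == 3 && sqrt(sum(colSums(u)^2)) < 0.35) next  # planar sp2
    h <- .ideal_h_positions(xyz, s, i, nb, u, bond_length)
    for (k in seq_len(nrow(h))) newH[[length(newH) + 1]] <-
      list(parent = i, pos = h[k, ])
  }
  if (!length(newH)) return(s)
  a <- s$atoms
  hdf <- do.call(rbind, lapply(seq_along(newH), function(k) {
    p <- newH[[k]]$parent
    data.frame(serial = max(a$serial) + k,
               name = paste0("H", a$name[p], k),
               element = "H",
               x = newH[[k]]$pos[1], y = newH[[k]]$pos[2], z = newH[[k]]$pos[3],
               occupancy = a$occupancy[p], b_factor = a$b_factor[p],
               resname = a$resname[p], resid = a$resid[p], chain = a$chain[p],
               stringsAsFactors = FALSE)
  }))
  if ("docking_type" %in% names(a)) hdf$docking_type <- "hydrogen"
  for (cn in setdiff(names(a), names(hdf))) hdf[[cn]] <- NA
  out <- s
  out$atoms <- rbind(a, hdf[names(a)])
  nb_new <- cbind(vapply(newH, `[[`, integer(1) + 0L, "parent"),
                  nrow(a) + seq_along(newH))
  out$bonds <- rbind(s$bonds, matrix(as.integer(nb_new), ncol = 2))
  out
}

.unit_bond_vectors <- function(xyz, i, nb) {
  if (!length(nb)) return(matrix(numeric(0), ncol = 3))
  v <- xyz[nb, , drop = FALSE] - matrix(xyz[i, ], length(nb), 3, byrow = TRUE)
  v / sqrt(rowSums(v^2))
}

.perp_frame <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

.tetra <- 109.4712206  # ideal tetrahedral angle, degrees

.ideal_h_positions <- function(xyz, s, i, nb, u, bl) {
  c0 <- xyz[i, ]
  nmiss <- 4 - length(nb)
  if (length(nb) == 3) {
    d <- -colSums(u); d <- d / sqrt(sum(d^2))
    return(matrix(c0 + bl * d, 1, 3))
  }
  if (length(nb) == 2) {
    b <- -(u[1, ] + u[2, ]); b <- b / sqrt(sum(b^2))
    p <- u[1, ] - u[2, ]
    w <- c(b[2] * p[3] - b[3] * p[2], b[3] * p[1] - b[1] * p[3],
           b[1] * p[2] - b[2] * p[1])
    w <- w / sqrt(sum(w^2))
    half <- (.tetra / 2) * pi / 180
    return(rbind(c0 + bl * (cos(half) * b + sin(half) * w),
                 c0 + bl * (cos(half) * b - sin(half) * w)))
  }
  if (length(nb) == 1) {
    axis <- -u[1, ]
    # stagger relative to the heaviest substituent on the vicinal atom
    fr <- .perp_frame(axis)
    phase <- 0
    vic <- setdiff(.neighbors(s, nb[1]), i)
    if (length(vic)) {
      mass <- match(s$atoms$element[vic], .periodic_symbols)
      ref <- xyz[vic[which.max(mass)], ] - xyz[nb[1], ]
      ref <- ref - sum(ref * axis) * axis
      if (sum(ref^2) > 1e-8) {
        ref <- ref / sqrt(sum(ref^2))
        phase <- atan2(sum(ref * fr$e2), sum(ref * fr$e1)) + pi  # anti = staggered
      }
    }
    pol <- (180 - .tetra) * pi / 180
    ang <- phase + c(0, 2 * pi / 3, 4 * pi / 3)
    return(t(vapply(ang, function(a)
      c0 + bl * (cos(pol) * axis + sin(pol) * (cos(a) * fr$e1 + sin(a) * fr$e2)),
      numeric(3))))
  }
  # isolated carbon: full tetrahedron
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  t(apply(dirs[seq_len(nmiss), , drop = FALSE], 1, function(d) c0 + bl * d))
}

.aromatic_flags <- function(s) {
  fl <- rep(FALSE, nrow(s$atoms))
  rings <- tryCatch(perceive_aromatic_rings(s), error = function(e) list())
  for (r in rings) fl[r$atom_indices] <- TRUE
  fl
}

#' Assign docking atom types
#'
#' Carbons in perceived aromatic rings become `aromatic-carbon`; other
#' carbons `aliphatic-carbon`; nitrogens in aromatic rings `ring-nitrogen`;
#' N, O and S `polar` with donor/acceptor flags following the base-score
#' convention (O and N accept; N, O and S bonded to a hydrogen donate);
#' hydrogens `hydrogen`; anything else `other`. Carbons with a bonded
#' N/O/S heteroatom lose their hydrophobic flag.
#'
#' @param s a [chpi_structure()] with connectivity available
#' @return the structure with `docking_type`, `hydrophobic`, `donor` and
#'   `acceptor` columns filled in
#' @export
assign_atom_types <- function(s) {
  if (!nrow(s$bonds) && nrow(s$atoms) > 1) s <- infer_bonds(s)
  el <- s$atoms$element
  arom <- .aromatic_flags(s)
  ty <- rep("other", length(el))
  ty[el == "C"] <- "aliphatic-carbon"
  ty[el == "C" & arom] <- "aromatic-carbon"
  ty[el %in% c("N", "O", "S", "P")] <- "polar"
  ty[el == "N" & arom] <- "ring-nitrogen"
  ty[el == "H"] <- "hydrogen"
  hydroph <- donor <- acceptor <- rep(FALSE, length(el))
  for (i in seq_along(el)) {
    nb <- .neighbors(s, i)
    nel <- el[nb]
    if (el[i] == "C")
      hydroph[i] <- !any(nel %in% c("N", "O", "S", "P", "F"))
    if (el[i] %in% c("O", "N")) acceptor[i] <- TRUE
    if (el[i] %in% c("N", "O", "S")) donor[i] <- any(nel == "H")
  }
  hydroph[el %in% c("F", "Cl", "Br", "I")] <- TRUE
  s$atoms$docking_type <- ty
  s$atoms$hydrophobic <- hydroph
  s$atoms$donor <- donor
  s$atoms$acceptor <- acceptor
  s
}
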