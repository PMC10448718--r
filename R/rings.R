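#' Aromatic ring perception
#'
#' Standard-residue rings come from templates: PHE and TYR contribute a
#' benzene ring, HIS an imidazole, and TRP an indole treated as two
#' independent rings (5- and 6-membered), each with its own centroid.
#' Any other 5- or 6-cycle of carbons/nitrogens (ligands, cofactors) is
#' found by subgraph matching on the bond graph and kept when the ring
#' atoms are coplanar within 0.2 angstrom maximum out-of-plane deviation
#' (a chair cyclohexane fails this test). The centroid is the unweighted
#' mean of the ring-atom coordinates; the normal is the unit normal of
#' the least-squares plane (sign arbitrary, normalized per use).
#'
#' @param s a [chpi_structure()] with connectivity available
#' @param planarity_tol maximum out-of-plane deviation, angstrom
#' @return list of `chpi_ring` objects with fields `atom_indices`,
#'   `centroid`, `normal`, `ring_carbons`, `parent`
#' @export
perceive_aromatic_rings <- function(s, planarity_tol = 0.2) {
  if (!nrow(s$bonds) && nrow(s$atoms) > 1) s <- infer_bonds(s)
  a <- s$atoms
  rings <- list()
  taken <- character(0)

  templ <- list(
    PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
    TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
    HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
    TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
               c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")))
  res_key <- paste(a$chain, a$resid)
  for (rk in unique(res_key)) {
    sel <- which(res_key == rk)
    rn <- a$resname[sel[1]]
    if (!rn %in% names(templ)) next
    for (names_t in templ[[rn]]) {
      idx <- sel[match(names_t, a$name[sel])]
      if (anyNA(idx)) next
      rings[[length(rings) + 1]] <- .make_ring(s, idx, parent = paste(rn, rk))
      taken <- c(taken, paste(sort(idx), collapse = "-"))
    }
  }

  # generic cycle perception for everything else
  if (nrow(s$bonds)) {
    heavy_ok <- a$element %in% c("C", "N")
    g <- igraph::graph_from_edgelist(s$bonds, directed = FALSE)
    if (igraph::vcount(g) < nrow(a))
      g <- igraph::add_vertices(g, nrow(a) - igraph::vcount(g))
    for (n_ring in c(5L, 6L)) {
      pat <- igraph::make_ring(n_ring)
      iso <- igraph::subgraph_isomorphisms(pat, g, method = "vf2")
      for (m in iso) {
        idx <- sort(as.integer(m))
        key <- paste(idx, collapse = "-")
        if (key %in% taken) next
        if (!all(heavy_ok[idx])) next
        verts <- as.integer(m)   # cycle order
        if (!.is_chordless(s, verts)) next
        if (.plane_dev(coords(s)[idx, , drop = FALSE]) > planarity_tol) next
        taken <- c(taken, key)
        parent <- if (a$resname[idx[1]] %in% names(templ))
          paste(a$resname[idx[1]], res_key[idx[1]]) else "ligand"
        rings[[length(rings) + 1]] <- .make_ring(s, verts, parent = parent)
      }
    }
  }
  rings
}

.is_chordless <- function(s, verts) {
  n <- length(verts)
  b <- s$bonds
  key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next
      if (paste(min(verts[i], verts[j]), max(verts[i], verts[j])) %in% key)
        return(FALSE)
    }
  }
  TRUE
}

.plane_fit <- function(p) {
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  n <- sv$v[, 3]
  list(centroid = ctr, normal = n / sqrt(sum(n^2)))
}

.plane_dev <- function(p) {
  pf <- .plane_fit(p)
  max(abs(sweep(p, 2, pf$centroid) %*% pf$normal))
}

.make_ring <- function(s, idx, parent) {
  p <- coords(s)[idx, , drop = FALSE]
  pf <- .plane_fit(p)
  carbons <- as.integer(idx[s$atoms$element[idx] == "C"])
  r <- list(atom_indices = as.integer(idx),
            ring_xyz = p,
            centroid = pf$centroid,
            normal = pf$normal,
            ring_carbons = carbons,
            carbon_xyz = coords(s)[carbons, , drop = FALSE],
            parent = parent)
  class(r) <- "chpi_ring"
  r
}

#' @export
print.chpi_ring <- function(x, ...) {
  cat(sprintf("chpi_ring (%d atoms, %d C) parent %s, centroid [%.2f %.2f %.2f]\n",
              length(x$atom_indices), length(x$ring_carbons), x$parent,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}
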