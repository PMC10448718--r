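#' Geometric descriptors of one C-H / aromatic-ring pair
#'
#' Computes the full descriptor set for a putative CH-pi contact:
#' \describe{
#'   \item{R}{H-centroid distance, angstrom.}
#'   \item{theta}{C-H-centroid angle at the hydrogen, degrees; 180 means
#'     the H points straight at the centroid.}
#'   \item{omega}{dihedral between the ring plane and the plane formed by
#'     the H and its two nearest ring carbons, measured about their shared
#'     edge; 90 places the H directly above the edge, values above 90 put
#'     it outside the ring perimeter.}
#'   \item{theta1}{angle between the aliphatic-carbon-centroid vector and
#'     the ring normal, folded to [0, 90].}
#'   \item{theta2}{tilt angle between the C-H bond axis and the ring
#'     normal, folded to [0, 90].}
#'   \item{r_h, r_v}{horizontal (in-plane) and vertical (along-normal)
#'     components of the carbon-centroid offset, angstrom.}
#'   \item{c_centroid}{carbon-centroid distance, angstrom.}
#' }
#' The hydrogen's own offsets are returned as `r_h_h`/`r_v_h` so that
#' R^2 = r_h_h^2 + r_v_h^2 holds exactly. `theta2_directed` is the
#' unfolded angle between the C->H vector and the ring-ward direction
#' (the normal oriented from the aliphatic carbon toward the ring plane);
#' it exceeds 90 degrees for hydrogens pointing away from the ring and is
#' the angle consumed by the hydrogen-dependent energy.
#'
#' @param s a [chpi_structure()]
#' @param c_idx,h_idx atom indices of the bonded aliphatic carbon and hydrogen
#' @param ring a `chpi_ring`
#' @return a `chpi_geometry` list
#' @export
chpi_geometry <- function(s, c_idx, h_idx, ring) {
  xyz <- coords(s)
  .chpi_geometry_xyz(xyz[c_idx, ], xyz[h_idx, ], ring)
}

.chpi_geometry_xyz <- function(cpos, hpos, ring) {
  n <- ring$normal
  if (sum(n^2) < 0.5 || !all(is.finite(n))) stop("degenerate ring normal")
  ctr <- ring$centroid
  hc <- ctr - hpos
  R <- sqrt(sum(hc^2))
  ch <- hpos - cpos
  u_ch <- ch / sqrt(sum(ch^2))
  theta <- .angle_deg(cpos - hpos, ctr - hpos)
  cc <- ctr - cpos
  c_centroid <- sqrt(sum(cc^2))
  r_v <- abs(sum(cc * n))
  r_h <- sqrt(max(c_centroid^2 - r_v^2, 0))
  r_v_h <- abs(sum(hc * n))
  r_h_h <- sqrt(max(R^2 - r_v_h^2, 0))
  theta1 <- .fold90(.angle_deg(-cc, n))
  theta2 <- .fold90(.angle_deg(u_ch, n))
  # ring-ward direction at the carbon: normal oriented toward the ring plane
  ringward <- if (sum((ctr - cpos) * n) >= 0) n else -n
  theta2_directed <- .angle_deg(u_ch, ringward)
  # omega: dihedral about the edge joining the two ring atoms nearest to H;
  # the second atom is constrained to be adjacent to the first in the ring
  # cycle so that the edge is a real ring bond (and the construction stays
  # well defined for symmetric axial poses)
  ring_xyz <- ring$ring_xyz
  nr <- nrow(ring_xyz)
  dH <- sqrt(rowSums(sweep(ring_xyz, 2, hpos)^2))
  i1 <- which.min(dH)
  nb <- c(if (i1 == 1) nr else i1 - 1, if (i1 == nr) 1 else i1 + 1)
  i2 <- nb[which.min(dH[nb])]
  p1 <- ring_xyz[i1, ]; p2 <- ring_xyz[i2, ]
  mid <- (p1 + p2) / 2
  e <- p2 - p1; e <- e / sqrt(sum(e^2))
  perp <- function(v) { w <- v - sum(v * e) * e; w }
  v_in <- perp(ctr - mid)      # in-plane, toward ring interior
  v_h <- perp(hpos - mid)
  omega <- .angle_deg(v_in, v_h)
  g <- list(R = R, theta = theta, omega = omega, theta1 = theta1,
            theta2 = theta2, r_h = r_h, r_v = r_v, c_centroid = c_centroid,
            r_h_h = r_h_h, r_v_h = r_v_h, theta2_directed = theta2_directed)
  class(g) <- "chpi_geometry"
  g
}

.angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

.fold90 <- function(ang) ifelse(ang > 90, 180 - ang, ang)

#' @export
print.chpi_geometry <- function(x, ...) {
  cat(sprintf(paste0("CH-pi geometry: R=%.3f A theta=%.1f omega=%.1f ",
                     "theta1=%.1f theta2=%.1f R_H=%.3f R_V=%.3f C-centroid=%.3f\n"),
              x$R, x$theta, x$omega, x$theta1, x$theta2, x$r_h, x$r_v,
              x$c_centroid))
  invisible(x)
}
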