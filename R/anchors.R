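#' Desk-scale dimer calibration anchors
#'
#' Recomputes, from scratch, the four quantities used to calibrate and
#' validate the CH-pi term on idealized methane-benzene dimers:
#' \describe{
#'   \item{t1}{base score alone, averaged over the horizontal trace
#'     (0-1.2 angstrom toward a C-C bond midpoint) of the canonical
#'     perpendicular dimer at 3.8 angstrom vertical separation, kcal/mol.}
#'   \item{t2}{same trace for the combined score (base plus
#'     hydrogen-dependent CH-pi term at unit weighting), kcal/mol.}
#'   \item{t3}{mean over the six dimer orientations of the vertical-scan
#'     minimum location of the combined score, angstrom.}
#'   \item{t4}{mean of the six minimum energies, kcal/mol.}
#' }
#'
#' @param params_h CH-pi parameters used for the combined score
#' @return list with entries `t1`, `t2`, `t3`, `t4`, each a list with
#'   `value` and `n` (trace points or geometries averaged), plus the
#'   per-geometry minima in `minima` and the two traces in `traces`
#' @export
dimer_anchors <- function(params_h = chpi_params_h()) {
  spec <- dimer_spec("A", r_v = 3.8, offset_direction = "mid")
  base <- scan_curve(spec, "horizontal", chpi_scorer(mode = "base"),
                     label = "base")
  comb <- scan_curve(spec, "horizontal",
                     chpi_scorer(w = 1, mode = "hdep", params_h = params_h),
                     label = "hdep w=1")
  sc <- chpi_scorer(w = 1, mode = "hdep", params_h = params_h)
  minima <- lapply(c("A", "B", "C", "D", "E", "F"), function(g)
    find_minimum(scan_curve(dimer_spec(g), "vertical", sc, label = g)))
  dist <- vapply(minima, `[[`, numeric(1), "abscissa")
  ener <- vapply(minima, `[[`, numeric(1), "energy")
  list(t1 = list(value = mean(base$energy), n = nrow(base)),
       t2 = list(value = mean(comb$energy), n = nrow(comb)),
       t3 = list(value = mean(dist), n = length(dist)),
       t4 = list(value = mean(ener), n = length(ener)),
       minima = data.frame(geometry = c("A", "B", "C", "D", "E", "F"),
                           abscissa = dist, energy = ener),
       traces = list(base = base, combined = comb))
}
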