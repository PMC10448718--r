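#' Define a rotatable bond
#'
#' @param axis_atoms two atom indices; the rotation axis runs from the
#'   first to the second
#' @param moving_set atom indices rotated by this bond (must not contain
#'   the axis atoms)
#' @param kind `"ligand-moiety"`, `"chi1"` or `"chi2"`
#' @return a `chpi_bond`
#' @export
rotatable_bond <- function(axis_atoms, moving_set,
                           kind = c("ligand-moiety", "chi1", "chi2")) {
  kind <- match.arg(kind)
  if (length(axis_atoms) != 2) stop("axis_atoms must be two atom indices")
  if (!length(moving_set)) stop("moving_set is empty")
  if (any(axis_atoms %in% moving_set))
    stop("axis atoms may not be in the moving set")
  structure(list(axis_atoms = as.integer(axis_atoms),
                 moving_set = as.integer(moving_set), kind = kind),
            class = "chpi_bond")
}

.rotate_about_bond <- function(xyz, axis_atoms, moving_set, angle_deg) {
  p0 <- xyz[axis_atoms[1], ]
  ax <- xyz[axis_atoms[2], ] - p0
  ax <- ax / sqrt(sum(ax^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  v <- sweep(xyz[moving_set, , drop = FALSE], 2, p0)
  xyz[moving_set, ] <- sweep(v %*% t(Rm), 2, p0, "+")
  xyz
}

#' Enumerate torsional rotamers on a 3-degree grid
#'
#' A grid search from 0 to 360 degrees in 3-degree increments over up to
#' two rotatable bonds yields `120^n` conformations. Enumeration is lazy:
#' the returned object holds the angle grid and a generator applying any
#' row to a fresh copy of the input coordinates.
#'
#' @param s a [chpi_structure()]
#' @param bonds list of one or two [rotatable_bond()]s
#' @param step grid increment, degrees (default 3)
#' @return a `chpi_rotamers` object with elements `angles` (matrix, one
#'   row per conformation) and `conformation(i)` returning the structure
#'   at row `i`
#' @export
enumerate_rotamers <- function(s, bonds, step = 3) {
  if (inherits(bonds, "chpi_bond")) bonds <- list(bonds)
  n <- length(bonds)
  if (n < 1 || n > 2) stop("between 1 and 2 rotatable bonds are supported")
  vals <- seq(0, 360 - step, by = step)
  angles <- as.matrix(expand.grid(rev(rep(list(vals), n)))[, n:1, drop = FALSE])
  colnames(angles) <- paste0("bond", seq_len(n))
  xyz0 <- coords(s)
  conformation <- function(i) {
    xyz <- xyz0
    for (b in seq_len(n))
      if (angles[i, b] != 0)
        xyz <- .rotate_about_bond(xyz, bonds[[b]]$axis_atoms,
                                  bonds[[b]]$moving_set, angles[i, b])
    out <- s
    coords(out) <- xyz
    out
  }
  structure(list(angles = angles, conformation = conformation,
                 bonds = bonds, step = step),
            class = "chpi_rotamers")
}

#' Intramolecular clash test
#'
#' Rejects a conformation when any non-bonded pair (1-2 and 1-3 pairs are
#' exempt; 1-4 pairs are checked) violates the inclusive thresholds:
#' heavy-heavy <= 2.0, heavy-hydrogen <= 1.75, hydrogen-hydrogen <= 1.40
#' angstrom.
#'
#' @param s a [chpi_structure()] with connectivity
#' @return `TRUE` when the conformation clashes (reject), else `FALSE`
#' @export
clash_filter <- function(s) {
  n <- nrow(s$atoms)
  if (n < 2) return(FALSE)
  xyz <- coords(s)
  isH <- s$atoms$element == "H"
  d <- as.matrix(stats::dist(xyz))
  thr <- matrix(2.0, n, n)
  thr[isH, ] <- 1.75; thr[, isH] <- 1.75
  thr[isH, isH] <- 1.40
  viol <- d <= thr
  diag(viol) <- FALSE
  if (nrow(s$bonds)) {
    adj <- matrix(FALSE, n, n)
    adj[s$bonds] <- TRUE
    adj <- adj | t(adj)
    onethree <- (adj %*% adj) > 0
    viol[adj | onethree] <- FALSE
  }
  any(viol)
}

.wrap180 <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

#' Torsion grid-search pose optimization
#'
#' Enumerates every rotamer of the subject's rotatable bonds (3-degree
#' grid), drops conformations failing [clash_filter()], scores survivors
#' with [total_energy()] against the partner, and returns the rotamer with
#' the most negative total. The rmsd to the reference pose is computed
#' over the moving-set heavy atoms in the fixed frame (no superposition);
#' angle deviations are wrapped to (-180, 180]. Exact score ties go to
#' the first angle tuple in grid order.
#'
#' @param receptor,ligand typed [chpi_structure()]s
#' @param bonds list of up to two [rotatable_bond()]s, indexing into the
#'   subject structure
#' @param subject which structure the bonds rotate: `"ligand"` or
#'   `"receptor"` (side-chain search). Only receptor-ligand interaction
#'   energy is scored; receptor-internal terms are not included
#' @param w,mode,params_h,params_c passed to [total_energy()]
#' @param reference reference pose of the subject (default: the input
#'   subject itself)
#' @param step torsion increment, degrees
#' @return a `chpi_rotamer_result` with `best_angles`, `best_breakdown`,
#'   `rmsd_to_reference`, `angle_deviation`, `n_enumerated`, `n_scored`
#' @export
best_rotamer <- function(receptor, ligand, bonds, subject = c("ligand", "receptor"),
                         w = 0.3, mode = c("hdep", "hindep"),
                         params_h = chpi_params_h(), params_c = chpi_params_c(),
                         reference = NULL, step = 3) {
  subject <- match.arg(subject)
  mode <- match.arg(mode)
  subj <- if (subject == "ligand") ligand else receptor
  if (is.null(reference)) reference <- subj
  rot <- enumerate_rotamers(subj, bonds, step = step)
  nconf <- nrow(rot$angles)
  best <- NULL; best_total <- Inf; nscored <- 0L
  for (i in seq_len(nconf)) {
    cand <- rot$conformation(i)
    if (clash_filter(cand)) next
    br <- if (subject == "ligand")
      total_energy(receptor, cand, w = w, mode = mode,
                   params_h = params_h, params_c = params_c)
    else
      total_energy(cand, ligand, w = w, mode = mode,
                   params_h = params_h, params_c = params_c)
    nscored <- nscored + 1L
    if (br$total < best_total) {   # strict: first (grid-order) tuple wins ties
      best_total <- br$total
      best <- list(angles = rot$angles[i, ], breakdown = br, structure = cand)
    }
  }
  if (is.null(best)) stop("no valid rotamer: every conformation clashes")
  mov <- sort(unique(unlist(lapply(rot$bonds, `[[`, "moving_set"))))
  mov <- mov[subj$atoms$element[mov] != "H"]
  rmsd <- if (length(mov)) {
    dd <- coords(best$structure)[mov, , drop = FALSE] -
      coords(reference)[mov, , drop = FALSE]
    sqrt(mean(rowSums(dd^2)))
  } else NA_real_
  ref_ang <- vapply(seq_along(rot$bonds), function(b) 0, numeric(1))
  structure(list(best_angles = best$angles,
                 best_breakdown = best$breakdown,
                 rmsd_to_reference = rmsd,
                 angle_deviation = .wrap180(best$angles - ref_ang),
                 n_enumerated = nconf, n_scored = nscored),
            class = "chpi_rotamer_result")
}

#' @export
print.chpi_rotamer_result <- function(x, ...) {
  cat(sprintf("best rotamer: angles (%s) deg, total %.4f kcal/mol, rmsd %.3f A (%d/%d rotamers scored)\n",
              paste(x$best_angles, collapse = ", "),
              x$best_breakdown$total, x$rmsd_to_reference,
              x$n_scored, x$n_enumerated))
  invisible(x)
}
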