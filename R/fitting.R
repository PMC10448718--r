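#' Fit range of a reference energy curve
#'
#' Fitting starts at the first grid point where the reference interaction
#' energy becomes negative (no interpolation) and ends at 6.0 angstrom.
#'
#' @param reference a `chpi_curve`
#' @return numeric `c(start, end)` in angstrom
#' @export
fit_range_from_curve <- function(reference) {
  neg <- which(reference$energy < 0)
  if (!length(neg)) stop("no fit range: reference energy is never negative")
  c(reference$abscissa[neg[1]], 6.0)
}

#' Specification of a grid-search parameter fit
#'
#' @param curves list of reference curves; each element is either a
#'   `chpi_curve` whose metadata names the dimer geometry, or a list with
#'   elements `reference` (the curve) and `geometry` (label `"A"`-`"F"`)
#' @param param_grid per-parameter `c(min, max, step)`; defaults to the
#'   stage-1 search box `e` 0.10-0.50, `r0` 1.50-4.55, `c` 0.05-2.00, all
#'   at 0.05 intervals
#' @param refine_halfwidth,refine_step stage-2 local refinement around the
#'   stage-1 winner (defaults 0.05 and 0.01)
#' @param fit_ranges optional list of `c(start, end)` per curve; by default
#'   derived from each reference via [fit_range_from_curve()]
#' @param w weighting factor used when reconstructing model curves
#'   (default 1, the value used during fitting)
#' @return a `chpi_fit_spec`
#' @export
fit_spec <- function(curves,
                     param_grid = list(e = c(0.10, 0.50, 0.05),
                                       r0 = c(1.50, 4.55, 0.05),
                                       c = c(0.05, 2.00, 0.05)),
                     refine_halfwidth = 0.05, refine_step = 0.01,
                     fit_ranges = NULL, w = 1) {
  if (!length(curves)) stop("empty curve set")
  curves <- lapply(curves, function(cv) {
    if (inherits(cv, "chpi_curve"))
      list(reference = cv, geometry = attr(cv, "meta")$spec$geometry)
    else cv
  })
  for (cv in curves) {
    if (is.null(cv$geometry) || !cv$geometry %in% names(.dimer_orientations))
      stop("every curve needs a dimer geometry label A-F")
    if (max(cv$reference$abscissa) < 6.0 - 1e-9)
      stop("reference curve must span to 6.0 angstrom")
  }
  for (g in param_grid) if (g[3] <= 0) stop("grid steps must be positive")
  if (is.null(fit_ranges))
    fit_ranges <- lapply(curves, function(cv) fit_range_from_curve(cv$reference))
  structure(list(curves = curves, param_grid = param_grid,
                 refine_halfwidth = refine_halfwidth,
                 refine_step = refine_step, fit_ranges = fit_ranges, w = w),
            class = "chpi_fit_spec")
}

# Precompute, per curve and scan point, the base-score energy and the
# CH-pi pair decomposition (distances + angular factors), so that model
# curves for any parameter triple are cheap linear algebra.
.fit_precompute <- function(spec, model) {
  lapply(seq_along(spec$curves), function(ci) {
    cv <- spec$curves[[ci]]
    xs <- cv$reference$abscissa
    rng <- spec$fit_ranges[[ci]]
    inr <- xs >= rng[1] - 1e-9 & xs <= rng[2] + 1e-9
    Rall <- numeric(0); fall <- numeric(0); pid <- integer(0)
    vina <- numeric(length(xs))
    for (p in seq_along(xs)) {
      dm <- build_dimer(dimer_spec(cv$geometry, r_v = xs[p]))
      vina[p] <- vina_base_energy(dm$receptor, dm$ligand)
      rings <- perceive_aromatic_rings(dm$receptor)
      pr <- if (model == "hdep") .chpi_pairs_h(dm$ligand, rings)
            else c(.chpi_pairs_c(dm$ligand, rings), list(f = NULL))
      if (length(pr$R)) {
        Rall <- c(Rall, pr$R)
        fall <- c(fall, if (model == "hdep") pr$f else rep(1, length(pr$R)))
        pid <- c(pid, rep(p, length(pr$R)))
      }
    }
    list(xs = xs, ref = cv$reference$energy, inrange = inr, vina = vina,
         R = Rall, f = fall, pid = pid, npoints = length(xs))
  })
}

# Exhaustive objective evaluation over a parameter box. The radial sums
# depend only on (r0, c); the depth e enters linearly, so it is swept as
# an inner vector. Ties resolve to the lexicographically smallest
# (e, r0, c) triple.
.fit_objective <- function(pre, grid_e, grid_r0, grid_c, w) {
  best <- NULL; best_obj <- Inf; neval <- 0L
  better <- function(obj, ee, r0, cc) {
    if (obj < best_obj - 1e-12) return(TRUE)
    if (obj > best_obj + 1e-12 || is.null(best)) return(FALSE)
    # tie: lexicographic (e, r0, c) ascending
    if (ee != best["e"]) return(ee < best["e"])
    if (r0 != best["r0"]) return(r0 < best["r0"])
    cc < best["c"]
  }
  for (r0 in grid_r0) for (cc in grid_c) {
    sps <- lapply(pre, function(pc) {
      sp <- numeric(pc$npoints)
      if (length(pc$R)) {
        wgt <- pc$f * exp(-((pc$R - r0) / (.chpi_breadth_factor * cc))^2) *
          (pc$R <= .chpi_cutoff)
        agg <- rowsum(wgt, pc$pid)
        sp[as.integer(rownames(agg))] <- agg[, 1]
      }
      sp
    })
    for (ee in grid_e) {
      obj <- 0
      for (ci in seq_along(pre)) {
        pc <- pre[[ci]]
        model <- pc$vina - w * ee * .chpi_depth_fraction * sps[[ci]]
        res <- (model - pc$ref)[pc$inrange]
        obj <- obj + sqrt(mean(res^2))
      }
      obj <- obj / length(pre)
      neval <- neval + 1L
      if (better(obj, ee, r0, cc)) {
        best_obj <- obj
        best <- c(e = ee, r0 = r0, c = cc)
      }
    }
  }
  list(params = best, obj = best_obj, n = neval)
}

#' Two-stage grid-search parameter fit
#'
#' Stage 1 evaluates every combination of the parameter box exhaustively;
#' the objective is the mean over curves of the rmsd between the model
#' curve (base score plus CH-pi term at the spec's weighting) and the
#' reference, restricted to each curve's fit range. Stage 2 refines the
#' winner locally (default +/- 0.05 at 0.01 steps, run once). Ties go to
#' the lexicographically smallest `(e, r0, c)`.
#'
#' @param spec a [fit_spec()]
#' @param model `"hdep"` (angular-weighted H/ring-carbon kernel) or
#'   `"hindep"` (carbon-only kernel)
#' @return a `chpi_fit` with `params`, `avg_rmsd`, `grid_points_evaluated`
#' @export
grid_fit <- function(spec, model = c("hdep", "hindep")) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "chpi_fit_spec"))
  pre <- .fit_precompute(spec, model)
  pg <- spec$param_grid
  gseq <- function(g) seq(g[1], g[2] + 1e-9, by = g[3])
  s1 <- .fit_objective(pre, gseq(pg$e), gseq(pg$r0), gseq(pg$c), spec$w)
  clamp <- function(v, g) v[v >= g[1] - 1e-9 & v <= g[2] + 1e-9]
  rseq <- function(center, g)
    clamp(seq(center - spec$refine_halfwidth, center + spec$refine_halfwidth
              + 1e-9, by = spec$refine_step), g)
  s2 <- .fit_objective(pre, rseq(s1$params["e"], pg$e),
                       rseq(s1$params["r0"], pg$r0),
                       rseq(s1$params["c"], pg$c), spec$w)
  win <- if (s2$obj <= s1$obj) s2 else s1
  wp <- unname(win$params)
  params <- if (model == "hdep") chpi_params_h(wp[1], wp[2], wp[3])
            else chpi_params_c(wp[1], wp[2], wp[3])
  structure(list(params = params, avg_rmsd = win$obj,
                 grid_points_evaluated = s1$n + s2$n,
                 stage1 = s1, model = model),
            class = "chpi_fit")
}

#' @export
print.chpi_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("chpi_fit (%s): e = %.2f, r0 = %.2f, c = %.2f; avg rmsd %.4f kcal/mol (%d grid points)\n",
              x$model, p$e, p$r0, p$c, x$avg_rmsd, x$grid_points_evaluated))
  invisible(x)
}

#' Fit the hydrogen-independent parameters
#'
#' The carbon-only functional form matches the angular-weighted form only
#' for the dimer orientations whose interacting hydrogen has unit angular
#' factor, so exactly the three curves labeled A, D and E must be
#' supplied.
#'
#' @param spec a [fit_spec()] whose curves are labeled A, D, E
#' @return a `chpi_fit` for the carbon-only kernel
#' @export
fit_h_independent <- function(spec) {
  labs <- vapply(spec$curves, function(cv) cv$geometry, character(1))
  extra <- setdiff(labs, c("A", "D", "E"))
  if (length(extra))
    stop("hydrogen-independent fitting uses curves A, D, E only; remove: ",
         paste(extra, collapse = ", "))
  if (!setequal(labs, c("A", "D", "E")) || length(labs) != 3)
    stop("supply exactly the three curves labeled A, D and E")
  grid_fit(spec, model = "hindep")
}

#' Synthetic reference curves from known parameters
#'
#' Generates vertical-scan energy curves (base score plus CH-pi at unit
#' weighting) for the labeled dimer geometries from a given parameter
#' triple, optionally adding gaussian noise. These stand in for external
#' reference data in parameter-recovery studies; they are synthetic, not
#' quantum-mechanical.
#'
#' @param geometries labels among A-F
#' @param mode `"hdep"` or `"hindep"`
#' @param params parameter object matching `mode`
#' @param noise_sd gaussian noise, kcal/mol (default 0)
#' @param seed seed used when `noise_sd > 0`
#' @return list of `chpi_curve`
#' @export
synth_reference_curves <- function(geometries = c("A", "B", "C", "D", "E", "F"),
                                   mode = c("hdep", "hindep"),
                                   params = NULL, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(params))
    params <- if (mode == "hdep") chpi_params_h() else chpi_params_c()
  scorer <- if (mode == "hdep")
    chpi_scorer(w = 1, mode = "hdep", params_h = params)
  else chpi_scorer(w = 1, mode = "hindep", params_c = params)
  if (noise_sd > 0) set.seed(seed)
  lapply(geometries, function(g) {
    cv <- scan_curve(dimer_spec(g), "vertical", scorer,
                     label = paste0("synthetic-", mode))
    if (noise_sd > 0) cv$energy <- cv$energy + stats::rnorm(nrow(cv), 0, noise_sd)
    cv
  })
}
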