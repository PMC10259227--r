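## Cubic energy grid around a chain: methyl-probe 12-6 Lennard-Jones map,
## retention of favorable points, per-point propensity scores.

#' Load methyl-probe Lennard-Jones parameters
#'
#' TSV with columns `element`, `epsilon` (kcal/mol) and `rmin` (Angstrom;
#' the per-atom contribution to the pair minimum distance). The `CH3` row
#' is the probe itself; pair parameters follow Lorentz-Berthelot rules:
#' `eps_ij = sqrt(eps_i * eps_probe)`, `rmin_ij = rmin_i + rmin_probe`.
#'
#' @param file Optional path to a parameter TSV; default is the packaged
#'   united-atom table.
#' @return Object of class `probe_params`: list with `elements`
#'   (data.frame element/epsilon/rmin) and `probe` (epsilon, rmin).
#' @export
load_probe_params <- function(file = NULL) {
  df <- utils::read.table(if (is.null(file)) ext_file("probe_params.tsv")
                          else file,
                          header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("element", "epsilon", "rmin") %in% names(df)),
            all(df$epsilon > 0), all(df$rmin > 0))
  probe <- df[df$element == "CH3", , drop = FALSE]
  if (nrow(probe) != 1) stop("parameter file must contain one CH3 probe row")
  structure(list(elements = df[df$element != "CH3", , drop = FALSE],
                 probe = list(epsilon = probe$epsilon, rmin = probe$rmin)),
            class = "probe_params")
}

pair_params <- function(params, elements) {
  i <- match(elements, params$elements$element)
  if (any(is.na(i))) {
    stop("no probe parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  list(eps = sqrt(params$elements$epsilon[i] * params$probe$epsilon),
       rmin = params$elements$rmin[i] + params$probe$rmin)
}

#' Build a cubic grid around a chain
#'
#' Axis-aligned box equal to the chain's atom bounding box expanded by
#' `padding` on all sides, discretized at `spacing` (cubic lattice).
#'
#' @param chain Chain data frame (non-empty).
#' @param spacing Grid resolution, Angstrom (default 0.9).
#' @param padding Box expansion beyond the atom bounding box, Angstrom
#'   (default 4.5, about the probe-carbon minimum distance, so that
#'   favorable points above the surface are inside the box).
#' @return Object of class `grid_map`: list with `origin` (3-vector),
#'   `spacing`, `dims` (3 integers), `padding`.
#' @export
build_grid <- function(chain, spacing = 0.9, padding = 4.5) {
  stopifnot(nrow(chain) > 0, spacing > 0, padding >= 0)
  lo <- c(min(chain$x), min(chain$y), min(chain$z)) - padding
  hi <- c(max(chain$x), max(chain$y), max(chain$z)) + padding
  dims <- as.integer(floor((hi - lo) / spacing + 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 padding = padding),
            class = "grid_map")
}

grid_axes <- function(grid) {
  lapply(1:3, function(d) {
    grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing
  })
}

#' Methyl-probe van der Waals energy at a point
#'
#' 12-6 Lennard-Jones sum over atoms:
#' `E = sum eps_ij * ((rmin_ij / r)^12 - 2 (rmin_ij / r)^6)`, zero beyond
#' the cutoff; the total is clamped at `clamp` inside atomic cores. At the
#' pair minimum distance from a single atom the energy is exactly
#' `-eps_ij`.
#'
#' @param point Numeric 3-vector, Angstrom.
#' @param atoms Chain data frame (uses `x`, `y`, `z`, `element`).
#' @param params `probe_params` object.
#' @param cutoff Nonbonded cutoff, Angstrom (default 8).
#' @param clamp Upper bound on the returned energy, kcal/mol.
#' @return Energy in kcal/mol.
#' @export
probe_energy <- function(point, atoms, params = load_probe_params(),
                         cutoff = 8, clamp = 1e3) {
  if (nrow(atoms) == 0) return(0)
  pp <- pair_params(params, atoms$element)
  dx <- atoms$x - point[1]; dy <- atoms$y - point[2]; dz <- atoms$z - point[3]
  r2 <- pmax(dx * dx + dy * dy + dz * dz, 1e-4)
  keep <- r2 <= cutoff * cutoff
  if (!any(keep)) return(0)
  t <- (pp$rmin[keep]^2 / r2[keep])^3
  min(sum(pp$eps[keep] * (t * t - 2 * t)), clamp)
}

#' Probe energies over a whole grid
#'
#' Vectorized evaluation of [probe_energy()] at every grid point
#' (per-atom accumulation over the local index box inside the cutoff).
#'
#' @param grid A `grid_map`.
#' @inheritParams probe_energy
#' @return Numeric 3D array with dimensions `grid$dims`, kcal/mol.
#' @export
grid_energies <- function(grid, atoms, params = load_probe_params(),
                          cutoff = 8, clamp = 1e3) {
  ax <- grid_axes(grid)
  E <- array(0, dim = grid$dims)
  pp <- pair_params(params, atoms$element)
  c2 <- cutoff * cutoff
  for (a in seq_len(nrow(atoms))) {
    ix <- which(abs(ax[[1]] - atoms$x[a]) <= cutoff)
    iy <- which(abs(ax[[2]] - atoms$y[a]) <= cutoff)
    iz <- which(abs(ax[[3]] - atoms$z[a]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[[1]][ix] - atoms$x[a])^2
    dy2 <- (ax[[2]][iy] - atoms$y[a])^2
    dz2 <- (ax[[3]][iz] - atoms$z[a])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    r2c <- pmax(r2, 1e-4)
    t <- (pp$rmin[a]^2 / r2c)^3
    e <- pp$eps[a] * (t * t - 2 * t)
    e[r2 > c2] <- 0
    E[ix, iy, iz] <- E[ix, iy, iz] + e
  }
  E[E > clamp] <- clamp
  E
}

#' Retain grid points with favorable probe energy
#'
#' @param grid A `grid_map`.
#' @param atoms Chain data frame (used when `energies` is `NULL`).
#' @param threshold Energy threshold, kcal/mol (must be negative); points
#'   with `energy < threshold` are retained.
#' @param params `probe_params` object.
#' @param energies Optional precomputed array from [grid_energies()].
#' @param cutoff,clamp Passed to [grid_energies()].
#' @return Data frame of retained points, classed `grid_points`: columns
#'   `ix`, `iy`, `iz` (1-based grid indices), `lin` (linear index), `x`,
#'   `y`, `z`, `energy`.
#' @export
retain_favorable <- function(grid, atoms = NULL, threshold,
                             params = load_probe_params(), energies = NULL,
                             cutoff = 8, clamp = 1e3) {
  stopifnot(threshold < 0)
  if (is.null(energies)) {
    energies <- grid_energies(grid, atoms, params, cutoff, clamp)
  }
  idx <- which(energies < threshold, arr.ind = TRUE)
  ax <- grid_axes(grid)
  pts <- data.frame(
    ix = as.integer(idx[, 1]), iy = as.integer(idx[, 2]),
    iz = as.integer(idx[, 3]),
    lin = as.integer(which(energies < threshold)),
    x = ax[[1]][idx[, 1]], y = ax[[2]][idx[, 2]], z = ax[[3]][idx[, 3]],
    energy = energies[idx])
  pts <- pts[order(pts$lin), , drop = FALSE]
  rownames(pts) <- NULL
  class(pts) <- c("grid_points", "data.frame")
  pts
}

#' Propensity score of a grid point
#'
#' Sum of per-atom scores of the standard-residue atoms lying within
#' `radius` of the point (each residue contributes through its in-radius
#' atoms only).
#'
#' @param point Numeric 3-vector.
#' @param chain Chain data frame.
#' @param table A `propensity_table`.
#' @param radius Neighborhood radius, Angstrom (default 1.6).
#' @return Numeric score; 0 when no atom is within `radius`.
#' @export
grid_point_propensity <- function(point, chain, table, radius = 1.6) {
  stopifnot(radius > 0)
  d2 <- (chain$x - point[1])^2 + (chain$y - point[2])^2 +
    (chain$z - point[3])^2
  sel <- chain$std & d2 <= radius * radius
  if (!any(sel)) return(0)
  sum(per_atom_score(chain$residue_type[sel], table))
}

#' Propensity scores for many points
#'
#' Vectorized [grid_point_propensity()] over the rows of a point set.
#'
#' @param points Data frame with `x`, `y`, `z` columns.
#' @param chain Chain data frame.
#' @param table A `propensity_table`.
#' @param radius Neighborhood radius, Angstrom.
#' @return Numeric vector, one score per point.
#' @export
points_propensity <- function(points, chain, table, radius = 1.6) {
  stopifnot(radius > 0)
  n <- nrow(points)
  if (n == 0) return(numeric(0))
  ch <- chain[chain$std, , drop = FALSE]
  if (nrow(ch) == 0) return(numeric(n))
  pa <- per_atom_score(ch$residue_type, table)
  out <- numeric(n)
  r2 <- radius * radius
  chunk <- max(1L, floor(4e6 / nrow(ch)))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(points$x[idx], ch$x, "-")^2 +
      outer(points$y[idx], ch$y, "-")^2 +
      outer(points$z[idx], ch$z, "-")^2
    out[idx] <- as.numeric((d2 <= r2) %*% pa)
  }
  out
}

#' Combine per-point propensities into an overall score
#'
#' Weighted sum of the three per-point propensity scores, by default after
#' per-scale standardization (z-score over the supplied point set) so that
#' scales with different units are commensurable. A scale with zero spread
#' standardizes to 0.
#'
#' @param points Data frame with columns `rip_score`, `hydro_score`,
#'   `solv_score` (see [predict_sites()] for how they are filled).
#' @param weights Numeric length-3 weights in the order RIP,
#'   hydrophobicity, solvation; default equal.
#' @param standardize Standardize each scale over `points` first
#'   (default `TRUE`).
#' @return Numeric vector of overall propensities, one per point.
#' @export
overall_propensity <- function(points, weights = c(1, 1, 1),
                               standardize = TRUE) {
  cols <- c("rip_score", "hydro_score", "solv_score")
  stopifnot(all(cols %in% names(points)), length(weights) == 3)
  m <- as.matrix(points[, cols, drop = FALSE])
  if (standardize && nrow(m) > 0) {
    m <- apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
    })
    m <- matrix(m, ncol = 3)
  }
  as.numeric(m %*% weights)
}

#' @export
print.grid_map <- function(x, ...) {
  cat("grid_map:", paste(x$dims, collapse = " x "), "points at",
      x$spacing, "A spacing (", prod(x$dims), "total )\n")
  invisible(x)
}
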