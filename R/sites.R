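## Candidate sites: single-linkage clustering of retained grid points,
## mapping clusters to protein atoms, ranking, and precision/coverage
## overlap scoring against actual interfaces.

#' Cluster retained grid points by spatial proximity
#'
#' Single-linkage connected components at `linkage_cutoff`: two points are
#' linked when their distance is at most the cutoff. When more than
#' `max_clusters` components exist, the `max_clusters` largest are kept
#' (ties broken by lower total energy, then by lowest grid linear index).
#'
#' @param points Data frame of points (`x`, `y`, `z`; optional `energy`,
#'   `lin`), e.g. from [retain_favorable()].
#' @param max_clusters Cluster cap, default 15.
#' @param linkage_cutoff Linkage distance, Angstrom. Default
#'   `0.9 * sqrt(3) + 1e-9`, i.e. 26-neighbor connectivity of the default
#'   cubic grid.
#' @return List of clusters, each a data frame of member points (subset of
#'   `points` rows); ordered largest first.
#' @export
cluster_points <- function(points, max_clusters = 15,
                           linkage_cutoff = 0.9 * sqrt(3) + 1e-9) {
  n <- if (is.null(points)) 0L else nrow(points)
  if (n == 0) return(list())
  stopifnot(max_clusters >= 1, linkage_cutoff > 0)

  comp <- linkage_components(points$x, points$y, points$z, linkage_cutoff)
  groups <- split(seq_len(n), comp)

  energy <- if ("energy" %in% names(points)) points$energy else numeric(n)
  lin <- if ("lin" %in% names(points)) points$lin else seq_len(n)
  size <- lengths(groups)
  etot <- vapply(groups, function(g) sum(energy[g]), 0)
  lmin <- vapply(groups, function(g) min(lin[g]), 0)
  ord <- order(-size, etot, lmin)
  groups <- unname(groups[ord][seq_len(min(length(groups), max_clusters))])

  lapply(groups, function(g) {
    cl <- points[g, , drop = FALSE]
    rownames(cl) <- NULL
    cl
  })
}

## Connected components under distance <= cutoff, via cell hashing plus
## igraph; exact (every candidate pair is distance-checked).
linkage_components <- function(x, y, z, cutoff) {
  n <- length(x)
  if (n == 1) return(1L)
  ci <- floor(x / cutoff); cj <- floor(y / cutoff); ck <- floor(z / cutoff)
  key <- paste(ci, cj, ck)
  cells <- split(seq_len(n), key)
  ckey <- names(cells)
  cell_ijk <- do.call(rbind, lapply(strsplit(ckey, " "), as.numeric))
  offsets <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offsets <- offsets[offsets$di > 0 |
                       (offsets$di == 0 & offsets$dj > 0) |
                       (offsets$di == 0 & offsets$dj == 0 & offsets$dk >= 0), ]
  ef <- integer(0); et <- integer(0)
  c2 <- cutoff * cutoff
  for (o in seq_len(nrow(offsets))) {
    nb <- paste(cell_ijk[, 1] + offsets$di[o],
                cell_ijk[, 2] + offsets$dj[o],
                cell_ijk[, 3] + offsets$dk[o])
    m <- match(nb, ckey)
    same <- offsets$di[o] == 0 & offsets$dj[o] == 0 & offsets$dk[o] == 0
    for (ci2 in which(!is.na(m))) {
      p <- cells[[ci2]]; q <- cells[[m[ci2]]]
      if (same) {
        if (length(p) < 2) next
        pr <- utils::combn(p, 2)
        a <- pr[1, ]; b <- pr[2, ]
      } else {
        a <- rep(p, each = length(q)); b <- rep(q, times = length(p))
      }
      d2 <- (x[a] - x[b])^2 + (y[a] - y[b])^2 + (z[a] - z[b])^2
      hit <- d2 <= c2
      ef <- c(ef, a[hit]); et <- c(et, b[hit])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  as.integer(igraph::components(g)$membership)
}

#' Protein atoms occluded by a cluster of grid points
#'
#' Union over the cluster's member points of the chain atoms within
#' `radius` of any point, deduplicated.
#'
#' @param cluster Data frame of grid points (one cluster).
#' @param chain Chain data frame.
#' @param radius Occlusion radius, Angstrom (default 1.6).
#' @return Chain-like data frame of the selected atoms (classed
#'   `ppi_patch`), possibly empty.
#' @export
site_atoms <- function(cluster, chain, radius = 1.6) {
  stopifnot(radius > 0)
  hit <- rep(FALSE, nrow(chain))
  r2 <- radius * radius
  chunk <- max(1L, floor(4e6 / max(1, nrow(chain))))
  for (s in seq(1, max(1, nrow(cluster)), by = chunk)) {
    if (nrow(cluster) == 0) break
    idx <- s:min(s + chunk - 1L, nrow(cluster))
    d2 <- outer(cluster$x[idx], chain$x, "-")^2 +
      outer(cluster$y[idx], chain$y, "-")^2 +
      outer(cluster$z[idx], chain$z, "-")^2
    hit <- hit | (colSums(d2 <= r2) > 0)
  }
  p <- chain[hit, , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("ppi_patch", "data.frame")
  p
}

#' Rank candidate sites
#'
#' Builds one predicted site per cluster (occluded atoms, cumulative
#' parametric scores, total probe energy) and orders sites by the combined
#' standardized score `z(cumulative overall propensity) +
#' z(|total energy|)`, descending. Deterministic tie-break: larger cluster
#' first, then lowest grid linear index.
#'
#' @param clusters List of clusters from [cluster_points()]; points should
#'   carry `rip_score`, `hydro_score`, `solv_score` and `overall` columns
#'   (as filled by [predict_sites()]); when absent they are computed here
#'   from `tables` with `prop_radius`.
#' @param chain Chain data frame.
#' @param tables Named list of `propensity_table`s: `rip`, `hydro`, `solv`.
#' @param site_radius Occlusion radius for [site_atoms()], Angstrom.
#' @param prop_radius Radius for per-point propensities when they must be
#'   computed, Angstrom.
#' @param weights Length-3 weights for [overall_propensity()].
#' @return List of `predicted_site` objects, rank 1 first. Each site has
#'   `rank`, `points`, `atoms`, `scores` (named numeric: rip, hydro,
#'   solv), `cum_propensity`, `total_energy`, `rank_score`, `tau` (NA
#'   until evaluated).
#' @export
rank_sites <- function(clusters, chain, tables, site_radius = 1.6,
                       prop_radius = site_radius, weights = c(1, 1, 1)) {
  if (length(clusters) == 0) return(list())
  clusters <- lapply(clusters, function(cl) {
    if (!all(c("rip_score", "hydro_score", "solv_score") %in% names(cl))) {
      cl$rip_score <- points_propensity(cl, chain, tables$rip, prop_radius)
      cl$hydro_score <- points_propensity(cl, chain, tables$hydro, prop_radius)
      cl$solv_score <- points_propensity(cl, chain, tables$solv, prop_radius)
    }
    if (!"overall" %in% names(cl)) {
      cl$overall <- overall_propensity(cl, weights)
    }
    cl
  })
  sites <- lapply(clusters, function(cl) {
    atoms <- site_atoms(cl, chain, site_radius)
    list(points = cl,
         atoms = atoms,
         scores = c(rip = patch_score(atoms, tables$rip),
                    hydro = patch_score(atoms, tables$hydro),
                    solv = patch_score(atoms, tables$solv)),
         cum_propensity = sum(cl$overall),
         total_energy = sum(cl$energy))
  })
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  }
  score <- zs(vapply(sites, `[[`, 0, "cum_propensity")) +
    zs(abs(vapply(sites, `[[`, 0, "total_energy")))
  size <- vapply(sites, function(s) nrow(s$points), 0L)
  lmin <- vapply(sites, function(s) {
    if ("lin" %in% names(s$points)) min(s$points$lin) else 1
  }, 0)
  ord <- order(-score, -size, lmin)
  sites <- sites[ord]
  for (i in seq_along(sites)) {
    sites[[i]]$rank <- i
    sites[[i]]$rank_score <- score[ord][i]
    sites[[i]]$tau <- NA_real_
    class(sites[[i]]) <- "predicted_site"
  }
  sites
}

atom_keys <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0) return(character(0))
  unique(paste(atoms$chain_id, atoms$residue_seq, atoms$insert, atoms$name,
               sep = "\r"))
}

#' Overlap score between a predicted and an actual site
#'
#' Precision `p = |P intersect A| / |P|`, coverage
#' `c = |P intersect A| / |A|`, combined by default into the harmonic mean
#' `tau = 2pc / (p + c)` (0 when the intersection is empty); the `"min"`
#' method returns `min(p, c)` instead. Atoms are identified by chain,
#' residue number, insertion code and atom name.
#'
#' @param predicted_atoms,actual_atoms Atom data frames; `actual_atoms`
#'   must be non-empty.
#' @param method `"harmonic"` (default) or `"min"`.
#' @param detail Return `p` and `c` alongside `tau`.
#' @return `tau` in `[0, 1]`, or a list `(tau, precision, coverage)` when
#'   `detail = TRUE`.
#' @export
site_overlap_score <- function(predicted_atoms, actual_atoms,
                               method = c("harmonic", "min"),
                               detail = FALSE) {
  method <- match.arg(method)
  a <- atom_keys(actual_atoms)
  if (length(a) == 0) stop("actual atom set is empty")
  p <- atom_keys(predicted_atoms)
  inter <- length(intersect(p, a))
  prec <- if (length(p) == 0) 0 else inter / length(p)
  cov <- inter / length(a)
  tau <- if (inter == 0) {
    0
  } else if (method == "harmonic") {
    2 * prec * cov / (prec + cov)
  } else {
    min(prec, cov)
  }
  if (detail) list(tau = tau, precision = prec, coverage = cov) else tau
}

#' Evaluate the top-k predicted sites against an actual site
#'
#' @param sites List of `predicted_site`s (rank order).
#' @param actual_atoms Actual interface patch (non-empty atom set).
#' @param k Number of top-ranked sites considered.
#' @param tau_min Correctness threshold on tau (default 0.25, inclusive).
#' @param method Overlap combiner, see [site_overlap_score()].
#' @return List: `best_tau`, `correct` (`best_tau >= tau_min`),
#'   `coverage` (coverage of the best-tau site), `k`, `n_sites`.
#' @export
evaluate_topk <- function(sites, actual_atoms, k, tau_min = 0.25,
                          method = "harmonic") {
  stopifnot(k >= 1)
  top <- utils::head(sites, k)
  if (length(top) == 0) {
    return(list(best_tau = 0, correct = FALSE, coverage = 0, k = k,
                n_sites = 0L))
  }
  ev <- lapply(top, function(s) {
    site_overlap_score(s$atoms, actual_atoms, method, detail = TRUE)
  })
  taus <- vapply(ev, `[[`, 0, "tau")
  best <- which.max(taus)
  list(best_tau = taus[best], correct = taus[best] >= tau_min,
       coverage = ev[[best]]$coverage, k = k, n_sites = length(sites))
}

#' Write predicted sites as TSV
#'
#' One row per site atom: `rank`, `chain`, `residue_seq`, `residue_type`,
#' `atom`, `tau` (empty when not evaluated).
#'
#' @param sites List of `predicted_site`s.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sites_tsv <- function(sites, file) {
  rows <- lapply(sites, function(s) {
    if (nrow(s$atoms) == 0) return(NULL)
    data.frame(rank = s$rank, chain = s$atoms$chain_id,
               residue_seq = s$atoms$residue_seq,
               residue_type = s$atoms$residue_type, atom = s$atoms$name,
               tau = ifelse(is.na(s$tau), "", sprintf("%.4f", s$tau)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(rank = integer(), chain = character(),
                     residue_seq = integer(), residue_type = character(),
                     atom = character(), tau = character())
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write predicted sites as a PDB file for visualization
#'
#' Site atoms are written with the B-factor column set to the site rank.
#'
#' @param sites List of `predicted_site`s.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sites_pdb <- function(sites, file) {
  keep <- Filter(function(s) nrow(s$atoms) > 0, sites)
  if (length(keep) == 0) stop("no site atoms to write")
  atoms <- do.call(rbind, lapply(keep, function(s) s$atoms))
  b <- unlist(lapply(keep, function(s) rep(s$rank, nrow(s$atoms))))
  write_pdb(atoms, file, b = b)
}

#' @export
print.predicted_site <- function(x, ...) {
  cat(sprintf(
    "predicted_site rank %d: %d points, %d atoms, E=%.2f, scores(rip=%.2f, hydro=%.2f, solv=%.2f)%s\n",
    x$rank, nrow(x$points), nrow(x$atoms), x$total_energy,
    x$scores["rip"], x$scores["hydro"], x$scores["solv"],
    if (is.na(x$tau)) "" else sprintf(", tau=%.3f", x$tau)))
  invisible(x)
}
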