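## Orchestration: run configuration, training-phase domain scan over
## parameter pairs and energy thresholds, prediction on unbound chains,
## and dataset-level evaluation.

#' Run configuration
#'
#' Central defaults for the whole pipeline. Units are Angstrom for
#' lengths and kcal/mol for energies.
#'
#' @param spacing Grid resolution (default 0.9).
#' @param padding Grid box padding beyond the atom bounding box.
#' @param tolerance ACP demarcation tolerance.
#' @param min_acps Minimum ACPs per retained interface.
#' @param tau_min Correctness threshold on the overlap score.
#' @param max_sites Maximum predicted sites returned per chain (default 10).
#' @param max_clusters Cluster cap during site formation (default 15).
#' @param energy_thresholds Candidate probe-energy thresholds for the
#'   training scan (all negative).
#' @param site_radius Probe-contact radius used by the pipeline to map grid
#'   points to occluded atoms and to score per-point propensities. Default
#'   5.0, about the probe-carbon Lennard-Jones minimum distance (~4.1) plus
#'   ~1; a favorable grid point floats at that distance from the surface
#'   atoms it touches.
#' @param linkage_cutoff Single-linkage distance; default 26-neighbor
#'   connectivity of the cubic grid (`spacing * sqrt(3) + 1e-9`).
#' @param weights Length-3 weights (RIP, hydrophobicity, solvation) for the
#'   overall point propensity.
#' @param cutoff Nonbonded cutoff for the probe energy.
#' @param clamp Positive clamp on core-region energies.
#' @param tau_method Overlap combiner, `"harmonic"` or `"min"`.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed feeds fixture generation).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(spacing = 0.9, padding = 4.5, tolerance = 1.0,
                       min_acps = 20, tau_min = 0.25, max_sites = 10,
                       max_clusters = 15,
                       energy_thresholds = seq(-0.5, -3.0, by = -0.5),
                       site_radius = 5.0,
                       linkage_cutoff = spacing * sqrt(3) + 1e-9,
                       weights = c(1, 1, 1), cutoff = 8, clamp = 1e3,
                       tau_method = "harmonic", seed = 1L) {
  stopifnot(spacing > 0, padding >= 0, tolerance >= 0, min_acps >= 1,
            tau_min >= 0, tau_min <= 1, max_sites >= 1, max_clusters >= 1,
            all(energy_thresholds < 0), site_radius > 0, linkage_cutoff > 0)
  structure(list(spacing = spacing, padding = padding, tolerance = tolerance,
                 min_acps = min_acps, tau_min = tau_min,
                 max_sites = max_sites, max_clusters = max_clusters,
                 energy_thresholds = energy_thresholds,
                 site_radius = site_radius, linkage_cutoff = linkage_cutoff,
                 weights = weights, cutoff = cutoff, clamp = clamp,
                 tau_method = tau_method, seed = as.integer(seed)),
            class = "run_config")
}

#' Assemble the three propensity tables
#'
#' @param rip A RIP `propensity_table` (e.g. from [derive_rip()]), or a
#'   named numeric vector of per-residue RIP scores.
#' @param atom_counts Count table used when `rip` is a bare vector.
#' @return Named list `rip`, `hydro`, `solv` of `propensity_table`s.
#' @export
load_tables <- function(rip, atom_counts = default_atom_counts()) {
  if (!inherits(rip, "propensity_table")) {
    rip <- propensity_table("RIP", rip, atom_counts)
  }
  list(rip = rip, hydro = hydrophobicity_table(), solv = solvation_table())
}

## Grid + energy field for one chain, computed once and reused across
## thresholds. Per-point propensities are computed on the superset retained
## at the least stringent threshold.
precompute_chain <- function(chain, config, tables,
                             params = load_probe_params()) {
  grid <- build_grid(chain, config$spacing, config$padding)
  E <- grid_energies(grid, chain, params, config$cutoff, config$clamp)
  thr0 <- max(config$energy_thresholds)
  pts <- retain_favorable(grid, threshold = thr0, energies = E)
  if (nrow(pts)) {
    pts$rip_score <- points_propensity(pts, chain, tables$rip,
                                       config$site_radius)
    pts$hydro_score <- points_propensity(pts, chain, tables$hydro,
                                         config$site_radius)
    pts$solv_score <- points_propensity(pts, chain, tables$solv,
                                        config$site_radius)
  }
  list(grid = grid, energies = E, points = pts)
}

## Ranked, unfiltered candidate sites of one chain at one threshold.
candidate_sites <- function(pre, chain, threshold, config, tables) {
  pts <- pre$points[pre$points$energy < threshold, , drop = FALSE]
  if (nrow(pts) == 0) return(list())
  pts$overall <- overall_propensity(pts, config$weights)
  clusters <- cluster_points(pts, config$max_clusters, config$linkage_cutoff)
  rank_sites(clusters, chain, tables, site_radius = config$site_radius)
}

## Unbound chains of a complex together with their actual patches.
complex_chains <- function(complex) {
  ifc <- complex$interface
  ids <- ifc$chain_pair
  list(list(id = ids[1], chain = complex$chains[[ids[1]]],
            actual = ifc$patch_a),
       list(id = ids[2], chain = complex$chains[[ids[2]]],
            actual = ifc$patch_b))
}

## Candidate sites for every (complex, chain, threshold), with tau against
## the chain's actual patch attached to each site.
pipeline_candidates <- function(complexes, config, tables) {
  lapply(seq_along(complexes), function(ci) {
    cx <- complexes[[ci]]
    lapply(complex_chains(cx), function(side) {
      pre <- precompute_chain(side$chain, config, tables)
      per_thr <- lapply(config$energy_thresholds, function(thr) {
        sites <- candidate_sites(pre, side$chain, thr, config, tables)
        for (i in seq_along(sites)) {
          sites[[i]]$tau <- site_overlap_score(sites[[i]]$atoms, side$actual,
                                               config$tau_method)
        }
        sites
      })
      names(per_thr) <- sprintf("%g", config$energy_thresholds)
      list(complex = ci, id = side$id, actual = side$actual,
           sites = per_thr)
    })
  })
}

PAIR_NAMES <- list(c("rip", "hydro"), c("rip", "solv"), c("hydro", "solv"))

scan_from_candidates <- function(cands, domain_sets, config) {
  thr_lab <- sprintf("%g", config$energy_thresholds)
  accepted <- lapply(thr_lab, function(t) {
    lapply(PAIR_NAMES, function(p) {
      stats::setNames(list(integer(0), integer(0)), p)
    })
  })
  names(accepted) <- thr_lab
  for (i in seq_along(accepted)) {
    names(accepted[[i]]) <- vapply(PAIR_NAMES, paste, "", collapse = "_")
  }
  n_ok <- stats::setNames(integer(length(thr_lab)), thr_lab)
  log_rows <- list()

  for (cx in cands) for (side in cx) {
    for (t in thr_lab) {
      chain_ok <- FALSE
      for (s in side$sites[[t]]) {
        bins <- vapply(c("rip", "hydro", "solv"), function(sc) {
          domain_index(domain_sets[[sc]], s$scores[[sc]])
        }, 0L)
        ok <- s$tau >= config$tau_min
        for (p in PAIR_NAMES) {
          pn <- paste(p, collapse = "_")
          in_range <- !is.na(bins[p[1]]) && !is.na(bins[p[2]])
          if (ok && in_range) {
            chain_ok <- TRUE
            accepted[[t]][[pn]][[p[1]]] <-
              sort(unique(c(accepted[[t]][[pn]][[p[1]]], bins[[p[1]]])))
            accepted[[t]][[pn]][[p[2]]] <-
              sort(unique(c(accepted[[t]][[pn]][[p[2]]], bins[[p[2]]])))
          }
        }
        log_rows[[length(log_rows) + 1]] <- data.frame(
          complex = side$complex, chain = side$id, threshold = as.numeric(t),
          rank = s$rank, tau = s$tau, rip = unname(s$scores["rip"]),
          hydro = unname(s$scores["hydro"]), solv = unname(s$scores["solv"]),
          bin_rip = bins[["rip"]], bin_hydro = bins[["hydro"]],
          bin_solv = bins[["solv"]], stringsAsFactors = FALSE)
      }
      if (chain_ok) n_ok[t] <- n_ok[t] + 1L
    }
  }

  best <- thr_lab[which.max(n_ok)]  # ties: first (least stringent) wins
  n_chains <- sum(lengths(cands))
  structure(list(
    energy_threshold = as.numeric(best),
    domain_sets = domain_sets,
    accepted = accepted[[best]],
    stats = data.frame(threshold = as.numeric(thr_lab),
                       chains_accepted = as.integer(n_ok),
                       n_chains = n_chains,
                       fraction = as.numeric(n_ok) / n_chains),
    log = do.call(rbind, log_rows)
  ), class = "optimal_ranges")
}

#' Training-phase domain scan
#'
#' For every (parameter pair, domain combination, energy threshold), runs
#' prediction on each unbound training chain, scores candidate sites
#' against the chain's actual patch, and accumulates the domain bins of
#' sites reaching the overlap threshold. The returned optimal ranges hold,
#' at the best energy threshold (the one maximizing the number of chains
#' with an accepted site; ties go to the least stringent threshold), the
#' union of accepting bins per parameter of each pair.
#'
#' @param complexes List of complexes; each a list with `chains` (named
#'   list of chain data frames) and `interface` (a `ppi_interface`
#'   demarcating the actual site).
#' @param domain_sets Named list of `domain_set`s: `rip`, `hydro`, `solv`.
#' @param energy_thresholds Optional override of `config$energy_thresholds`.
#' @param config A [run_config()].
#' @param tables Propensity tables ([load_tables()]).
#' @return Object of class `optimal_ranges`: `energy_threshold`,
#'   `domain_sets`, `accepted` (per pair, the accepted bin indices per
#'   scale), `stats` (per-threshold acceptance), `log` (every scored
#'   (chain, threshold, site) tuple, for audit).
#' @export
scan_domains <- function(complexes, domain_sets, energy_thresholds = NULL,
                         config = run_config(), tables) {
  if (length(complexes) == 0) stop("empty training set")
  if (!is.null(energy_thresholds)) {
    stopifnot(all(energy_thresholds < 0))
    config$energy_thresholds <- energy_thresholds
  }
  cands <- pipeline_candidates(complexes, config, tables)
  ranges <- scan_from_candidates(cands, domain_sets, config)
  ranges$rip_scale <- tables$rip$per_residue
  ranges
}

#' Train optimal ranges on a set of complexes
#'
#' Full training phase: derives a RIP table from the training interfaces
#' (unless `tables` is supplied), generates candidate sites for every
#' chain and threshold, builds score domains from the IQR-filtered
#' candidate-site cumulative score distributions (Scott's-rule bins), and
#' runs the domain scan.
#'
#' @inheritParams scan_domains
#' @param tables Optional pre-built tables; derived from the training data
#'   when `NULL`.
#' @param rip_pseudocount Smoothing for [derive_rip()].
#' @return An `optimal_ranges` object (see [scan_domains()]).
#' @export
train_ranges <- function(complexes, config = run_config(), tables = NULL,
                         rip_pseudocount = 0.5) {
  if (length(complexes) == 0) stop("empty training set")
  if (is.null(tables)) {
    interfaces <- lapply(complexes, `[[`, "interface")
    ref_chains <- unlist(lapply(complexes, `[[`, "chains"), recursive = FALSE)
    tables <- load_tables(derive_rip(interfaces, ref_chains,
                                     rip_pseudocount))
  }
  cands <- pipeline_candidates(complexes, config, tables)
  score_pool <- list(rip = numeric(0), hydro = numeric(0),
                     solv = numeric(0))
  for (cx in cands) for (side in cx) for (t in names(side$sites)) {
    for (s in side$sites[[t]]) {
      for (sc in names(score_pool)) {
        score_pool[[sc]] <- c(score_pool[[sc]], unname(s$scores[sc]))
      }
    }
  }
  if (length(score_pool$rip) < 4) {
    stop("too few candidate sites to build score domains")
  }
  domain_sets <- lapply(names(score_pool), function(sc) {
    make_domains(remove_outliers_iqr(score_pool[[sc]]), sc)
  })
  names(domain_sets) <- names(score_pool)
  ranges <- scan_from_candidates(cands, domain_sets, config)
  ranges$rip_scale <- tables$rip$per_residue
  ranges
}

site_accepted <- function(site, ranges) {
  for (p in PAIR_NAMES) {
    pn <- paste(p, collapse = "_")
    acc <- ranges$accepted[[pn]]
    if (is.null(acc) || !length(acc[[p[1]]]) || !length(acc[[p[2]]])) next
    b1 <- domain_index(ranges$domain_sets[[p[1]]], site$scores[[p[1]]])
    b2 <- domain_index(ranges$domain_sets[[p[2]]], site$scores[[p[2]]])
    if (!is.na(b1) && !is.na(b2) && b1 %in% acc[[p[1]]] &&
        b2 %in% acc[[p[2]]]) {
      return(TRUE)
    }
  }
  FALSE
}

#' Predict interaction sites on an unbound chain
#'
#' Builds the energy grid, retains favorable points at the trained energy
#' threshold, clusters them, drops clusters whose cumulative parametric
#' scores fall outside the accepted domains (when ranges were learned),
#' ranks the survivors and returns at most `max_sites` sites. When the
#' domain filter would reject every cluster (or no domains were learned),
#' ranking proceeds unfiltered with a warning: the filter is a soft prior.
#'
#' @param chain Chain data frame.
#' @param ranges An `optimal_ranges` from [train_ranges()]/[scan_domains()],
#'   or `NULL` for unfiltered prediction at the first configured threshold.
#' @param config A [run_config()].
#' @param tables Propensity tables; when `NULL` and `ranges` carries a RIP
#'   scale, tables are rebuilt from it.
#' @param max_sites Override of `config$max_sites`.
#' @return List of `predicted_site`s (possibly empty), ranks `1..n`.
#' @export
predict_sites <- function(chain, ranges = NULL, config = run_config(),
                          tables = NULL, max_sites = config$max_sites) {
  if (is.null(tables)) {
    if (is.null(ranges$rip_scale)) {
      stop("supply 'tables' or ranges with an embedded RIP scale")
    }
    tables <- load_tables(unlist(ranges$rip_scale)[AA3])
  }
  pre <- precompute_chain(chain, config, tables)
  thr <- if (!is.null(ranges)) {
    ranges$energy_threshold
  } else {
    config$energy_thresholds[1]
  }
  if (nrow(pre$points) == 0 ||
      !any(pre$points$energy < thr)) {
    warning("no favorable grid points; empty prediction")
    return(list())
  }
  sites <- candidate_sites(pre, chain, thr, config, tables)
  if (!is.null(ranges)) {
    any_domains <- any(vapply(ranges$accepted, function(a) {
      all(lengths(a) > 0)
    }, TRUE))
    if (any_domains) {
      keep <- vapply(sites, site_accepted, TRUE, ranges = ranges)
      if (!any(keep)) {
        warning("domain filter rejected all candidate sites; ",
                "returning unfiltered ranking")
      } else {
        sites <- sites[keep]
      }
    } else {
      warning("no accepted domains learned; returning unfiltered ranking")
    }
  }
  sites <- utils::head(sites, max_sites)
  for (i in seq_along(sites)) sites[[i]]$rank <- i
  sites
}

#' Evaluate predictions over a dataset of complexes
#'
#' Predicts sites for every unbound chain of every complex and compares
#' them with the actual patches. A chain counts as correct when any of its
#' predicted sites reaches `tau_min`.
#'
#' @inheritParams scan_domains
#' @param ranges Trained `optimal_ranges`.
#' @param tau_min Correctness threshold (default from `config`).
#' @param tables Propensity tables; rebuilt from `ranges` when `NULL`.
#' @return List with `records` (one row per chain: `complex`, `chain`,
#'   `n_sites`, `best_tau`, `correct`, `cov_top1`, `cov_top2`) and
#'   `summary` (`accuracy`, `mean_cov_top1`, `mean_cov_top2`, `n_chains`).
#' @export
evaluate_dataset <- function(complexes, ranges, config = run_config(),
                             tables = NULL, tau_min = config$tau_min) {
  rows <- list()
  for (ci in seq_along(complexes)) {
    for (side in complex_chains(complexes[[ci]])) {
      sites <- suppressWarnings(
        predict_sites(side$chain, ranges, config, tables))
      full <- evaluate_topk(sites, side$actual, max(1, length(sites)),
                            tau_min, config$tau_method)
      t1 <- evaluate_topk(sites, side$actual, 1, tau_min, config$tau_method)
      t2 <- evaluate_topk(sites, side$actual, 2, tau_min, config$tau_method)
      rows[[length(rows) + 1]] <- data.frame(
        complex = ci, chain = side$id, n_sites = length(sites),
        best_tau = full$best_tau, correct = full$correct,
        cov_top1 = t1$coverage, cov_top2 = t2$coverage,
        tau_top2 = t2$best_tau, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  list(records = records,
       summary = list(accuracy = mean(records$correct),
                      mean_cov_top1 = mean(records$cov_top1),
                      mean_cov_top2 = mean(records$cov_top2),
                      n_chains = nrow(records)))
}

#' Serialize / restore optimal ranges as JSON
#'
#' The JSON carries the energy threshold, domain-set edges, accepted bins
#' per parameter pair, per-threshold scan statistics and the RIP scale
#' (the audit log stays in the R object only). Output is deterministic for
#' identical inputs.
#'
#' @param ranges An `optimal_ranges`.
#' @param file Path.
#' @return `write_ranges` returns `file` invisibly; `read_ranges` the
#'   restored `optimal_ranges`.
#' @export
write_ranges <- function(ranges, file) {
  payload <- list(
    energy_threshold = ranges$energy_threshold,
    domain_sets = lapply(ranges$domain_sets, unclass),
    accepted = ranges$accepted,
    stats = ranges$stats,
    rip_scale = as.list(ranges$rip_scale)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  ds <- lapply(raw$domain_sets, function(r) {
    structure(list(scale_name = r$scale_name, edges = as.numeric(r$edges),
                   n_bins = as.integer(r$n_bins)), class = "domain_set")
  })
  accepted <- lapply(raw$accepted, function(a) lapply(a, as.integer))
  structure(list(energy_threshold = as.numeric(raw$energy_threshold),
                 domain_sets = ds, accepted = accepted,
                 stats = as.data.frame(raw$stats),
                 rip_scale = unlist(raw$rip_scale)),
            class = "optimal_ranges")
}

#' @export
print.optimal_ranges <- function(x, ...) {
  cat("optimal_ranges: energy threshold", x$energy_threshold, "kcal/mol\n")
  for (pn in names(x$accepted)) {
    a <- x$accepted[[pn]]
    cat("  ", pn, ": ",
        paste(vapply(names(a), function(s) {
          paste0(s, "{", paste(a[[s]], collapse = ","), "}")
        }, ""), collapse = " x "), "\n", sep = "")
  }
  if (!is.null(x$stats)) {
    cat("  chains accepted per threshold:",
        paste(sprintf("%g:%d", x$stats$threshold, x$stats$chains_accepted),
              collapse = " "), "\n")
  }
  invisible(x)
}
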