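## Deterministic synthetic two-chain complexes with a constructed,
## recoverable interface. Residues are idealized stacks of carbon spheres
## on a lattice: chain A presents an elevated contact plateau, chain B
## mirrors it across a small gap, so the designated facing atom pairs are
## exactly the ACPs under the default demarcation parameters.

#' Specification of a synthetic complex
#'
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#' @param n_residues Residues per chain (lattice sites), default 40.
#' @param interface_size Target ACP count; this many centrally located
#'   lattice sites form the contact zone (one facing atom pair, hence one
#'   ACP, per contact site).
#' @param composition Optional named weights over the 20 residue types for
#'   sampling residue identities (uniform when `NULL`).
#' @param gap Distance between facing contact atoms, Angstrom; must stay
#'   below the carbon-carbon ACP cutoff `2 * 1.70 + tolerance`.
#' @param tolerance ACP tolerance the fixture must satisfy (default 1.0).
#' @param lattice_spacing Residue lattice spacing, Angstrom.
#' @param recess How far non-contact residues are recessed from the
#'   contact plane, Angstrom; must exceed the ACP cutoff minus `gap` so
#'   that only contact-zone atoms touch.
#' @param jitter Uniform coordinate jitter amplitude in x/y, Angstrom.
#' @return Validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_residues = 40, interface_size = 25,
                         composition = NULL, gap = 3.5, tolerance = 1.0,
                         lattice_spacing = 4.0, recess = 4.5,
                         jitter = 0.15) {
  cutoff <- 2 * 1.70 + tolerance
  if (gap + 2 * sqrt(2) * jitter >= cutoff) {
    stop("unsatisfiable fixture spec: gap too large for any ACP")
  }
  stopifnot(n_residues >= 1, interface_size >= 1,
            interface_size <= n_residues, recess + gap > cutoff,
            lattice_spacing > 2 * 1.3 + 2 * jitter)
  structure(list(seed = as.integer(seed), n_residues = n_residues,
                 interface_size = interface_size, composition = composition,
                 gap = gap, tolerance = tolerance,
                 lattice_spacing = lattice_spacing, recess = recess,
                 jitter = jitter),
            class = "fixture_spec")
}

## Idealized chain: one residue per lattice site, all carbon, serial
## numbers starting at serial0 + 1 so the two chains never collide.
## Contact residues present a flat contact layer -- up to 3 atoms in the
## contact plane (offsets 0, +1.3, -1.3 along x) with the remaining atoms
## stacked away from the plane at 1.5 A spacing; recessed residues stack
## all their atoms away from a plane `recess` further back. The flat
## layers of the two chains face each other across the gap, giving a
## multi-atom contact patch like a real interface layer.
fixture_chain <- function(spec, chain_id, types, contact, jxy, sign, z0,
                          serial0 = 0L) {
  counts <- residue_atom_count(types)
  names_pool <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CJ",
                  "CK", "CL")
  flat_dx <- c(0, 1.3, -1.3)
  nx <- ceiling(sqrt(spec$n_residues))
  site_x <- (((seq_len(spec$n_residues) - 1) %% nx)) * spec$lattice_spacing
  site_y <- (((seq_len(spec$n_residues) - 1) %/% nx)) * spec$lattice_spacing
  rows <- vector("list", spec$n_residues)
  serial <- 0L
  for (r in seq_len(spec$n_residues)) {
    n <- counts[r]
    nf <- if (contact[r]) min(n, 3L) else 0L
    top <- if (contact[r]) z0 else z0 + sign * spec$recess
    dx <- c(flat_dx[seq_len(nf)], rep(0, n - nf))
    dz <- if (nf > 0) c(rep(0, nf), 1.5 * seq_len(n - nf))
          else 1.5 * (seq_len(n) - 1)
    idx <- serial + seq_len(n)
    rows[[r]] <- data.frame(
      serial = serial0 + idx,
      name = names_pool[seq_len(n)],
      element = "C",
      residue_type = types[r],
      residue_seq = r,
      insert = "",
      chain_id = chain_id,
      x = site_x[r] + dx + jxy[idx, 1],
      y = site_y[r] + jxy[idx, 2],
      z = top + sign * dz,
      vdw_radius = vdw_radius("C"),
      std = TRUE,
      stringsAsFactors = FALSE)
    serial <- serial + n
  }
  ch <- do.call(rbind, rows)
  rownames(ch) <- NULL
  class(ch) <- c("ppi_chain", "data.frame")
  ch
}

## Contact zone: the interface_size lattice sites closest to the lattice
## centroid (deterministic tie-break by site index).
contact_sites <- function(spec) {
  nx <- ceiling(sqrt(spec$n_residues))
  sx <- ((seq_len(spec$n_residues) - 1) %% nx)
  sy <- ((seq_len(spec$n_residues) - 1) %/% nx)
  d2 <- (sx - mean(sx))^2 + (sy - mean(sy))^2
  ord <- order(d2, seq_along(d2))
  contact <- rep(FALSE, spec$n_residues)
  contact[ord[seq_len(spec$interface_size)]] <- TRUE
  contact
}

#' Generate a synthetic two-chain complex with a known interface
#'
#' Builds two idealized chains facing each other across `spec$gap`: the
#' contact-zone residues of each chain present their top atom at the
#' contact plane, everything else is recessed, so the facing top-atom
#' pairs of the contact zone are exactly the ACPs found by [find_acps()]
#' with the spec's tolerance. The ground-truth interface is recorded both
#' as the designated atom serials and as a demarcated `ppi_interface`.
#'
#' @param spec A [fixture_spec()].
#' @param contact_types Optional character vector (length
#'   `interface_size`) fixing the residue types of the contact zone on
#'   both chains; sampled from `spec$composition` when `NULL`.
#' @return List of class `ppi_fixture`: `chains` (named list `A`, `B`),
#'   `interface` (demarcated ground truth), `designated` (list
#'   `serial_a`, `serial_b` of the constructed contact atoms), `spec`.
#' @export
make_synthetic_complex <- function(spec, contact_types = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  contact <- contact_sites(spec)
  prob <- if (is.null(spec$composition)) NULL else spec$composition[AA3]

  gen <- withr::with_seed(spec$seed, {
    types_a <- sample(AA3, spec$n_residues, replace = TRUE, prob = prob)
    types_b <- sample(AA3, spec$n_residues, replace = TRUE, prob = prob)
    if (!is.null(contact_types)) {
      stopifnot(length(contact_types) == spec$interface_size,
                all(contact_types %in% AA3))
      types_a[contact] <- contact_types
      types_b[contact] <- contact_types
    }
    n_at <- sum(residue_atom_count(types_a))
    n_bt <- sum(residue_atom_count(types_b))
    jit <- matrix(stats::runif((n_at + n_bt) * 2, -spec$jitter,
                               spec$jitter), ncol = 2)
    list(types_a = types_a, types_b = types_b,
         jit_a = jit[seq_len(n_at), , drop = FALSE],
         jit_b = jit[n_at + seq_len(n_bt), , drop = FALSE])
  })

  chain_a <- fixture_chain(spec, "A", gen$types_a, contact, gen$jit_a,
                           sign = -1, z0 = 0)
  chain_b <- fixture_chain(spec, "B", gen$types_b, contact, gen$jit_b,
                           sign = +1, z0 = spec$gap,
                           serial0 = nrow(chain_a))

  ifc <- build_interface(chain_a, chain_b, tolerance = spec$tolerance)
  if (nrow(ifc$acps) < spec$interface_size) {
    stop("unsatisfiable fixture spec: constructed interface has ",
         nrow(ifc$acps), " ACPs, expected >= ", spec$interface_size)
  }
  top_a <- chain_a$serial[contact[chain_a$residue_seq] & chain_a$z == 0]
  top_b <- chain_b$serial[contact[chain_b$residue_seq] &
                            chain_b$z == spec$gap]
  structure(list(chains = list(A = chain_a, B = chain_b),
                 interface = ifc,
                 designated = list(serial_a = top_a, serial_b = top_b),
                 spec = spec),
            class = "ppi_fixture")
}

#' Generate a complex whose patch scores land in a target score bin
#'
#' Deterministic greedy adjustment of the contact-zone residue composition
#' (both chains share it) until the cumulative patch score under `table`
#' falls inside `target_bin`. Starts from an all-glycine contact zone, so
#' a bin covering the all-GLY score yields an all-GLY interface.
#'
#' @param spec A [fixture_spec()].
#' @param target_bin Numeric `c(lo, hi)`; membership is `lo <= s < hi`
#'   (closed at the top as for a final domain bin: `lo <= s <= hi`).
#' @param table `propensity_table` defining the score being targeted.
#' @param max_steps Bound on greedy replacement steps.
#' @return A `ppi_fixture` whose true patches score inside `target_bin`
#'   under `table`.
#' @export
make_scored_fixture <- function(spec, target_bin, table, max_steps = 1000) {
  stopifnot(length(target_bin) == 2, target_bin[1] < target_bin[2])
  ## per-site patch contribution: a contact residue exposes min(count, 3)
  ## atoms in the contact layer, each carrying its per-atom score
  pa <- per_atom_score(AA3, table) *
    pmin(residue_atom_count(AA3, table$atom_counts), 3)
  names(pa) <- AA3
  k <- spec$interface_size
  types <- rep("GLY", k)
  score <- sum(pa[types])
  inside <- function(s) s >= target_bin[1] && s <= target_bin[2]
  mid <- mean(target_bin)
  step <- 0L
  while (!inside(score) && step < max_steps) {
    step <- step + 1L
    i <- ((step - 1L) %% k) + 1L
    cand <- score - pa[types[i]] + pa
    best <- names(pa)[which.min(abs(cand - mid))]
    if (abs(cand[best] - mid) < abs(score - mid) - 1e-12) {
      score <- unname(cand[best])
      types[i] <- best
    } else if (i == k) {
      break  # full sweep with no improvement
    }
  }
  if (!inside(score)) {
    stop("target bin not achievable for scale '", table$scale_name,
         "' with ", k, " contact residues")
  }
  fx <- make_synthetic_complex(spec, contact_types = types)
  fx$target <- list(scale = table$scale_name, bin = target_bin,
                    score = score)
  fx
}

#' Write a fixture to disk
#'
#' PDB file of the complex plus a TSV of the ground-truth ACPs.
#'
#' @param fixture A `ppi_fixture`.
#' @param pdb_file,truth_file Output paths (`NULL` skips either).
#' @return Invisible list of the written paths.
#' @export
write_fixture <- function(fixture, pdb_file = NULL, truth_file = NULL) {
  if (!is.null(pdb_file)) write_pdb(fixture$chains, pdb_file)
  if (!is.null(truth_file)) write_acps_tsv(fixture$interface, truth_file)
  invisible(list(pdb = pdb_file, truth = truth_file))
}

#' @export
print.ppi_fixture <- function(x, ...) {
  cat("ppi_fixture: seed", x$spec$seed, "-", x$spec$n_residues,
      "residues/chain,", nrow(x$interface$acps), "ACPs\n")
  invisible(x)
}
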