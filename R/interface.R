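## Interface demarcation: atomic contact pairs (ACPs), interaction
## interfaces (PPIIs) and per-chain interacting patches (PPIPs).

#' Find atomic contact pairs between two chains
#'
#' Two heavy atoms on different chains form an atomic contact pair (ACP)
#' when their distance is strictly less than the sum of their van der Waals
#' radii plus a tolerance (default 1 Angstrom). Only standard-residue atoms
#' participate.
#'
#' @param chain_a,chain_b Chain data frames (see [parse_structure()]).
#' @param tolerance Tolerance added to the radius sum, Angstrom (>= 0).
#' @return A `data.frame` with one row per ACP: `index_a`, `index_b` (row
#'   indices into the chains), `chain_a`, `serial_a`, `chain_b`,
#'   `serial_b`, `distance`. Rows are ordered by (`index_a`, `index_b`).
#' @export
find_acps <- function(chain_a, chain_b, tolerance = 1.0) {
  stopifnot(tolerance >= 0)
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      chain_a = character(), serial_a = integer(),
                      chain_b = character(), serial_b = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (is.null(chain_a) || is.null(chain_b) ||
      nrow(chain_a) == 0 || nrow(chain_b) == 0) {
    return(empty)
  }
  ia <- which(chain_a$std)
  ib <- which(chain_b$std)
  if (length(ia) == 0 || length(ib) == 0) return(empty)

  bx <- chain_b$x[ib]; by <- chain_b$y[ib]; bz <- chain_b$z[ib]
  rb <- chain_b$vdw_radius[ib]
  out_a <- integer(0); out_b <- integer(0); out_d <- numeric(0)

  ## chunk over chain A rows to bound the distance-matrix size
  chunk <- max(1L, floor(4e6 / length(ib)))
  for (s in seq(1, length(ia), by = chunk)) {
    idx <- ia[s:min(s + chunk - 1L, length(ia))]
    dx <- outer(chain_a$x[idx], bx, "-")
    dy <- outer(chain_a$y[idx], by, "-")
    dz <- outer(chain_a$z[idx], bz, "-")
    d2 <- dx * dx + dy * dy + dz * dz
    cut <- outer(chain_a$vdw_radius[idx] + tolerance, rb, "+")
    hit <- which(d2 < cut * cut, arr.ind = TRUE)
    if (nrow(hit)) {
      out_a <- c(out_a, idx[hit[, 1]])
      out_b <- c(out_b, ib[hit[, 2]])
      out_d <- c(out_d, sqrt(d2[hit]))
    }
  }
  ord <- order(out_a, out_b)
  data.frame(index_a = out_a[ord], index_b = out_b[ord],
             chain_a = chain_a$chain_id[out_a[ord]],
             serial_a = chain_a$serial[out_a[ord]],
             chain_b = chain_b$chain_id[out_b[ord]],
             serial_b = chain_b$serial[out_b[ord]],
             distance = out_d[ord], stringsAsFactors = FALSE)
}

#' Assemble an interaction interface (PPII) from ACPs
#'
#' The interface is the collection of ACPs between one pair of chains; the
#' per-chain patches (PPIPs) are the deduplicated interacting atoms each
#' chain contributes, regardless of how many ACPs an atom participates in.
#'
#' @param chain_a,chain_b Chain data frames.
#' @param acps ACP table from [find_acps()] on the same chains; computed
#'   with `tolerance` when `NULL`.
#' @param tolerance Passed to [find_acps()] when `acps` is `NULL`.
#' @return An object of class `ppi_interface`: list with `chain_pair`,
#'   `acps`, `patch_a`, `patch_b` (each patch a chain-like `data.frame` of
#'   unique interacting atoms, classed `ppi_patch`).
#' @export
build_interface <- function(chain_a, chain_b, acps = NULL, tolerance = 1.0) {
  if (is.null(acps)) acps <- find_acps(chain_a, chain_b, tolerance)
  patch <- function(chain, idx) {
    p <- chain[sort(unique(idx)), , drop = FALSE]
    rownames(p) <- NULL
    class(p) <- c("ppi_patch", "data.frame")
    p
  }
  structure(list(
    chain_pair = c(if (nrow(chain_a)) chain_a$chain_id[1] else NA_character_,
                   if (nrow(chain_b)) chain_b$chain_id[1] else NA_character_),
    acps = acps,
    patch_a = patch(chain_a, acps$index_a),
    patch_b = patch(chain_b, acps$index_b)
  ), class = "ppi_interface")
}

#' Keep interfaces with a minimum number of ACPs
#'
#' @param interfaces List of `ppi_interface` objects.
#' @param min_acps Minimum ACP count (inclusive), default 20.
#' @return The retained interfaces, input order preserved.
#' @export
filter_interfaces <- function(interfaces, min_acps = 20) {
  stopifnot(min_acps >= 1)
  interfaces[vapply(interfaces, function(x) nrow(x$acps), 0L) >= min_acps]
}

#' Demarcate all pairwise interfaces of a structure
#'
#' Runs [find_acps()] on every pair of chains and keeps interfaces with at
#' least `min_acps` contact pairs.
#'
#' @param structure A `ppi_structure` (or named list of chains).
#' @param chains Optional character vector restricting which chain ids to
#'   consider.
#' @param tolerance ACP tolerance, Angstrom.
#' @param min_acps Minimum ACP count per retained interface.
#' @return List of `ppi_interface` objects.
#' @export
demarcate <- function(structure, chains = NULL, tolerance = 1.0,
                      min_acps = 20) {
  ids <- names(structure)
  if (!is.null(chains)) ids <- intersect(ids, chains)
  if (length(ids) < 2) stop("need at least two chains to demarcate")
  out <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      iface <- build_interface(structure[[ids[i]]], structure[[ids[j]]],
                               tolerance = tolerance)
      out[[paste(ids[i], ids[j], sep = ":")]] <- iface
    }
  }
  filter_interfaces(out, min_acps)
}

#' Write an ACP table as TSV
#'
#' Columns: `chain_a`, `serial_a`, `chain_b`, `serial_b`, `distance`.
#'
#' @param interface A `ppi_interface` (or bare ACP table).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_acps_tsv <- function(interface, file) {
  acps <- if (inherits(interface, "ppi_interface")) interface$acps else interface
  df <- acps[, c("chain_a", "serial_a", "chain_b", "serial_b", "distance")]
  df$distance <- sprintf("%.3f", df$distance)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.ppi_interface <- function(x, ...) {
  cat("ppi_interface", paste(x$chain_pair, collapse = ":"), "-",
      nrow(x$acps), "ACPs;", nrow(x$patch_a), "+", nrow(x$patch_b),
      "patch atoms\n")
  invisible(x)
}
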