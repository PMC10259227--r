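## Shared builders for toy chains, PDB text and score tables.

## A chain data frame from bare coordinates; defaults are lone glycines
## (one CA per residue) so every atom carries a full residue score.
toy_chain <- function(x, y = 0, z = 0, chain_id = "A",
                      residue_type = "GLY", element = "C",
                      name = "CA", residue_seq = NULL) {
  n <- length(x)
  y <- rep_len(y, n); z <- rep_len(z, n)
  residue_type <- rep_len(residue_type, n)
  element <- rep_len(element, n)
  chain_id <- rep_len(chain_id, n)
  if (is.null(residue_seq)) residue_seq <- seq_len(n)
  ch <- data.frame(
    serial = seq_len(n),
    name = rep_len(name, n),
    element = element,
    residue_type = residue_type,
    residue_seq = residue_seq,
    insert = rep_len("", n),
    chain_id = chain_id,
    x = x, y = y, z = z,
    vdw_radius = vdw_radius(element),
    std = residue_type %in% names(default_atom_counts()),
    stringsAsFactors = FALSE)
  class(ch) <- c("ppi_chain", "data.frame")
  ch
}

## Random blob of glycine CA atoms inside a box, for oracle comparisons.
random_chain <- function(n, chain_id = "A", span = 20,
                         elements = c("C", "N", "O", "S")) {
  toy_chain(stats::runif(n, 0, span), stats::runif(n, 0, span),
            stats::runif(n, 0, span), chain_id = chain_id,
            element = sample(elements, n, replace = TRUE))
}

## Minimal fixed-width PDB ATOM line.
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, element = "C", type = "ATOM",
                     alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, b, element)
}

## A constant score scale over the 20 residues.
flat_table <- function(value = 1, scale_name = "flat") {
  propensity_table(scale_name,
                   stats::setNames(rep(value, 20),
                                   names(default_atom_counts())))
}

## Tables for pipeline tests: uniform RIP plus the packaged scales.
toy_tables <- function() load_tables(stats::setNames(rep(1, 20),
                                     names(default_atom_counts())))

## A manually assembled interface from two patches (for scale tests that
## need interfaces without geometry).
manual_interface <- function(patch_a, patch_b) {
  class(patch_a) <- c("ppi_patch", "data.frame")
  class(patch_b) <- c("ppi_patch", "data.frame")
  structure(list(chain_pair = c(patch_a$chain_id[1], patch_b$chain_id[1]),
                 acps = data.frame(index_a = seq_len(nrow(patch_a))),
                 patch_a = patch_a, patch_b = patch_b),
            class = "ppi_interface")
}

## Brute-force ACP oracle: one pass per chain-A atom against every
## chain-B atom, no chunking, no candidate pruning.
acp_oracle <- function(chain_a, chain_b, tolerance) {
  res <- list()
  jj <- which(chain_b$std)
  for (i in which(chain_a$std)) {
    d <- sqrt((chain_a$x[i] - chain_b$x[jj])^2 +
              (chain_a$y[i] - chain_b$y[jj])^2 +
              (chain_a$z[i] - chain_b$z[jj])^2)
    hit <- d < chain_a$vdw_radius[i] + chain_b$vdw_radius[jj] + tolerance
    if (any(hit)) {
      res[[length(res) + 1]] <-
        data.frame(index_a = i, index_b = jj[hit], distance = d[hit])
    }
  }
  if (!length(res)) {
    return(data.frame(index_a = integer(), index_b = integer(),
                      distance = numeric()))
  }
  do.call(rbind, res)
}

## Default end-to-end fixture set (shared by pipeline/acceptance tests).
fixture_batch <- function(seeds) {
  lapply(seeds, function(s) make_synthetic_complex(fixture_spec(seed = s)))
}
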