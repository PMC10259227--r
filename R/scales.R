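## Per-residue score scales (residue interface propensity, hydrophobicity,
## solvation free energy), their per-atom decomposition, and cumulative
## patch scores.

#' Construct a propensity table
#'
#' A propensity table couples a per-residue score scale with the per-residue
#' heavy-atom counts used to decompose residue scores into per-atom scores
#' (residue score divided by the number of heavy atoms the residue normally
#' has, ignoring the peptide-bond backbone atoms N, C, O).
#'
#' @param scale_name Label, e.g. `"RIP"`, `"hydrophobicity"`, `"solvation"`.
#' @param per_residue Named numeric vector of residue scores covering the 20
#'   standard residues.
#' @param atom_counts Named integer vector of per-residue heavy-atom counts
#'   ([default_atom_counts()]).
#' @return Object of class `propensity_table`.
#' @export
propensity_table <- function(scale_name, per_residue,
                             atom_counts = default_atom_counts()) {
  missing <- setdiff(AA3, names(per_residue))
  if (length(missing)) {
    stop("scale '", scale_name, "' is missing residues: ",
         paste(missing, collapse = ", "))
  }
  if (!all(AA3 %in% names(atom_counts)) || any(atom_counts < 1)) {
    stop("atom_counts must cover all 20 standard residues with counts >= 1")
  }
  structure(list(scale_name = scale_name,
                 per_residue = per_residue[AA3],
                 atom_counts = atom_counts[AA3]),
            class = "propensity_table")
}

#' Load a score scale from a TSV file
#'
#' File format: two tab-separated columns `residue` and `score`, `#`
#' comments allowed.
#'
#' @param file Path to the scale file.
#' @param scale_name Label for the resulting table.
#' @inheritParams propensity_table
#' @return A `propensity_table`.
#' @export
load_scale <- function(file, scale_name = basename(file),
                       atom_counts = default_atom_counts()) {
  propensity_table(scale_name, read_kv_tsv(file, "residue", "score"),
                   atom_counts)
}

#' Packaged hydrophobicity scale (Hessa et al. 2005)
#' @return A `propensity_table` of apparent membrane-insertion free
#'   energies (kcal/mol).
#' @export
hydrophobicity_table <- function() {
  cached("hydro", function()
    load_scale(ext_file("hydrophobicity_hessa2005.tsv"), "hydrophobicity"))
}

#' Packaged solvation free-energy scale (Wimley & White 1996)
#' @return A `propensity_table` of interfacial transfer free energies
#'   (kcal/mol).
#' @export
solvation_table <- function() {
  cached("solv", function()
    load_scale(ext_file("solvation_wimley_white1996.tsv"), "solvation"))
}

#' Heavy-atom count of a residue excluding peptide-bond atoms
#'
#' @param residue_type 3-letter code(s), standard residues only.
#' @param counts Count table ([default_atom_counts()]).
#' @return Integer count(s); glycine is 1 (CA only).
#' @examples
#' residue_atom_count("TRP")  # 11
#' @export
residue_atom_count <- function(residue_type, counts = default_atom_counts()) {
  n <- counts[residue_type]
  if (any(is.na(n))) {
    stop("no atom count for residue(s): ",
         paste(unique(residue_type[is.na(n)]), collapse = ", "))
  }
  unname(n)
}

#' Per-atom score of a residue type under a scale
#'
#' The residue's scale score divided by its heavy-atom count (excluding
#' peptide-bond atoms), so that summing over a residue's counted atoms
#' reconstructs the residue score.
#'
#' @param residue_type 3-letter code(s).
#' @param table A `propensity_table`.
#' @return Numeric per-atom score(s).
#' @export
per_atom_score <- function(residue_type, table) {
  s <- table$per_residue[residue_type]
  if (any(is.na(s))) {
    stop("scale '", table$scale_name, "' has no score for residue(s): ",
         paste(unique(residue_type[is.na(s)]), collapse = ", "))
  }
  unname(s / table$atom_counts[residue_type])
}

#' Cumulative patch score under a scale
#'
#' Linear sum of per-atom scores over a patch's interacting atoms (the
#' cumulative RIP / hydrophobicity / solvation score of a PPIP). The empty
#' patch scores 0.
#'
#' @param patch A `ppi_patch` (or any data frame with a `residue_type`
#'   column; non-standard residues must be absent).
#' @param table A `propensity_table`.
#' @return Numeric scalar.
#' @export
patch_score <- function(patch, table) {
  if (is.null(patch) || nrow(patch) == 0) return(0)
  sum(per_atom_score(patch$residue_type, table))
}

#' Derive a residue interface propensity (RIP) table
#'
#' Frequency-ratio propensity: for each residue type, the pseudocount-
#' smoothed frequency of residues contributing at least one interacting
#' atom to an interface patch, divided by the smoothed frequency of the
#' type among all residues of the reference chains. A residue counts once
#' per interface regardless of how many of its atoms interact.
#'
#' @param interfaces List of `ppi_interface` objects (at least one).
#' @param reference_chains List of chain data frames giving the background
#'   residue composition.
#' @param pseudocount Additive smoothing, default 0.5 (must be > 0 unless
#'   every residue type occurs in both sets).
#' @param atom_counts Count table for the resulting `propensity_table`.
#' @return A `propensity_table` with `scale_name = "RIP"`; strictly
#'   positive scores when `pseudocount > 0`.
#' @export
derive_rip <- function(interfaces, reference_chains, pseudocount = 0.5,
                       atom_counts = default_atom_counts()) {
  if (length(interfaces) == 0) stop("need at least one interface")
  tally <- function(types) {
    tab <- table(factor(types, levels = AA3))
    as.numeric(tab)
  }
  iface_types <- unlist(lapply(interfaces, function(ifc) {
    unlist(lapply(list(ifc$patch_a, ifc$patch_b), function(p) {
      if (nrow(p) == 0) return(character(0))
      ## residue counted once per patch, however many of its atoms interact
      p$residue_type[!duplicated(paste(p$chain_id, p$residue_seq, p$insert))]
    }))
  }), use.names = FALSE)
  ref_types <- unlist(lapply(reference_chains, function(ch) {
    ch <- ch[ch$std, , drop = FALSE]
    ch$residue_type[!duplicated(paste(ch$chain_id, ch$residue_seq, ch$insert))]
  }), use.names = FALSE)

  ni <- tally(iface_types); Ni <- sum(ni)
  nr <- tally(ref_types); Nr <- sum(nr)
  if (pseudocount <= 0 && (any(ni == 0) || any(nr == 0))) {
    stop("zero counts present; use pseudocount > 0")
  }
  k <- length(AA3) * pseudocount
  fi <- (ni + pseudocount) / (Ni + k)
  fr <- (nr + pseudocount) / (Nr + k)
  propensity_table("RIP", stats::setNames(fi / fr, AA3), atom_counts)
}

#' @export
print.propensity_table <- function(x, ...) {
  cat("propensity_table '", x$scale_name, "' (20 residues)\n", sep = "")
  print(round(x$per_residue, 3))
  invisible(x)
}
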