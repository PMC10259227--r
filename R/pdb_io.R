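## PDB reading/writing. Parsing is delegated to bio3d; on top of its atom
## table we resolve altlocs by occupancy, infer elements, drop hydrogens,
## and attach van der Waals radii.

#' Parse a protein structure from PDB text or file
#'
#' Reads ATOM records, drops hydrogens and waters, resolves alternate
#' locations (highest occupancy wins, ties go to altloc "A"), optionally
#' maps selenomethionine-style modified residues to their parent residue,
#' and splits the result into chains.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB text
#'   (either one string with embedded newlines or one element per line).
#' @param model_policy `"first"` keeps the first MODEL of a multi-model
#'   file; `"error"` fails on multi-model input.
#' @param radii Named vector of van der Waals radii per element
#'   ([default_vdw_radii()]).
#' @param nonstandard How to treat non-standard residues: `"map"` renames
#'   residues listed in `mapping` to their parent type, keeps the rest
#'   flagged non-standard; `"keep"` keeps all flagged; `"drop"` removes them.
#' @param mapping Named character vector, modified residue -> parent.
#' @param on_unknown_element `"error"` or `"skip"` (skip drops the atom with
#'   a warning) for elements absent from `radii`.
#' @return An object of class `ppi_structure`: a named list of chains, each
#'   a `data.frame` with columns `serial`, `name`, `element`,
#'   `residue_type`, `residue_seq`, `insert`, `chain_id`, `x`, `y`, `z`,
#'   `vdw_radius`, `std` (logical: standard residue).
#' @examples
#' txt <- c(
#'  "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
#'  "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
#'  "END")
#' s <- parse_structure(txt)
#' names(s)
#' @export
parse_structure <- function(pdb,
                            model_policy = c("first", "error"),
                            radii = default_vdw_radii(),
                            nonstandard = c("map", "keep", "drop"),
                            mapping = c(MSE = "MET"),
                            on_unknown_element = c("error", "skip")) {
  model_policy <- match.arg(model_policy)
  nonstandard <- match.arg(nonstandard)
  on_unknown_element <- match.arg(on_unknown_element)

  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (!any(startsWith(lines, "ATOM"))) stop("no protein atoms in PDB input")
  n_models <- sum(startsWith(lines, "MODEL"))
  if (n_models > 1 && model_policy == "error") {
    stop("multi-model PDB input (", n_models, " models)")
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  p <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE,
                       hex = TRUE)
  a <- p$atom

  keep <- a$type == "ATOM"
  if (nonstandard != "drop" && length(mapping)) {
    ## HETATM records of known modified residues are protein atoms
    mod <- a$type == "HETATM" & a$resid %in% names(mapping)
    keep <- keep | mod
    if (nonstandard == "map") a$resid[mod] <- unname(mapping[a$resid[mod]])
  }
  a <- a[keep & !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms in PDB input")

  element <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  blank <- element == ""
  if (any(blank)) {
    guess <- gsub("[0-9']", "", trimws(a$elety[blank]))
    element[blank] <- toupper(substr(guess, 1, 1))
    two <- toupper(substr(guess, 1, 2)) %in% c("SE", "FE", "ZN", "MG", "CL")
    element[blank][two] <- toupper(substr(guess[two], 1, 2))
  }
  a$element <- element
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy protein atoms in PDB input")

  ## altloc resolution: one conformer per (chain, resno, insert, atom name)
  ins <- ifelse(is.na(a$insert), "", a$insert)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  key <- paste(a$chain, a$resno, ins, a$elety, sep = "\r")
  ord <- order(key, -occ, alt != "A", alt, method = "radix")
  keep_rows <- sort(seq_len(nrow(a))[ord][!duplicated(key[ord])])
  a <- a[keep_rows, , drop = FALSE]
  ins <- ifelse(is.na(a$insert), "", a$insert)

  unknown <- !(a$element %in% names(radii))
  if (any(unknown)) {
    bad <- unique(a$element[unknown])
    if (on_unknown_element == "error") {
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "))
    }
    warning("skipping atoms with unknown element(s): ",
            paste(bad, collapse = ", "))
    a <- a[!unknown, , drop = FALSE]
    ins <- ifelse(is.na(a$insert), "", a$insert)
  }

  std <- a$resid %in% AA3
  if (nonstandard == "drop") {
    a <- a[std, , drop = FALSE]
    ins <- ins[std]
    std <- rep(TRUE, nrow(a))
  }
  if (nrow(a) == 0) stop("no protein atoms left after filtering")

  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = a$element,
    residue_type = a$resid,
    residue_seq = a$resno,
    insert = ins,
    chain_id = ifelse(is.na(a$chain), " ", a$chain),
    x = a$x, y = a$y, z = a$z,
    vdw_radius = unname(default_radius_lookup(radii, a$element)),
    std = std,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite atom coordinates in PDB input")
  }

  chains <- split(atoms, atoms$chain_id)
  chains <- lapply(chains, function(ch) {
    rownames(ch) <- NULL
    class(ch) <- c("ppi_chain", "data.frame")
    ch
  })
  structure(chains, class = "ppi_structure")
}

default_radius_lookup <- function(radii, elements) radii[elements]

#' Van der Waals radius of an element
#'
#' @param element Element symbol(s), e.g. `"C"`.
#' @param radii Radii table as from [default_vdw_radii()].
#' @return Radius in Angstrom.
#' @examples
#' vdw_radius("C")  # 1.70
#' @export
vdw_radius <- function(element, radii = default_vdw_radii()) {
  r <- radii[element]
  if (any(is.na(r))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Write chains to a PDB file
#'
#' Serializes one or more chains (or a whole `ppi_structure`) back to PDB
#' ATOM records via bio3d. Coordinates survive a round trip to 3 decimals.
#'
#' @param chains A chain `data.frame`, a list of chains, or a
#'   `ppi_structure`.
#' @param file Output path.
#' @param b Optional numeric vector (recycled) written to the B-factor
#'   column, e.g. a site rank for visualization.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(chains, file, b = 0) {
  if (is.data.frame(chains)) chains <- list(chains)
  atoms <- do.call(rbind, lapply(chains, as.data.frame))
  b <- rep_len(b, nrow(atoms))
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)),
    eleno = atoms$serial,
    elety = atoms$name,
    resid = atoms$residue_type,
    chain = atoms$chain_id,
    resno = atoms$residue_seq,
    insert = ifelse(atoms$insert == "", NA, atoms$insert),
    o = rep(1, nrow(atoms)),
    b = b,
    elesy = atoms$element
  )
  invisible(file)
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat("ppi_structure:", length(x), "chain(s)\n")
  for (id in names(x)) {
    cat("  chain", id, "-", nrow(x[[id]]), "heavy atoms,",
        length(unique(paste(x[[id]]$residue_seq, x[[id]]$insert))),
        "residues\n")
  }
  invisible(x)
}
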