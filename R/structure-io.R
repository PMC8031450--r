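#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via \code{bio3d::read.pdb}) and returns the heavy-atom
#' record table in source-file order. Hydrogens (and deuteriums) are dropped,
#' water molecules (HOH/WAT/DOD/H2O residues) are removed, and alternate
#' locations are resolved by keeping altloc blank or 'A' records (first
#' occurrence wins on ties). Metal ions and cofactors present in the file are
#' kept and tagged as protein atoms. Only the first model of a multi-model
#' file is read.
#'
#' @param path Path to a PDB file.
#' @param id Identifier for the structure; defaults to the file base name.
#' @return A \code{molecular_structure}: list with \code{atoms} (data.frame
#'   with columns element, x, y, z, source_index), \code{id}, \code{path}.
#' @export
read_protein <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at$source_index <- seq_len(nrow(at))
  elem <- pdb_element(at)
  keep <- !(elem %in% c("H", "D")) &
    !(toupper(at$resid) %in% c("HOH", "WAT", "DOD", "H2O"))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- keep & (alt == "" | alt == "A")
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) > 0) {
    # collapse duplicated altloc records (e.g. both '' and 'A' present)
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    first <- !duplicated(key)
    at <- at[first, , drop = FALSE]
    elem <- elem[first]
  }
  if (nrow(at) == 0) stop("no heavy atoms in PDB file: ", path)
  new_structure(
    data.frame(element = elem, x = at$x, y = at$y, z = at$z,
               source_index = at$source_index, stringsAsFactors = FALSE),
    id = if (is.null(id)) strip_ext(path) else id, path = path)
}

#' Read a ligand structure from a mol2 or SDF file
#'
#' Dispatches on the file extension: \code{.mol2} via \code{bio3d::read.mol2},
#' \code{.sdf}/\code{.sd}/\code{.mol} via \code{ChemmineR::read.SDFset}.
#' Hydrogens are dropped; the remaining heavy atoms keep source-file order.
#'
#' @inheritParams read_protein
#' @return A \code{molecular_structure} (see \code{\link{read_protein}}).
#' @export
read_ligand <- function(path, id = NULL) {
  if (!file.exists(path)) stop("ligand file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") {
    # bio3d's reader rejects a BOND section keyword with zero bond records
    # (legal mol2, and required by Open Babel); fall back to the package's
    # minimal TRIPOS parser for such files
    m <- tryCatch(suppressWarnings(bio3d::read.mol2(path)),
                  error = function(e) NULL)
    if (!is.null(m)) {
      at <- m$atom
      df <- data.frame(element = sub("\\..*$", "", at$elety),
                       x = at$x, y = at$y, z = at$z,
                       source_index = seq_len(nrow(at)),
                       stringsAsFactors = FALSE)
    } else {
      at <- tryCatch(
        parse_mol2_stream(readLines(path, warn = FALSE))[[1]],
        error = function(e) stop("failed to parse mol2 file '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
      df <- data.frame(element = at$element, x = at$x, y = at$y, z = at$z,
                       source_index = seq_len(nrow(at)),
                       stringsAsFactors = FALSE)
    }
  } else if (ext %in% c("sdf", "sd", "mol")) {
    sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("failed to parse SDF file '", path,
                                              "': ", conditionMessage(e), call. = FALSE))
    ab <- ChemmineR::atomblock(sdfs[[1]])
    df <- data.frame(element = sub("_.*$", "", rownames(ab)),
                     x = ab[, 1], y = ab[, 2], z = ab[, 3],
                     source_index = seq_len(nrow(ab)), stringsAsFactors = FALSE)
  } else {
    stop("unsupported ligand format '.", ext, "' (expected mol2 or SDF): ", path)
  }
  df$element <- normalize_element(df$element)
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(df) == 0) stop("no heavy atoms in ligand file: ", path)
  rownames(df) <- NULL
  new_structure(df, id = if (is.null(id)) strip_ext(path) else id, path = path)
}

#' Extract the binding pocket from a protein-ligand pair
#'
#' Retains every ligand heavy atom plus each protein atom whose minimum
#' Euclidean distance to any ligand atom is at most \code{cutoff} (inclusive,
#' default 4.0 Angstrom). Distances are computed on raw file coordinates.
#'
#' @param protein,ligand \code{molecular_structure} objects, or an existing
#'   \code{pocket_complex} in place of both (re-selection, used for
#'   idempotence).
#' @param cutoff Pocket cutoff in Angstrom.
#' @param id Complex identifier; defaults to the ligand id.
#' @return A \code{pocket_complex}: list with \code{ligand_atoms},
#'   \code{protein_atoms} (data.frames with element, x, y, z, source_index),
#'   \code{cutoff}, \code{id}. A warning is issued when no protein atom falls
#'   within the cutoff; the pocket is returned with an empty protein set.
#' @export
select_pocket <- function(protein, ligand = NULL, cutoff = 4.0, id = NULL) {
  if (inherits(protein, "pocket_complex") && is.null(ligand)) {
    prot_atoms <- protein$protein_atoms
    lig_atoms <- protein$ligand_atoms
    if (is.null(id)) id <- protein$id
  } else {
    stopifnot(inherits(protein, "molecular_structure"),
              inherits(ligand, "molecular_structure"))
    prot_atoms <- protein$atoms
    lig_atoms <- ligand$atoms
    if (is.null(id)) id <- ligand$id
  }
  if (nrow(lig_atoms) == 0) stop("ligand has no atoms")
  if (nrow(prot_atoms) > 0) {
    dmin <- min_dist_to_set(prot_atoms, lig_atoms)
    prot_atoms <- prot_atoms[dmin <= cutoff, , drop = FALSE]
    rownames(prot_atoms) <- NULL
  }
  if (nrow(prot_atoms) == 0)
    warning("no protein atom within ", cutoff, " Angstrom of the ligand (", id, ")")
  structure(list(ligand_atoms = lig_atoms, protein_atoms = prot_atoms,
                 cutoff = cutoff, id = id),
            class = "pocket_complex")
}

#' @export
print.pocket_complex <- function(x, ...) {
  cat("Binding pocket '", x$id, "': ", nrow(x$ligand_atoms), " ligand + ",
      nrow(x$protein_atoms), " protein heavy atoms (cutoff ",
      format(x$cutoff), " A)\n", sep = "")
  invisible(x)
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat("Molecular structure '", x$id, "': ", nrow(x$atoms),
      " heavy atoms [", paste(utils::head(unique(x$atoms$element), 8),
                              collapse = " "), "]\n", sep = "")
  invisible(x)
}

# ---- internal helpers ------------------------------------------------------

new_structure <- function(atoms, id, path = NA_character_) {
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(nzchar(atoms$element)))
  structure(list(atoms = atoms, id = id, path = path),
            class = "molecular_structure")
}

# element symbol from a bio3d PDB atom table: prefer the element column,
# fall back to the atom-name heuristic
pdb_element <- function(at) {
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- trimws(elem)
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    guess <- sub("[0-9'].*$", "", trimws(at$elety[miss]))
    elem[miss] <- substr(guess, 1, 2)
  }
  normalize_element(elem)
}

normalize_element <- function(e) {
  e <- trimws(e)
  one <- nchar(e) == 1
  e[one] <- toupper(e[one])
  e[!one] <- paste0(toupper(substr(e[!one], 1, 1)),
                    tolower(substr(e[!one], 2, nchar(e[!one]))))
  e
}

strip_ext <- function(path) sub("\\.[^.]*$", "", basename(path))

atom_coords <- function(df) cbind(df$x, df$y, df$z)

# minimum distance from each row of `from` to the atom set `to`
min_dist_to_set <- function(from, to) {
  a <- atom_coords(from)
  b <- atom_coords(to)
  cross <- a %*% t(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

# all pocket atoms in canonical node order (ligand first, then protein),
# with a molecule tag column
pocket_atoms <- function(pocket) {
  lig <- pocket$ligand_atoms
  prot <- pocket$protein_atoms
  lig$molecule <- if (nrow(lig)) "ligand" else character(0)
  prot$molecule <- if (nrow(prot)) "protein" else character(0)
  rbind(lig, prot)
}
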