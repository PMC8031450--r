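#' Per-atom descriptors from the Open Babel backend
#'
#' Runs the \code{obabel} command-line tool on one or more structure files
#' (PDB, mol2 or SDF, auto-detected by extension), requesting Gasteiger
#' partial charges and a mol2 conversion, and parses the result into one
#' data frame of per-atom typed descriptors per input file. Bond perception,
#' atom typing and charge assignment are entirely Open Babel's; this function
#' only reads them back.
#'
#' Each returned data frame has one row per atom (hydrogens included, in
#' Open Babel's atom order, which matches the source-file order) with columns
#' \code{element}, \code{x}, \code{y}, \code{z}, \code{hybridization}
#' (0--3; SYBYL .1/.2/.3 suffixes, aromatic and amide types map to 2, types
#' without a hybridization state map to 0), \code{heavy_valence} (bonded
#' non-hydrogen atoms), \code{hetero_valence} (bonded atoms that are neither
#' carbon nor hydrogen) and \code{partial_charge} (Gasteiger; non-finite
#' values are replaced by 0 with a warning).
#'
#' @param paths Character vector of structure file paths, one molecule each.
#' @return A named list of data frames, one per input path.
#' @export
annotate_structures <- function(paths) {
  stopifnot(length(paths) >= 1, all(file.exists(paths)))
  if (Sys.which("obabel") == "")
    stop("the Open Babel 'obabel' executable is required but not on the PATH")
  out <- tempfile(fileext = ".mol2")
  err <- tempfile(fileext = ".txt")
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- system2("obabel", c(shQuote(path.expand(paths)), "-omol2",
                                "--partialcharge", "gasteiger",
                                "-O", shQuote(out)),
                    stdout = err, stderr = err)
  if (status != 0 || !file.exists(out))
    stop("obabel failed (exit ", status, "): ",
         paste(readLines(err, warn = FALSE), collapse = " "))
  mols <- parse_mol2_stream(readLines(out, warn = FALSE))
  if (length(mols) != length(paths))
    stop("obabel returned ", length(mols), " molecules for ", length(paths),
         " input files; inputs must hold one molecule each")
  names(mols) <- paths
  mols
}

# parse the multi-molecule mol2 text obabel emits; minimal by design --
# user-facing mol2 reading goes through bio3d, this reader only consumes
# obabel's own well-formed output stream
parse_mol2_stream <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no molecules in obabel output")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    chunk <- lines[starts[i]:ends[i]]
    parse_mol2_molecule(chunk)
  })
}

parse_mol2_molecule <- function(chunk) {
  sect <- function(tag) {
    hit <- grep(paste0("^@<TRIPOS>", tag), chunk)
    if (length(hit) == 0) return(character(0))
    from <- hit[1] + 1L
    nxt <- grep("^@<TRIPOS>", chunk)
    nxt <- nxt[nxt > hit[1]]
    to <- if (length(nxt)) nxt[1] - 1L else length(chunk)
    if (from > to) return(character(0))
    ln <- trimws(chunk[from:to])
    ln[nzchar(ln)]
  }
  at <- sect("ATOM")
  if (length(at) == 0) stop("mol2 molecule without atoms in obabel output")
  f <- strsplit(at, "[[:space:]]+")
  typ <- vapply(f, `[`, "", 6)
  chg <- suppressWarnings(vapply(f, function(v)
    as.numeric(v[length(v)]), 0))
  bad <- !is.finite(chg)
  if (any(bad)) {
    warning(sum(bad), " non-finite partial charge(s) replaced by 0")
    chg[bad] <- 0
  }
  n <- length(f)
  elem <- normalize_element(sub("\\..*$", "", typ))
  heavy <- integer(n)
  hetero <- integer(n)
  for (b in sect("BOND")) {
    v <- strsplit(b, "[[:space:]]+")[[1]]
    i <- as.integer(v[2]); j <- as.integer(v[3])
    if (is.na(i) || is.na(j)) next
    if (!elem[j] %in% c("H", "D")) heavy[i] <- heavy[i] + 1L
    if (!elem[i] %in% c("H", "D")) heavy[j] <- heavy[j] + 1L
    if (!elem[j] %in% c("H", "D", "C")) hetero[i] <- hetero[i] + 1L
    if (!elem[i] %in% c("H", "D", "C")) hetero[j] <- hetero[j] + 1L
  }
  data.frame(
    element = elem,
    x = vapply(f, function(v) as.numeric(v[3]), 0),
    y = vapply(f, function(v) as.numeric(v[4]), 0),
    z = vapply(f, function(v) as.numeric(v[5]), 0),
    hybridization = sybyl_hybridization(typ),
    heavy_valence = heavy,
    hetero_valence = hetero,
    partial_charge = chg,
    stringsAsFactors = FALSE)
}

# SYBYL atom-type suffix -> hybridization state in {0,1,2,3}; values the
# backend reports outside {1,2,3} (ions, halogens, bare types) clamp to 0
sybyl_hybridization <- function(type) {
  suf <- ifelse(grepl("\\.", type), sub("^[^.]*\\.", "", type), "")
  h <- integer(length(suf))
  h[suf == "1"] <- 1L
  h[suf %in% c("2", "ar", "am", "co2", "pl3", "cat")] <- 2L
  h[suf %in% c("3", "4", "t3", "o", "o2", "th")] <- 3L
  h
}

# match annotation rows to a structure's heavy atoms by rounded coordinates;
# returns the annotation data.frame reordered to the structure's atom order,
# with zeroed descriptor rows (and a warning) where no match is found
align_annotation <- function(structure, ann) {
  key <- function(x, y, z) sprintf("%.2f|%.2f|%.2f", x, y, z)
  ann_heavy <- ann[!(ann$element %in% c("H", "D")), , drop = FALSE]
  idx <- match(key(structure$atoms$x, structure$atoms$y, structure$atoms$z),
               key(ann_heavy$x, ann_heavy$y, ann_heavy$z))
  out <- ann_heavy[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " atom(s) of '", structure$id,
            "' not matched in the backend annotation; descriptors zeroed")
    out[is.na(idx), c("hybridization", "heavy_valence", "hetero_valence",
                      "partial_charge")] <- 0
    out$element[is.na(idx)] <- structure$atoms$element[is.na(idx)]
  }
  out$x <- structure$atoms$x
  out$y <- structure$atoms$y
  out$z <- structure$atoms$z
  rownames(out) <- NULL
  out
}
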