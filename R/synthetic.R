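#' Parameters of the synthetic pocket generator
#'
#' The generator emulates a binding pocket at desk scale: ligand heavy atoms
#' drawn uniformly in a 4 Angstrom ball at the origin, protein heavy atoms
#' rejection-sampled into a shell 2--8 Angstrom from the nearest ligand
#' atom, a minimum inter-atomic spacing of 1.2 Angstrom, and elements drawn
#' from {C, N, O, S} with fixed weights. The affinity label is planted: a
#' linear function of the inter-molecular contact counts in the four 1
#' Angstrom distance bins up to 4 Angstrom, plus Gaussian noise. Because the
#' protein shell starts at 2 Angstrom, the two sub-2-Angstrom contact bins
#' are structurally empty; the label signal lives in the (2,3] and (3,4]
#' bins. The default weights and intercept put labels in roughly the 2--12
#' pKd range observed in affinity databases.
#'
#' @param n_ligand_atoms Integer range (min, max) of ligand heavy atoms.
#' @param n_protein_atoms Integer range of protein shell atoms.
#' @param shell_range Protein shell (min, max) distance in Angstrom from the
#'   nearest ligand atom.
#' @param min_spacing Minimum distance between any two atoms, Angstrom.
#' @param ligand_radius Radius of the ligand ball, Angstrom.
#' @param element_pool Named sampling weights over element symbols.
#' @param planted_weights Length-4 weights over the 1 Angstrom
#'   inter-molecular contact bins (0,1], (1,2], (2,3], (3,4].
#' @param intercept Baseline affinity.
#' @param noise_sigma Standard deviation of the label noise.
#' @param seed Master seed; each complex uses a substream keyed by
#'   (seed, index) so a dataset can be extended without relabeling.
#' @return A \code{synth_params} list.
#' @export
synth_params <- function(n_ligand_atoms = c(8L, 15L),
                         n_protein_atoms = c(30L, 120L),
                         shell_range = c(2.0, 8.0),
                         min_spacing = 1.2,
                         ligand_radius = 4.0,
                         element_pool = c(C = 0.60, N = 0.18, O = 0.16,
                                          S = 0.06),
                         planted_weights = c(0.8, 0.5, 0.2, 0.1),
                         intercept = 2.0,
                         noise_sigma = 0.3,
                         seed = 1L) {
  stopifnot(length(planted_weights) == 4, length(shell_range) == 2,
            shell_range[1] >= min_spacing, shell_range[1] < shell_range[2],
            min_spacing > 0, noise_sigma >= 0,
            max(n_ligand_atoms) + max(n_protein_atoms) <= 200)
  structure(list(n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_protein_atoms = as.integer(n_protein_atoms),
                 shell_range = shell_range, min_spacing = min_spacing,
                 ligand_radius = ligand_radius,
                 element_pool = element_pool,
                 planted_weights = planted_weights,
                 intercept = intercept, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# deterministic 32-bit substream seed from (seed, index, stream)
substream_seed <- function(seed, index, stream = 0L) {
  ((as.numeric(seed) %% 2147483647) * 69069 + as.numeric(index) * 1234567 +
     as.numeric(stream) * 987654321) %% 2147483647
}

#' Planted affinity of a synthetic complex
#'
#' Counts inter-molecular (ligand-protein) atom pairs in the distance bins
#' (0,1], (1,2], (2,3], (3,4] Angstrom and returns
#' label = weights . counts + intercept + Normal(0, noise_sigma^2),
#' the noise drawn from the complex's own (seed, index) substream so labels
#' are reproducible atom-for-atom.
#'
#' @param ligand_xyz,protein_xyz Numeric matrices of 3D coordinates.
#' @param params A \code{\link{synth_params}}.
#' @param index Complex index keying the noise substream.
#' @return List with \code{label} and \code{contact_counts} (length-4
#'   integer vector).
#' @export
planted_label <- function(ligand_xyz, protein_xyz, params, index = 1L) {
  stopifnot(inherits(params, "synth_params"))
  counts <- integer(4)
  if (nrow(protein_xyz) > 0 && nrow(ligand_xyz) > 0) {
    d2 <- outer(rowSums(ligand_xyz^2), rowSums(protein_xyz^2), "+") -
      2 * ligand_xyz %*% t(protein_xyz)
    d <- sqrt(pmax(d2, 0))
    for (k in 1:4) counts[k] <- sum(d > k - 1 & d <= k)
  }
  noise <- 0
  if (params$noise_sigma > 0) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(substream_seed(params$seed, index, stream = 1L))
    noise <- stats::rnorm(1, 0, params$noise_sigma)
  }
  list(label = sum(params$planted_weights * counts) + params$intercept + noise,
       contact_counts = counts)
}

sample_in_ball <- function(radius) {
  repeat {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

#' Generate one synthetic protein-ligand complex
#'
#' Deterministic from (\code{params$seed}, \code{index}). Atom counts are
#' drawn uniformly from the configured ranges, geometry is rejection-sampled
#' under the spacing and shell constraints, coordinates are rounded to 3
#' decimals (PDB precision) so written fixtures round-trip exactly, and the
#' label comes from \code{\link{planted_label}}.
#'
#' @param params A \code{\link{synth_params}}.
#' @param index Positive integer complex index.
#' @param max_attempts Rejection-sampling budget per atom.
#' @return A \code{synthetic_complex}: list with \code{ligand},
#'   \code{protein} (data.frames: element, x, y, z), \code{label},
#'   \code{contact_counts}, \code{id}, \code{index}.
#' @export
generate_complex <- function(params, index = 1L, max_attempts = 20000L) {
  stopifnot(inherits(params, "synth_params"), index >= 1)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(substream_seed(params$seed, index))
  nl <- sample(params$n_ligand_atoms[1]:params$n_ligand_atoms[2], 1)
  np <- sample(params$n_protein_atoms[1]:params$n_protein_atoms[2], 1)
  spacing <- params$min_spacing + 2e-3  # margin so rounding cannot violate
  lig <- matrix(NA_real_, nl, 3)
  i <- 1L
  attempts <- 0L
  while (i <= nl) {
    if ((attempts <- attempts + 1L) > max_attempts)
      stop("ligand sampling failed after ", max_attempts,
           " attempts; loosen min_spacing or ligand_radius")
    p <- sample_in_ball(params$ligand_radius)
    if (i == 1L || min_dist(p, lig[seq_len(i - 1L), , drop = FALSE]) >=
        spacing) {
      lig[i, ] <- p
      i <- i + 1L
    }
  }
  shell <- params$shell_range
  rmax <- params$ligand_radius + shell[2]
  prot <- matrix(NA_real_, np, 3)
  i <- 1L
  attempts <- 0L
  while (i <= np) {
    if ((attempts <- attempts + 1L) > max_attempts * 10L)
      stop("protein shell sampling failed; loosen shell_range or spacing")
    p <- sample_in_ball(rmax)
    dl <- min_dist(p, lig)
    if (dl < shell[1] || dl > shell[2]) next
    if (i > 1L && min_dist(p, prot[seq_len(i - 1L), , drop = FALSE]) <
        spacing) next
    prot[i, ] <- p
    i <- i + 1L
  }
  lig <- round(lig, 3)
  prot <- round(prot, 3)
  elems <- sample(names(params$element_pool), nl + np, replace = TRUE,
                  prob = params$element_pool)
  lab <- planted_label(lig, prot, params, index = index)
  structure(list(
    ligand = data.frame(element = elems[seq_len(nl)], x = lig[, 1],
                        y = lig[, 2], z = lig[, 3], stringsAsFactors = FALSE),
    protein = data.frame(element = elems[nl + seq_len(np)], x = prot[, 1],
                         y = prot[, 2], z = prot[, 3],
                         stringsAsFactors = FALSE),
    label = lab$label, contact_counts = lab$contact_counts,
    id = sprintf("syn%05d", index), index = as.integer(index)),
    class = "synthetic_complex")
}

min_dist <- function(p, pts) {
  sqrt(min(colSums((t(pts) - p)^2)))
}

#' @export
print.synthetic_complex <- function(x, ...) {
  cat("Synthetic complex '", x$id, "': ", nrow(x$ligand), " ligand + ",
      nrow(x$protein), " shell atoms, label ", format(x$label, digits = 4),
      ", contacts (", paste(x$contact_counts, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Turn a synthetic complex into a pocket without file round-trip
#'
#' Applies the same pocket cutoff as the file pipeline, directly on the
#' in-memory geometry. Used for fast structure-only property checks.
#'
#' @param cx A \code{synthetic_complex}.
#' @param cutoff Pocket cutoff in Angstrom.
#' @return A \code{pocket_complex}.
#' @export
as_pocket <- function(cx, cutoff = 4.0) {
  stopifnot(inherits(cx, "synthetic_complex"))
  lig <- cx$ligand
  prot <- cx$protein
  lig$source_index <- seq_len(nrow(lig))
  prot$source_index <- seq_len(nrow(prot))
  select_pocket(new_structure(prot, id = cx$id),
                new_structure(lig, id = cx$id),
                cutoff = cutoff, id = cx$id)
}

#' Write a synthetic dataset to disk
#'
#' Generates \code{n} complexes and writes, per complex, a minimal
#' standards-conformant protein PDB and ligand mol2 file plus one
#' PDBbind-style index file with the planted labels. Regenerating with the
#' same seed is byte-identical.
#'
#' @param n Number of complexes.
#' @param params A \code{\link{synth_params}}.
#' @param dir Output directory (created if needed).
#' @param first_index Index of the first complex (allows extending a
#'   dataset without relabeling earlier complexes).
#' @return Data frame manifest: \code{id}, \code{label},
#'   \code{protein_path}, \code{ligand_path}, \code{index}; the index file
#'   path is attached as attribute \code{"index_path"}.
#' @export
generate_dataset <- function(n, params = synth_params(), dir = tempfile(),
                             first_index = 1L) {
  stopifnot(n >= 1)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  idx <- seq.int(first_index, length.out = n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    cx <- generate_complex(params, index = idx[k])
    pp <- file.path(dir, paste0(cx$id, "_protein.pdb"))
    lp <- file.path(dir, paste0(cx$id, "_ligand.mol2"))
    write_minimal_pdb(cx$protein, pp, id = cx$id)
    write_minimal_mol2(cx$ligand, lp, id = cx$id)
    rows[[k]] <- data.frame(id = cx$id, label = cx$label,
                            protein_path = pp, ligand_path = lp,
                            index = cx$index, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  index_path <- file.path(dir, "index.txt")
  writeLines(c("# synthetic affinity index",
               "# code  resolution  release_year  -logKd/Ki",
               sprintf("%s  2.00  2026  %.4f", manifest$id, manifest$label)),
             index_path)
  attr(manifest, "index_path") <- index_path
  manifest
}

write_minimal_pdb <- function(atoms, path, id = "SYN") {
  lines <- c(sprintf("HEADER    SYNTHETIC POCKET SHELL        %s", id),
             sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(atoms)),
                     substr(paste0(atoms$element, seq_len(nrow(atoms))), 1, 4),
                     "UNK", "A", seq_len(nrow(atoms)),
                     atoms$x, atoms$y, atoms$z, 1.0, 0.0,
                     toupper(atoms$element)),
             "END")
  writeLines(lines, path)
  invisible(path)
}

write_minimal_mol2 <- function(atoms, path, id = "LIG") {
  n <- nrow(atoms)
  lines <- c("@<TRIPOS>MOLECULE", id,
             sprintf("%d 0 1 0 0", n),
             "SMALL", "NO_CHARGES", "",
             "@<TRIPOS>ATOM",
             sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %5d %-4s %9.4f",
                     seq_len(n),
                     substr(paste0(atoms$element, seq_len(n)), 1, 4),
                     atoms$x, atoms$y, atoms$z,
                     paste0(atoms$element, ".3"), 1L, "LIG", 0),
             "@<TRIPOS>BOND")
  writeLines(lines, path)
  invisible(path)
}
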