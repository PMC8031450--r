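# Fixture builders shared across the test files. Everything is generated in
# code at test time; nothing binary is stored in the repository.

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 5 heavy atoms + 3 hydrogens + 1 water + an altloc A/B pair (counted once)
fixture_pdb_mixed <- function() {
  write_fixture(c(
    "HEADER    TEST STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   1       1.470   0.100   0.000  0.50  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  CB  ALA A   1       2.000  -0.800  -1.200  1.00  0.00           C",
    "ATOM      7  H   ALA A   1      -0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      8  HA  ALA A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "ATOM      9  HB1 ALA A   1       2.500  -1.600  -0.900  1.00  0.00           H",
    "HETATM   10  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), ".pdb")
}

# propane with explicit hydrogens: 3 C + 8 H
fixture_mol2_propane <- function() {
  write_fixture(c(
    "@<TRIPOS>MOLECULE", "propane", "11 10 1", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    " 1 C1  0.000  0.000  0.000 C.3 1 LIG 0.0",
    " 2 C2  1.540  0.000  0.000 C.3 1 LIG 0.0",
    " 3 C3  2.053  1.452  0.000 C.3 1 LIG 0.0",
    " 4 H1 -0.400  0.900  0.000 H   1 LIG 0.0",
    " 5 H2 -0.400 -0.500  0.800 H   1 LIG 0.0",
    " 6 H3 -0.400 -0.500 -0.800 H   1 LIG 0.0",
    " 7 H4  1.900 -0.500  0.900 H   1 LIG 0.0",
    " 8 H5  1.900 -0.500 -0.900 H   1 LIG 0.0",
    " 9 H6  1.700  2.000  0.900 H   1 LIG 0.0",
    "10 H7  1.700  2.000 -0.900 H   1 LIG 0.0",
    "11 H8  3.150  1.450  0.000 H   1 LIG 0.0",
    "@<TRIPOS>BOND",
    " 1  1  2 1", " 2  2  3 1", " 3  1  4 1", " 4  1  5 1", " 5  1  6 1",
    " 6  2  7 1", " 7  2  8 1", " 8  3  9 1", " 9  3 10 1", "10  2 11 1"),
    ".mol2")
}

# chlorobenzene heavy atoms only: 6 aromatic C + Cl
fixture_sdf_chlorobenzene <- function() {
  ring <- sapply(0:5, function(k) {
    a <- pi * k / 3
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            1.39 * cos(a), 1.39 * sin(a), 0, "C")
  })
  cl <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                3.13, 0, 0, "Cl")
  bonds <- c("  1  2  4  0", "  2  3  4  0", "  3  4  4  0", "  4  5  4  0",
             "  5  6  4  0", "  6  1  4  0", "  1  7  1  0")
  write_fixture(c(
    "chlorobenzene", "  pocketgcn tests", "",
    "  7  7  0  0  0  0  0  0  0  0999 V2000",
    ring, cl, bonds, "M  END", "$$$$"), ".sdf")
}

# a bare pocket_complex from coordinate matrices (no files, no backend);
# used by adjacency/graph property tests
make_pocket <- function(lig_xyz, prot_xyz, lig_elem = NULL, prot_elem = NULL,
                        cutoff = 4, id = "test") {
  as_df <- function(xyz, elem) {
    data.frame(element = if (is.null(elem)) rep("C", nrow(xyz)) else elem,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               source_index = seq_len(nrow(xyz)), stringsAsFactors = FALSE)
  }
  structure(list(ligand_atoms = as_df(lig_xyz, lig_elem),
                 protein_atoms = as_df(prot_xyz, prot_elem),
                 cutoff = cutoff, id = id),
            class = "pocket_complex")
}

# random pocket with distances spanning the interesting 0-6 A range
random_pocket <- function(seed, n_lig = NULL, n_prot = NULL) {
  set.seed(seed)
  if (is.null(n_lig)) n_lig <- sample(3:8, 1)
  if (is.null(n_prot)) n_prot <- sample(5:20, 1)
  lig <- matrix(runif(3 * n_lig, -2, 2), ncol = 3)
  prot <- matrix(runif(3 * n_prot, -4, 4), ncol = 3)
  elems <- c("C", "N", "O", "S")
  make_pocket(lig, prot,
              lig_elem = sample(elems, n_lig, replace = TRUE),
              prot_elem = sample(elems, n_prot, replace = TRUE),
              id = paste0("rnd", seed))
}

# brute-force double-loop oracle for the binned adjacency construction
brute_force_bins <- function(pocket, n_bins, inter_max = 4, intra_max = 2) {
  atoms <- rbind(cbind(pocket$ligand_atoms, molecule = "ligand"),
                 cbind(pocket$protein_atoms, molecule = "protein"))
  n <- nrow(atoms)
  out <- replicate(n_bins, matrix(0, n, n), simplify = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    inter <- atoms$molecule[i] != atoms$molecule[j]
    if (inter && d > inter_max) next
    if (!inter && d > intra_max) next
    for (k in seq_len(n_bins)) {
      if (d > inter_max * (k - 1) / n_bins && d <= inter_max * k / n_bins)
        out[[k]][i, j] <- 1
    }
  }
  out
}

# small labelled graph set built in memory (no obabel), cached per session
synthetic_graphs <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 60, seed = 11, n_bins = 2) {
    key <- paste(n, seed, n_bins, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    params <- synth_params(seed = seed)
    gs <- lapply(seq_len(n), function(i) {
      cx <- generate_complex(params, i)
      featurize_pocket(as_pocket(cx), n_bins = n_bins, label = cx$label,
                       id = cx$id)
    })
    cache[[key]] <- gs
    gs
  }
})
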