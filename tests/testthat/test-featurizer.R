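test_that("atom descriptors have length 13 and a single-class one-hot", {
  f <- atom_features("C", hybridization = 3, heavy_valence = 2)
  expect_length(f, 13)
  expect_equal(unname(f[["C"]]), 1)
  expect_equal(sum(f[1:9]), 1)

  cl <- atom_features("Cl")
  expect_equal(unname(cl[["Halogen"]]), 1)
  expect_equal(sum(cl[1:9]), 1)

  zn <- atom_features("Zn")
  expect_equal(unname(zn[["Metal"]]), 1)

  # unclassified element: all-zero one-hot is allowed
  xe <- atom_features("Xe")
  expect_equal(sum(xe[1:9]), 0)
})

test_that("hybridization outside 1..3 clamps to 0 and bad charges are zeroed", {
  expect_equal(unname(atom_features("C", hybridization = 5)[["hybridization"]]), 0)
  expect_equal(unname(atom_features("C", hybridization = -1)[["hybridization"]]), 0)
  expect_warning(f <- atom_features("C", partial_charge = NaN), "non-finite")
  expect_equal(unname(f[["partial_charge"]]), 0)
})

test_that("backend annotation reproduces known propane descriptors", {
  path <- fixture_mol2_propane()
  ann <- annotate_structures(path)[[1]]
  # central carbon: atom 2
  expect_equal(ann$element[2], "C")
  expect_equal(ann$hybridization[2], 3)
  expect_equal(ann$heavy_valence[2], 2)
  expect_equal(ann$hetero_valence[2], 0)
  # independent backend query: re-run obabel and read the charge column raw
  out <- tempfile(fileext = ".mol2")
  system2("obabel", c(path, "-omol2", "--partialcharge", "gasteiger",
                      "-O", out), stdout = FALSE, stderr = FALSE)
  raw <- readLines(out)
  atom_start <- grep("@<TRIPOS>ATOM", raw) + 1
  fields <- strsplit(trimws(raw[atom_start + 1]), "\\s+")[[1]]
  expect_equal(ann$partial_charge[2], as.numeric(fields[length(fields)]),
               tolerance = 1e-8)
  expect_false(ann$partial_charge[2] == 0)
})

test_that("backend annotation classifies chlorobenzene's halogen", {
  ann <- annotate_structures(fixture_sdf_chlorobenzene())[[1]]
  expect_equal(sum(ann$element == "Cl"), 1)
  f <- atom_features(ann$element[7], ann$hybridization[7],
                     ann$heavy_valence[7], ann$hetero_valence[7],
                     ann$partial_charge[7])
  expect_equal(unname(f[["Halogen"]]), 1)
  # aromatic ring carbons are sp2 with two heavy neighbours (three for C1)
  expect_true(all(ann$hybridization[1:6] == 2))
  expect_equal(sort(ann$heavy_valence[1:6]), c(2, 2, 2, 2, 2, 3))
})

test_that("feature matrix rows follow the canonical node ordering", {
  pocket <- random_pocket(101, n_lig = 4, n_prot = 6)
  fm <- build_feature_matrix(pocket)
  expect_equal(dim(fm), c(10, 13))
  atoms <- c(pocket$ligand_atoms$element, pocket$protein_atoms$element)
  for (i in seq_along(atoms))
    expect_equal(fm[i, ], atom_features(atoms[i]), ignore_attr = TRUE)
})

test_that("adjacency bins follow the interval and admissibility rules", {
  # ligand-protein pair at 3.5 A: bin 4 of 4 only
  p <- make_pocket(matrix(0, 1, 3), matrix(c(3.5, 0, 0), 1))
  b4 <- build_adjacency_bins(p, 4)
  expect_equal(sapply(b4$matrices, function(m) m[1, 2]), c(0, 0, 0, 1))

  # protein-protein pair at 2.5 A: intra-molecular limit 2 A excludes it
  p2 <- make_pocket(matrix(c(50, 50, 50), 1),
                    matrix(c(0, 0, 0, 2.5, 0, 0), 2, byrow = TRUE))
  b <- build_adjacency_bins(p2, 4)
  expect_true(all(sapply(b$matrices, function(m) m[2, 3] == 0)))

  # ligand-ligand pair at exactly 2.0 A: bin 1 of 2 (left-open, right-closed)
  p3 <- make_pocket(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE),
                    matrix(c(50, 50, 50), 1))
  b2 <- build_adjacency_bins(p3, 2)
  expect_equal(b2$matrices[[1]][1, 2], 1)
  expect_equal(b2$matrices[[2]][1, 2], 0)

  # any pair at 4.2 A: everywhere zero
  p4 <- make_pocket(matrix(0, 1, 3), matrix(c(4.2, 0, 0), 1))
  expect_true(all(sapply(build_adjacency_bins(p4, 8)$matrices, sum) == 0))

  expect_error(build_adjacency_bins(p4, 3), "n_bins")
})

test_that("bins partition admissible pairs and match the brute-force oracle", {
  for (seed in 1:25) {
    pocket <- random_pocket(seed)
    for (nb in c(1L, 2L, 4L)) {
      bins <- build_adjacency_bins(pocket, nb)
      oracle <- brute_force_bins(pocket, nb)
      for (k in seq_len(nb)) {
        expect_equal(bins$matrices[[k]], oracle[[k]])
        expect_true(isSymmetric(bins$matrices[[k]]))
        expect_true(all(diag(bins$matrices[[k]]) == 0))
      }
      # each pair sits in at most one bin
      expect_true(max(Reduce(`+`, bins$matrices)) <= 1)
    }
    # refinement: union over n=4 bins == union over n=2 bins == n=1 matrix
    u1 <- build_adjacency_bins(pocket, 1)$matrices[[1]]
    u2 <- Reduce(`+`, build_adjacency_bins(pocket, 2)$matrices)
    u4 <- Reduce(`+`, build_adjacency_bins(pocket, 4)$matrices)
    expect_equal(u2, u1)
    expect_equal(u4, u1)
  }
})

test_that("bins beyond 2 A contain only inter-molecular pairs", {
  for (seed in 26:35) {
    pocket <- random_pocket(seed)
    nl <- nrow(pocket$ligand_atoms)
    bins <- build_adjacency_bins(pocket, 8)
    for (k in 5:8) {
      m <- bins$matrices[[k]]
      expect_true(all(m[seq_len(nl), seq_len(nl)] == 0))
      expect_true(all(m[-seq_len(nl), -seq_len(nl)] == 0))
    }
  }
})

test_that("graph assembly pads with zeros and rejects oversized pockets", {
  pocket <- random_pocket(77, n_lig = 3, n_prot = 4)
  g <- featurize_pocket(pocket, n_bins = 2, label = 6.5)
  expect_s3_class(g, "pocket_graph")
  expect_equal(dim(g$features), c(200, 13))
  expect_equal(g$n_nodes, 7)
  expect_true(all(g$features[8:200, ] == 0))
  for (m in g$adjacency) {
    expect_equal(dim(m), c(200, 200))
    expect_true(all(m[8:200, ] == 0))
    expect_true(all(m[, 8:200] == 0))
  }

  # the cap: 200 accepted, 201 rejected
  feats <- matrix(0, 201, 13)
  bins201 <- structure(list(matrices = list(matrix(0, 201, 201)),
                            n_bins = 1L, n_atoms = 201L),
                       class = "adjacency_bins")
  rej <- assemble_graph(feats, bins201, id = "big")
  expect_s3_class(rej, "graph_rejection")
  expect_equal(rej$id, "big")

  feats200 <- matrix(0, 200, 13)
  bins200 <- structure(list(matrices = list(matrix(0, 200, 200)),
                            n_bins = 1L, n_atoms = 200L),
                       class = "adjacency_bins")
  ok <- assemble_graph(feats200, bins200)
  expect_s3_class(ok, "pocket_graph")
  expect_equal(ok$n_nodes, 200)

  expect_error(assemble_graph(matrix(0, 5, 13), bins200), "disagree")
})
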