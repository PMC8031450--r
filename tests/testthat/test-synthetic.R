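test_that("generated complexes respect the geometric constraints", {
  params <- synth_params(seed = 3)
  for (i in 1:5) {
    cx <- generate_complex(params, i)
    xyz <- rbind(as.matrix(cx$ligand[, c("x", "y", "z")]),
                 as.matrix(cx$protein[, c("x", "y", "z")]))
    d <- as.matrix(dist(xyz))
    diag(d) <- Inf
    expect_gte(min(d), params$min_spacing)
    # ligand inside its ball, protein inside the shell
    lig <- as.matrix(cx$ligand[, c("x", "y", "z")])
    expect_lte(max(sqrt(rowSums(lig^2))), params$ligand_radius + 1e-6)
    dl <- as.matrix(dist(xyz))[seq_len(nrow(lig)),
                               nrow(lig) + seq_len(nrow(cx$protein)),
                               drop = FALSE]
    nearest <- apply(dl, 2, min)
    expect_true(all(nearest >= params$shell_range[1] - 1e-9))
    expect_true(all(nearest <= params$shell_range[2] + 1e-9))
    expect_true(nrow(cx$ligand) >= params$n_ligand_atoms[1] &&
                  nrow(cx$ligand) <= params$n_ligand_atoms[2])
    expect_true(all(c(cx$ligand$element, cx$protein$element) %in%
                      names(params$element_pool)))
  }
})

test_that("generation is deterministic per (seed, index) substream", {
  params <- synth_params(seed = 9)
  a <- generate_complex(params, 4)
  b <- generate_complex(params, 4)
  expect_identical(a, b)
  c2 <- generate_complex(params, 5)
  expect_false(identical(a$ligand, c2$ligand))
  # substreams make datasets extensible: complex 4 is the same whether or
  # not complexes 1-3 were generated first
  invisible(lapply(1:3, function(i) generate_complex(params, i)))
  expect_identical(generate_complex(params, 4), a)
})

test_that("the planted label follows the contact-count formula", {
  params <- synth_params(seed = 2, noise_sigma = 0,
                         planted_weights = c(1.5, 1.0, 0.5, 0.25),
                         intercept = 4)
  # one inter pair at 3.5 A -> bin 4, label 4 + 0.25
  lab <- planted_label(matrix(0, 1, 3), matrix(c(3.5, 0, 0), 1), params)
  expect_equal(lab$contact_counts, c(0, 0, 0, 1))
  expect_equal(lab$label, 4.25)
  # no protein atoms in range -> intercept only
  lab0 <- planted_label(matrix(0, 1, 3), matrix(c(9, 0, 0), 1), params)
  expect_equal(lab0$contact_counts, rep(0, 4))
  expect_equal(lab0$label, 4)
  # with noise, the label deviates by the complex's own Gaussian draw
  pn <- synth_params(seed = 2, noise_sigma = 0.3,
                     planted_weights = c(1.5, 1.0, 0.5, 0.25), intercept = 4)
  labn <- planted_label(matrix(0, 1, 3), matrix(c(3.5, 0, 0), 1), pn,
                        index = 6)
  expect_false(labn$label == 4.25)
  expect_lt(abs(labn$label - 4.25), 4 * 0.3)
})

test_that("contact counts agree with the featurizer's 4-bin adjacency", {
  params <- synth_params(seed = 13)
  for (i in 1:8) {
    cx <- generate_complex(params, i)
    pocket <- as_pocket(cx)
    bins <- build_adjacency_bins(pocket, 4)
    nl <- nrow(pocket$ligand_atoms)
    inter <- sapply(bins$matrices, function(m)
      sum(m[seq_len(nl), -seq_len(nl), drop = FALSE]))
    expect_equal(unname(inter), cx$contact_counts)
  }
})

test_that("least squares on contact counts recovers the planted weights", {
  params <- synth_params(seed = 19)
  cxs <- lapply(1:500, function(i) generate_complex(params, i))
  counts <- t(sapply(cxs, function(cx) cx$contact_counts))
  labels <- sapply(cxs, function(cx) cx$label)
  # the protein shell starts at 2 A, so the first two bins are empty by
  # construction; the identifiable coefficients are bins 3 and 4
  expect_true(all(counts[, 1:2] == 0))
  fit <- lm(labels ~ counts[, 3] + counts[, 4])
  est <- coef(summary(fit))
  expect_lt(abs(est[1, 1] - params$intercept), 3 * est[1, 2])
  expect_lt(abs(est[2, 1] - params$planted_weights[3]), 3 * est[2, 2])
  expect_lt(abs(est[3, 1] - params$planted_weights[4]), 3 * est[3, 2])
})

test_that("labels span the intended affinity range", {
  params <- synth_params(seed = 29)
  labels <- sapply(1:300, function(i) generate_complex(params, i)$label)
  expect_gt(min(labels), 0)
  expect_lt(max(labels), 15)
  expect_gt(diff(range(labels)), 5)   # spans roughly the 2-12 pKd decade
})

test_that("dataset writing is deterministic and pipeline-compatible", {
  params <- synth_params(seed = 37)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_dataset(10, params, dir = d1)
  m2 <- generate_dataset(10, params, dir = d2)
  expect_equal(length(list.files(d1, pattern = "protein\\.pdb$")), 10)
  expect_equal(length(list.files(d1, pattern = "ligand\\.mol2$")), 10)
  expect_identical(readLines(attr(m1, "index_path")),
                   readLines(attr(m2, "index_path")))

  # full round trip: generate -> read -> featurize, nothing rejected
  fd <- featurize_dataset(m1, n_bins = 4)
  expect_length(fd$graphs, 10)
  expect_length(fd$rejects, 0)
  for (g in fd$graphs) {
    expect_lte(g$n_nodes, 200)
    expect_gte(g$n_nodes, 1)
    expect_equal(g$n_bins, 4L)
  }
  # labels carried through from the manifest
  expect_equal(sapply(fd$graphs, function(g) g$label), m1$label)
})
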