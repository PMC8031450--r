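ONE_HOT_CLASSES <- c("B", "C", "N", "O", "P", "S", "Se", "Halogen", "Metal")
HALOGENS <- c("F", "Cl", "Br", "I", "At")
METALS <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba",
            "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Cd", "Hg", "Mo", "Al")

FEATURE_NAMES <- c(ONE_HOT_CLASSES, "hybridization", "heavy_valence",
                   "hetero_valence", "partial_charge")

#' Build the 13-long descriptor of one atom
#'
#' The descriptor is a 9-class element one-hot (B, C, N, O, P, S, Se,
#' Halogen = F/Cl/Br/I/At, Metal = common biologically relevant metals)
#' followed by hybridization (0--3), heavy valence (attached non-hydrogen
#' atoms), hetero valence (attached atoms that are neither C nor H) and the
#' Gasteiger partial charge. Elements outside all nine classes get an
#' all-zero one-hot. Hybridization values outside {1,2,3} clamp to 0 and
#' non-finite charges become 0 with a warning.
#'
#' @param element Chemical element symbol.
#' @param hybridization,heavy_valence,hetero_valence,partial_charge Typed
#'   descriptor values, normally taken from \code{\link{annotate_structures}}.
#' @return Named numeric vector of length 13.
#' @export
atom_features <- function(element, hybridization = 0, heavy_valence = 0,
                          hetero_valence = 0, partial_charge = 0) {
  one_hot <- numeric(length(ONE_HOT_CLASSES))
  names(one_hot) <- ONE_HOT_CLASSES
  cls <- element_class(element)
  if (!is.na(cls)) one_hot[cls] <- 1
  hyb <- if (is.finite(hybridization) && hybridization %in% 1:3)
    hybridization else 0
  if (!is.finite(partial_charge)) {
    warning("non-finite partial charge for ", element, " replaced by 0")
    partial_charge <- 0
  }
  out <- c(one_hot, hybridization = hyb,
           heavy_valence = max(0, heavy_valence),
           hetero_valence = max(0, hetero_valence),
           partial_charge = partial_charge)
  out
}

element_class <- function(element) {
  if (element %in% c("B", "C", "N", "O", "P", "S", "Se")) return(element)
  if (element %in% HALOGENS) return("Halogen")
  if (element %in% METALS) return("Metal")
  NA_character_
}

#' Build the unpadded feature matrix of a pocket
#'
#' Row i holds \code{\link{atom_features}} of pocket atom i under the
#' canonical node ordering: ligand atoms first in source-file order, then
#' protein atoms in source-file order. Typed descriptors (hybridization,
#' valences, charge) are taken from backend annotations when supplied;
#' without annotations the structural one-hot is computed from the element
#' symbols alone and the typed fields are zero.
#'
#' @param pocket A \code{pocket_complex}.
#' @param annotations Optional list with components \code{ligand} and
#'   \code{protein}: per-atom descriptor tables from
#'   \code{\link{annotate_structures}} aligned to the full source structures.
#' @return Numeric N x 13 matrix, N the pocket atom count.
#' @export
build_feature_matrix <- function(pocket, annotations = NULL) {
  atoms <- pocket_atoms(pocket)
  if (nrow(atoms) == 0) stop("empty pocket")
  desc <- data.frame(hybridization = numeric(nrow(atoms)),
                     heavy_valence = numeric(nrow(atoms)),
                     hetero_valence = numeric(nrow(atoms)),
                     partial_charge = numeric(nrow(atoms)))
  if (!is.null(annotations)) {
    nl <- nrow(pocket$ligand_atoms)
    pick <- function(ann, rows) ann[rows, c("hybridization", "heavy_valence",
                                            "hetero_valence", "partial_charge")]
    if (!is.null(annotations$ligand) && nl > 0)
      desc[seq_len(nl), ] <- pick(annotations$ligand,
                                  pocket$ligand_atoms$source_index)
    if (!is.null(annotations$protein) && nrow(pocket$protein_atoms) > 0)
      desc[nl + seq_len(nrow(pocket$protein_atoms)), ] <-
        pick(annotations$protein, pocket$protein_atoms$source_index)
  }
  out <- t(vapply(seq_len(nrow(atoms)), function(i)
    atom_features(atoms$element[i], desc$hybridization[i],
                  desc$heavy_valence[i], desc$hetero_valence[i],
                  desc$partial_charge[i]),
    numeric(length(FEATURE_NAMES))))
  colnames(out) <- FEATURE_NAMES
  out
}

#' Build the distance-binned binary adjacency matrices of a pocket
#'
#' With n bins, bin k connects atom pairs whose Euclidean distance d
#' satisfies 4(k-1)/n < d <= 4k/n, restricted to admissible pairs:
#' inter-molecular (ligand-protein) pairs up to 4 Angstrom and
#' intra-molecular pairs up to 2 Angstrom. Bin boundaries are left-open,
#' right-closed; diagonals are zero; all matrices are symmetric. Bins
#' covering distances beyond 2 Angstrom therefore hold only inter-molecular
#' contacts.
#'
#' @param pocket A \code{pocket_complex}.
#' @param n_bins Number of bins, one of 1, 2, 4, 8.
#' @param inter_max,intra_max Admissibility limits in Angstrom.
#' @return An \code{adjacency_bins} object: list with \code{matrices} (list
#'   of n_bins symmetric 0/1 matrices in pocket node order), \code{n_bins},
#'   \code{n_atoms}.
#' @export
build_adjacency_bins <- function(pocket, n_bins, inter_max = 4, intra_max = 2) {
  if (!n_bins %in% c(1L, 2L, 4L, 8L))
    stop("n_bins must be one of 1, 2, 4, 8 (got ", n_bins, ")")
  atoms <- pocket_atoms(pocket)
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(atom_coords(atoms)))
  inter <- outer(atoms$molecule, atoms$molecule, "!=")
  admissible <- (inter & d <= inter_max) | (!inter & d <= intra_max)
  diag(admissible) <- FALSE
  edges <- vector("list", n_bins)
  for (k in seq_len(n_bins)) {
    lo <- inter_max * (k - 1) / n_bins
    hi <- inter_max * k / n_bins
    m <- (d > lo & d <= hi & admissible) * 1
    dimnames(m) <- NULL
    edges[[k]] <- m
  }
  structure(list(matrices = edges, n_bins = as.integer(n_bins),
                 n_atoms = as.integer(n)),
            class = "adjacency_bins")
}

#' Assemble a padded pocket graph
#'
#' Combines an unpadded feature matrix and adjacency bins into the padded
#' fixed-size tensors the network consumes: features zero-padded to
#' \code{max_nodes} x 13, every bin matrix zero-padded to
#' \code{max_nodes} x \code{max_nodes} (stored sparse). Pockets larger than
#' \code{max_nodes} are rejected, mirroring the >200-node filter of the
#' dataset pipeline. The symmetric degree-normalized adjacency of each bin
#' (see \code{\link{normalize_adjacency}}) is computed here once, on the
#' unpadded matrices, and cached in the graph for the model.
#'
#' @param features Unpadded N x 13 matrix from
#'   \code{\link{build_feature_matrix}}.
#' @param bins An \code{adjacency_bins} over the same N atoms.
#' @param label Affinity label in -log10(Kd/Ki) units (NA allowed).
#' @param id Complex identifier.
#' @param max_nodes Fixed graph size (default 200).
#' @return A \code{pocket_graph}, or a \code{graph_rejection} (list with
#'   \code{id}, \code{n_nodes}, \code{reason}) when N exceeds
#'   \code{max_nodes}.
#' @export
assemble_graph <- function(features, bins, label = NA_real_, id = "complex",
                           max_nodes = 200L) {
  stopifnot(inherits(bins, "adjacency_bins"))
  n <- nrow(features)
  if (n != bins$n_atoms)
    stop("feature matrix (", n, " atoms) and adjacency bins (", bins$n_atoms,
         " atoms) disagree")
  if (n > max_nodes)
    return(structure(list(id = id, n_nodes = n,
                          reason = sprintf("%d nodes exceed the %d-node cap",
                                           n, max_nodes)),
                     class = "graph_rejection"))
  feat <- matrix(0, max_nodes, ncol(features),
                 dimnames = list(NULL, colnames(features)))
  feat[seq_len(n), ] <- features
  adj <- lapply(bins$matrices, function(m) {
    ij <- which(m != 0, arr.ind = TRUE)
    Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                         dims = c(max_nodes, max_nodes))
  })
  a_hat <- lapply(bins$matrices, function(m)
    normalize_adjacency(Matrix::Matrix(m, sparse = TRUE)))
  structure(list(features = feat, adjacency = adj, a_hat = a_hat,
                 n_nodes = n, n_bins = bins$n_bins, max_nodes = max_nodes,
                 label = label, id = id),
            class = "pocket_graph")
}

#' @export
print.pocket_graph <- function(x, ...) {
  cat("Pocket graph '", x$id, "': ", x$n_nodes, "/", x$max_nodes,
      " nodes, ", x$n_bins, " distance bin(s), label ",
      format(x$label, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Featurize one pocket into a padded graph
#'
#' Convenience wrapper: feature matrix + adjacency bins + assembly.
#'
#' @inheritParams build_feature_matrix
#' @inheritParams build_adjacency_bins
#' @inheritParams assemble_graph
#' @return A \code{pocket_graph} or \code{graph_rejection}.
#' @export
featurize_pocket <- function(pocket, n_bins = 2L, annotations = NULL,
                             label = NA_real_, id = pocket$id,
                             max_nodes = 200L) {
  assemble_graph(build_feature_matrix(pocket, annotations),
                 build_adjacency_bins(pocket, n_bins),
                 label = label, id = id, max_nodes = max_nodes)
}

#' Featurize a dataset of protein-ligand complexes
#'
#' Reads each complex's protein (PDB) and ligand (mol2/SDF) file, extracts
#' the pocket at \code{cutoff}, annotates atoms through the Open Babel
#' backend (two batched invocations for the whole dataset) and assembles the
#' padded graphs. Complexes whose pockets exceed \code{max_nodes} are
#' reported in \code{rejects} rather than silently dropped.
#'
#' @param records Data frame with columns \code{id}, \code{label},
#'   \code{protein_path}, \code{ligand_path} (e.g. the manifest written by
#'   \code{\link{generate_dataset}}, or \code{\link{parse_index}} output
#'   joined with file locations).
#' @param n_bins Number of adjacency bins.
#' @param cutoff Pocket cutoff in Angstrom.
#' @param max_nodes Fixed graph size.
#' @param annotate Logical; set \code{FALSE} to skip the backend and use
#'   element-only features (structural one-hot, zero typed fields).
#' @return List with \code{graphs} (list of \code{pocket_graph}) and
#'   \code{rejects} (list of \code{graph_rejection}).
#' @export
featurize_dataset <- function(records, n_bins = 2L, cutoff = 4.0,
                              max_nodes = 200L, annotate = TRUE) {
  stopifnot(all(c("id", "label", "protein_path", "ligand_path") %in%
                  names(records)))
  prot_ann <- lig_ann <- NULL
  if (annotate) {
    prot_ann <- annotate_structures(records$protein_path)
    lig_ann <- annotate_structures(records$ligand_path)
  }
  graphs <- list()
  rejects <- list()
  for (i in seq_len(nrow(records))) {
    prot <- read_protein(records$protein_path[i], id = records$id[i])
    lig <- read_ligand(records$ligand_path[i], id = records$id[i])
    pocket <- select_pocket(prot, lig, cutoff = cutoff, id = records$id[i])
    ann <- NULL
    if (annotate)
      ann <- list(protein = align_annotation(prot, prot_ann[[i]]),
                  ligand = align_annotation(lig, lig_ann[[i]]))
    g <- featurize_pocket(pocket, n_bins = n_bins, annotations = ann,
                          label = records$label[i], id = records$id[i],
                          max_nodes = max_nodes)
    if (inherits(g, "graph_rejection")) rejects[[length(rejects) + 1L]] <- g
    else graphs[[length(graphs) + 1L]] <- g
  }
  list(graphs = graphs, rejects = rejects)
}
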