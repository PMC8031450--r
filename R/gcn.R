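#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes D^(-1/2) (A + I) D^(-1/2), where D is the diagonal degree matrix
#' of A + I. Adding the identity gives every node a self-loop, so isolated
#' (including padded) nodes get degree 1 and a diagonal entry of exactly 1.
#' The output is symmetric and its spectral radius is at most 1.
#'
#' @param A Square symmetric 0/1 matrix (base or \pkg{Matrix} sparse) with a
#'   zero diagonal.
#' @return The normalized matrix, same storage class family as the input.
#' @export
normalize_adjacency <- function(A) {
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!isSymmetric(as.matrix(A), tol = 0))
    stop("adjacency matrix must be symmetric")
  if (any(Matrix::diag(A) != 0))
    stop("adjacency matrix must have a zero diagonal")
  n <- nrow(A)
  s <- 1 / sqrt(Matrix::rowSums(A) + 1)
  if (inherits(A, "Matrix")) {
    At <- A + Matrix::Diagonal(n)
    D <- Matrix::Diagonal(n, s)
    methods::as(D %*% At %*% D, "CsparseMatrix")
  } else {
    At <- A + diag(n)
    t(t(At * s) * s)
  }
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' One graph-convolution layer
#'
#' Computes sigma(A_hat F W): neighbor aggregation through the normalized
#' adjacency, a linear map by the trainable weight matrix, then the
#' activation. No additive bias term.
#'
#' @param F_mat Node-feature matrix (N x F).
#' @param a_hat Normalized adjacency (N x N), from
#'   \code{\link{normalize_adjacency}}.
#' @param W Weight matrix (F x F').
#' @param activation Activation function (default ReLU).
#' @return N x F' node-feature matrix.
#' @export
graph_conv <- function(F_mat, a_hat, W, activation = relu) {
  if (ncol(F_mat) != nrow(W)) stop("feature/weight dimension mismatch: ",
                                   ncol(F_mat), " vs ", nrow(W))
  if (nrow(F_mat) != ncol(a_hat)) stop("feature/adjacency dimension mismatch")
  activation(as.matrix(a_hat %*% (F_mat %*% W)))
}

#' Graph gather readout
#'
#' Column-wise sum of the node features over the first \code{n_nodes} rows
#' only, so zero-padded rows never contribute.
#'
#' @param F_mat Node-feature matrix.
#' @param n_nodes Number of real (non-padded) nodes.
#' @return Numeric vector of length \code{ncol(F_mat)}.
#' @export
graph_gather <- function(F_mat, n_nodes) {
  if (n_nodes > nrow(F_mat))
    stop("n_nodes (", n_nodes, ") exceeds matrix rows (", nrow(F_mat), ")")
  colSums(F_mat[seq_len(n_nodes), , drop = FALSE])
}

#' Network architecture configuration
#'
#' Defaults follow the reference architecture: a node-wise input
#' fully-connected layer of width 128 with dropout, then one graph
#' convolution block per distance bin (graph-convolution widths 128/128/32,
#' node-wise fully-connected widths 128/128/16 x n_bins, dropout after the
#' first two), a sum gather per block, concatenation, a fully-connected
#' layer of width 128 with dropout and a linear scalar output. All hidden
#' activations are ReLU.
#'
#' @param n_bins Number of adjacency bins (1, 2, 4 or 8).
#' @param input_fc_width Width of the node-wise input layer.
#' @param gc_widths Widths of the three graph-convolution layers per block.
#' @param block_fc_widths Widths of the node-wise fully-connected layers in
#'   each block; the default third width is 16 x n_bins.
#' @param final_fc_width Width of the post-concatenation layer.
#' @param dropout_rate Dropout probability in [0, 1).
#' @param block_layout \code{"three_fc"} (default; every graph convolution is
#'   followed by a node-wise fully-connected layer, gather reads the third FC)
#'   or \code{"two_fc"} (no FC after the last graph convolution; gather reads
#'   its 32-wide output directly).
#' @param seed Integer seed for reproducible weight initialization.
#' @return A \code{network_config} list.
#' @export
network_config <- function(n_bins = 2L, input_fc_width = 128L,
                           gc_widths = c(128L, 128L, 32L),
                           block_fc_widths = c(128L, 128L, 16L * n_bins),
                           final_fc_width = 128L, dropout_rate = 0.5,
                           block_layout = c("three_fc", "two_fc"),
                           seed = 1L) {
  if (!n_bins %in% c(1L, 2L, 4L, 8L))
    stop("n_bins must be one of 1, 2, 4, 8 (got ", n_bins, ")")
  stopifnot(length(gc_widths) == 3, all(gc_widths > 0),
            length(block_fc_widths) == 3, all(block_fc_widths > 0),
            input_fc_width > 0, final_fc_width > 0,
            dropout_rate >= 0, dropout_rate < 1)
  block_layout <- match.arg(block_layout)
  structure(list(n_bins = as.integer(n_bins),
                 n_features = 13L,
                 input_fc_width = as.integer(input_fc_width),
                 gc_widths = as.integer(gc_widths),
                 block_fc_widths = as.integer(block_fc_widths),
                 final_fc_width = as.integer(final_fc_width),
                 dropout_rate = dropout_rate,
                 block_layout = block_layout,
                 seed = as.integer(seed)),
            class = "network_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Instantiate a network from a configuration
#'
#' Allocates all trainable weights (Glorot-uniform, reproducible from
#' \code{config$seed}; biases start at zero). Graph-convolution layers carry
#' no bias; node-wise and dense fully-connected layers do.
#'
#' @param config A \code{\link{network_config}}.
#' @return A \code{gcn_network}: list with \code{config} and \code{weights}.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(config$seed)
  gw <- config$gc_widths
  fw <- config$block_fc_widths
  blocks <- lapply(seq_len(config$n_bins), function(b) {
    blk <- list(
      wg1 = glorot(config$input_fc_width, gw[1]),
      wf1 = glorot(gw[1], fw[1]), bf1 = numeric(fw[1]),
      wg2 = glorot(fw[1], gw[2]),
      wf2 = glorot(gw[2], fw[2]), bf2 = numeric(fw[2]),
      wg3 = glorot(fw[2], gw[3]))
    if (config$block_layout == "three_fc") {
      blk$wf3 <- glorot(gw[3], fw[3])
      blk$bf3 <- numeric(fw[3])
    }
    blk
  })
  gathered <- if (config$block_layout == "three_fc") fw[3] else gw[3]
  weights <- list(
    w_in = glorot(config$n_features, config$input_fc_width),
    b_in = numeric(config$input_fc_width),
    blocks = blocks,
    w_fc = glorot(config$n_bins * gathered, config$final_fc_width),
    b_fc = numeric(config$final_fc_width),
    w_out = glorot(config$final_fc_width, 1L),
    b_out = 0)
  structure(list(config = config, weights = weights), class = "gcn_network")
}

#' @export
print.gcn_network <- function(x, ...) {
  cfg <- x$config
  gathered <- if (cfg$block_layout == "three_fc")
    cfg$block_fc_widths[3] else cfg$gc_widths[3]
  cat("Graph convolutional affinity network\n",
      "  distance bins: ", cfg$n_bins,
      " | block layout: ", cfg$block_layout, "\n",
      "  input FC ", cfg$n_features, "->", cfg$input_fc_width,
      " | GC widths (", paste(cfg$gc_widths, collapse = ", "),
      ") | block FC (", paste(cfg$block_fc_widths, collapse = ", "), ")\n",
      "  readout: ", cfg$n_bins, " x ", gathered, " -> FC ",
      cfg$final_fc_width, " -> 1 | dropout ", cfg$dropout_rate, "\n",
      "  trainable parameters: ", n_parameters(x), "\n", sep = "")
  invisible(x)
}

n_parameters <- function(net) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + length(x)
    invisible(NULL)
  }
  walk(net$weights)
  tot
}

# ---- batched forward pass --------------------------------------------------

# Stack the real (non-padded) nodes of a list of graphs into one batch.
# Dropping padded rows is numerically identical to carrying them and
# re-zeroing after every node-wise layer: padded rows have zero features,
# biases never reach the gather because only real rows are summed, and the
# normalized adjacency couples a padded node only to itself.
batch_inputs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n_nodes, 0L)
  X <- do.call(rbind, lapply(graphs, function(g)
    g$features[seq_len(g$n_nodes), , drop = FALSE]))
  group <- rep(seq_along(graphs), ns)
  n_bins <- graphs[[1]]$n_bins
  A <- lapply(seq_len(n_bins), function(b)
    methods::as(Matrix::bdiag(lapply(graphs, function(g) g$a_hat[[b]])),
                "CsparseMatrix"))
  list(X = X, group = group, A = A, n = length(graphs),
       labels = vapply(graphs, function(g) g$label, 0),
       ids = vapply(graphs, function(g) g$id, ""))
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  (matrix(stats::runif(nr * nc) >= rate, nr, nc)) / (1 - rate)
}

apply_mask <- function(H, mask) if (is.null(mask)) H else H * mask

# Forward pass over a prepared batch. With keep_cache the intermediates
# needed by the backward pass are retained. Dropout masks are drawn from the
# current RNG stream only when train_mode is TRUE.
forward_batch <- function(net, batch, train_mode = FALSE, keep_cache = FALSE) {
  w <- net$weights
  cfg <- net$config
  p <- if (train_mode) cfg$dropout_rate else 0
  three <- cfg$block_layout == "three_fc"
  cache <- list()

  Zin <- sweep_add(batch$X %*% w$w_in, w$b_in)
  Hin <- relu(Zin)
  m_in <- drop_mask(nrow(Hin), ncol(Hin), p)
  H1 <- apply_mask(Hin, m_in)
  if (keep_cache) cache$input <- list(Hin = Hin, m_in = m_in)

  gathered <- vector("list", cfg$n_bins)
  bcache <- vector("list", cfg$n_bins)
  for (b in seq_len(cfg$n_bins)) {
    blk <- w$blocks[[b]]
    A <- batch$A[[b]]
    Hg1 <- relu(as.matrix(A %*% (H1 %*% blk$wg1)))
    Hf1 <- relu(sweep_add(Hg1 %*% blk$wf1, blk$bf1))
    m1 <- drop_mask(nrow(Hf1), ncol(Hf1), p)
    Hd1 <- apply_mask(Hf1, m1)
    Hg2 <- relu(as.matrix(A %*% (Hd1 %*% blk$wg2)))
    Hf2 <- relu(sweep_add(Hg2 %*% blk$wf2, blk$bf2))
    m2 <- drop_mask(nrow(Hf2), ncol(Hf2), p)
    Hd2 <- apply_mask(Hf2, m2)
    Hg3 <- relu(as.matrix(A %*% (Hd2 %*% blk$wg3)))
    Htop <- if (three) relu(sweep_add(Hg3 %*% blk$wf3, blk$bf3)) else Hg3
    gathered[[b]] <- rowsum(Htop, batch$group, reorder = TRUE)
    if (keep_cache)
      bcache[[b]] <- list(Hg1 = Hg1, Hf1 = Hf1, m1 = m1, Hd1 = Hd1,
                          Hg2 = Hg2, Hf2 = Hf2, m2 = m2, Hd2 = Hd2,
                          Hg3 = Hg3, Htop = Htop)
  }
  G <- do.call(cbind, gathered)
  Hfc <- relu(sweep_add(G %*% w$w_fc, w$b_fc))
  m_fc <- drop_mask(nrow(Hfc), ncol(Hfc), p)
  Hfd <- apply_mask(Hfc, m_fc)
  pred <- drop(Hfd %*% w$w_out) + w$b_out
  if (keep_cache)
    cache <- c(cache, list(H1 = H1, blocks = bcache, G = G, Hfc = Hfc,
                           m_fc = m_fc, Hfd = Hfd))
  list(pred = pred, cache = if (keep_cache) cache else NULL)
}

sweep_add <- function(M, b) M + rep(b, each = nrow(M))

#' Predict affinities for pocket graphs
#'
#' Deterministic eval-mode forward pass (dropout off) over a list of graphs.
#'
#' @param net A \code{gcn_network}.
#' @param graphs List of \code{pocket_graph} objects featurized with the
#'   network's bin count.
#' @param batch_size Graphs per forward batch.
#' @return Data frame with columns \code{id}, \code{predicted} and
#'   \code{measured} (the stored labels, possibly NA), in input order.
#' @export
predict_graphs <- function(net, graphs, batch_size = 128L) {
  stopifnot(inherits(net, "gcn_network"))
  if (length(graphs) == 0)
    return(data.frame(id = character(0), predicted = numeric(0),
                      measured = numeric(0)))
  check_bins(net, graphs)
  out <- vector("list", ceiling(length(graphs) / batch_size))
  idx <- split(seq_along(graphs), ceiling(seq_along(graphs) / batch_size))
  for (k in seq_along(idx)) {
    batch <- batch_inputs(graphs[idx[[k]]])
    fw <- forward_batch(net, batch, train_mode = FALSE)
    out[[k]] <- data.frame(id = batch$ids, predicted = fw$pred,
                           measured = batch$labels)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Forward pass on a single pocket graph
#'
#' @param net A \code{gcn_network}.
#' @param graph A \code{pocket_graph} with the network's bin count.
#' @param train_mode Logical; when TRUE dropout is active (stochastic
#'   output drawn from the current RNG stream).
#' @return A single numeric prediction.
#' @export
forward <- function(net, graph, train_mode = FALSE) {
  stopifnot(inherits(net, "gcn_network"), inherits(graph, "pocket_graph"))
  check_bins(net, list(graph))
  forward_batch(net, batch_inputs(list(graph)), train_mode = train_mode)$pred
}

check_bins <- function(net, graphs) {
  nb <- unique(vapply(graphs, function(g) g$n_bins, 0L))
  if (length(nb) != 1 || nb != net$config$n_bins)
    stop("graph bin count (", paste(nb, collapse = ","),
         ") does not match the network configuration (", net$config$n_bins, ")")
  invisible(TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
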