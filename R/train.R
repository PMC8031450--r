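#' Training configuration
#'
#' Adam at learning rate 0.001 minimizing mean squared error, with
#' early stopping on validation MSE (patience 10 epochs, best weights
#' restored). Batches are fixed-size stacks of pocket graphs, reshuffled
#' every epoch from the seeded stream.
#'
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Graphs per gradient step (>= 1).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (>= 1).
#' @param clip_norm Global gradient-norm ceiling per step (Inf disables).
#'   The sum-gather readout scales with the node count, so raw gradients
#'   can spike on large-pocket batches; clipping keeps Adam stable.
#' @param lr_decay Factor applied to the learning rate when the validation
#'   loss has not improved for \code{lr_patience} epochs (plateau decay);
#'   the best weights seen so far are restored at each decay, so training
#'   refines around the current optimum instead of jittering past it.
#'   Set to 1 to disable.
#' @param lr_patience Non-improving epochs tolerated before a decay step.
#' @param min_lr Floor under the decayed learning rate.
#' @param ema_decay Per-update exponential-moving-average coefficient for
#'   the weights that are validated and returned (0 disables averaging).
#'   Dropout makes the raw per-epoch weights a noisy trajectory; validating
#'   the running average instead of the endpoint removes most of that
#'   variance without touching the optimizer itself.
#' @param seed Integer seed driving shuffling and dropout.
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200L,
                         batch_size = 32L, patience = 15L, clip_norm = 5,
                         lr_decay = 0.5, lr_patience = 3L, min_lr = 1e-5,
                         ema_decay = 0.98, seed = 1L) {
  stopifnot(learning_rate >= 0, max_epochs >= 1, batch_size >= 1,
            patience >= 1, clip_norm > 0, lr_decay > 0, lr_decay <= 1,
            lr_patience >= 1, min_lr >= 0, ema_decay >= 0, ema_decay < 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 clip_norm = clip_norm,
                 lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience),
                 min_lr = min_lr,
                 ema_decay = ema_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  total <- 0
  acc <- function(x) {
    if (is.list(x)) lapply(x, acc) else total <<- total + sum(x^2)
    invisible(NULL)
  }
  acc(grads)
  gnorm <- sqrt(total)
  if (gnorm <= clip_norm) return(grads)
  scale_leaf <- function(x) if (is.list(x)) lapply(x, scale_leaf) else
    x * (clip_norm / gnorm)
  scale_leaf(grads)
}

# gradient of the batch-mean squared error w.r.t. every weight
backward_batch <- function(net, batch, fw) {
  w <- net$weights
  cfg <- net$config
  three <- cfg$block_layout == "three_fc"
  cc <- fw$cache
  y <- batch$labels
  resid <- fw$pred - y
  loss <- mean(resid^2)
  d_pred <- matrix(2 * resid / length(y), ncol = 1)

  g <- list(blocks = vector("list", cfg$n_bins))
  g$w_out <- crossprod(cc$Hfd, d_pred)
  g$b_out <- sum(d_pred)
  dHfd <- d_pred %*% t(w$w_out)
  dHfc <- apply_mask(dHfd, cc$m_fc) * (cc$Hfc > 0)
  g$w_fc <- crossprod(cc$G, dHfc)
  g$b_fc <- colSums(dHfc)
  dG <- dHfc %*% t(w$w_fc)

  gathered <- ncol(cc$G) / cfg$n_bins
  dH1 <- matrix(0, nrow(cc$H1), ncol(cc$H1))
  for (b in seq_len(cfg$n_bins)) {
    blk <- w$blocks[[b]]
    bc <- cc$blocks[[b]]
    A <- batch$A[[b]]
    dGb <- dG[, (b - 1) * gathered + seq_len(gathered), drop = FALSE]
    dHtop <- dGb[batch$group, , drop = FALSE]  # gather backward: broadcast
    gb <- list()
    if (three) {
      dZf3 <- dHtop * (bc$Htop > 0)
      gb$wf3 <- crossprod(bc$Hg3, dZf3)
      gb$bf3 <- colSums(dZf3)
      dHg3 <- dZf3 %*% t(blk$wf3)
    } else {
      dHg3 <- dHtop
    }
    dMg3 <- dHg3 * (bc$Hg3 > 0)
    dZg3 <- as.matrix(A %*% dMg3)        # A symmetric
    gb$wg3 <- crossprod(bc$Hd2, dZg3)
    dHd2 <- dZg3 %*% t(blk$wg3)
    dHf2 <- apply_mask(dHd2, bc$m2) * (bc$Hf2 > 0)
    gb$wf2 <- crossprod(bc$Hg2, dHf2)
    gb$bf2 <- colSums(dHf2)
    dHg2 <- dHf2 %*% t(blk$wf2)
    dMg2 <- dHg2 * (bc$Hg2 > 0)
    dZg2 <- as.matrix(A %*% dMg2)
    gb$wg2 <- crossprod(bc$Hd1, dZg2)
    dHd1 <- dZg2 %*% t(blk$wg2)
    dHf1 <- apply_mask(dHd1, bc$m1) * (bc$Hf1 > 0)
    gb$wf1 <- crossprod(bc$Hg1, dHf1)
    gb$bf1 <- colSums(dHf1)
    dHg1 <- dHf1 %*% t(blk$wf1)
    dMg1 <- dHg1 * (bc$Hg1 > 0)
    dZg1 <- as.matrix(A %*% dMg1)
    gb$wg1 <- crossprod(cc$H1, dZg1)
    dH1 <- dH1 + dZg1 %*% t(blk$wg1)
    g$blocks[[b]] <- gb
  }
  dHin <- apply_mask(dH1, cc$input$m_in) * (cc$input$Hin > 0)
  g$w_in <- crossprod(batch$X, dHin)
  g$b_in <- colSums(dHin)
  list(grads = g, loss = loss)
}

# element-wise walk over two parallel nested weight lists; companion leaves
# are looked up by name where names exist, so construction order is free
param_walk <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]] else b[[i]]
      out[[i]] <- param_walk(a[[i]], bi, f)
    }
    out
  } else f(a, b)
}

adam_init <- function(weights) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(weights), v = zero(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_walk(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_walk(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  steps <- param_walk(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  weights <- param_walk(weights, steps, function(w, s) w - lr * s)
  list(weights = weights, state = state)
}

validation_loss <- function(net, graphs, batch_size = 256L) {
  pred <- predict_graphs(net, graphs, batch_size = batch_size)
  mean((pred$predicted - pred$measured)^2)
}

#' Train a network on pocket graphs
#'
#' Minimizes the mean squared error between predicted and measured affinity
#' with Adam, monitoring validation MSE after every epoch. Training stops
#' when the validation loss has not improved for \code{patience} consecutive
#' epochs (or at \code{max_epochs}); the weights from the best validation
#' epoch are returned. The whole run is reproducible from
#' \code{cfg$seed}, which drives per-epoch shuffling and dropout.
#'
#' @param net A \code{gcn_network} (initial weights).
#' @param train_graphs,val_graphs Non-empty lists of labelled
#'   \code{pocket_graph} objects with the network's bin count.
#' @param cfg A \code{\link{train_config}}.
#' @param verbose Print per-epoch losses.
#' @return List with \code{network} (trained, best-epoch weights) and
#'   \code{history} (a \code{train_history}: data.frame of per-epoch train
#'   and validation loss plus \code{best_epoch} and \code{stopped_early}
#'   attributes).
#' @export
train_network <- function(net, train_graphs, val_graphs, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(net, "gcn_network"), inherits(cfg, "train_config"),
            length(train_graphs) >= 1, length(val_graphs) >= 1)
  check_bins(net, train_graphs)
  check_bins(net, val_graphs)
  if (any(!is.finite(vapply(train_graphs, function(g) g$label, 0))))
    stop("training graphs must carry finite labels")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(cfg$seed)

  state <- adam_init(net$weights)
  ema <- if (cfg$ema_decay > 0) net$weights else NULL
  best <- list(loss = Inf, weights = net$weights, epoch = 0L)
  bad_epochs <- 0L
  lr_wait <- 0L
  lr <- cfg$learning_rate
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  stopped_early <- FALSE
  n <- length(train_graphs)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    for (idx in batches) {
      batch <- batch_inputs(train_graphs[idx])
      fw <- forward_batch(net, batch, train_mode = TRUE, keep_cache = TRUE)
      bw <- backward_batch(net, batch, fw)
      epoch_loss <- epoch_loss + bw$loss * length(idx)
      if (lr > 0) {
        upd <- adam_step(net$weights, clip_gradients(bw$grads, cfg$clip_norm),
                         state, lr)
        net$weights <- upd$weights
        state <- upd$state
        if (!is.null(ema))
          ema <- param_walk(ema, net$weights, function(e, w)
            cfg$ema_decay * e + (1 - cfg$ema_decay) * w)
      }
    }
    # validation (and the returned model) use the averaged weights when
    # averaging is enabled; the raw weights keep optimizing underneath
    mon <- net
    if (!is.null(ema)) mon$weights <- ema
    vl <- validation_loss(mon, val_graphs)
    if (!is.finite(vl))
      stop("validation loss diverged (non-finite) at epoch ", epoch)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f",
                      epoch, epoch_loss / n, vl))
    if (vl < best$loss) {
      best <- list(loss = vl, weights = mon$weights, epoch = epoch)
      bad_epochs <- 0L
      lr_wait <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      lr_wait <- lr_wait + 1L
      if (bad_epochs >= cfg$patience) {
        stopped_early <- TRUE
        break
      }
      if (cfg$lr_decay < 1 && lr_wait >= cfg$lr_patience &&
          lr * cfg$lr_decay >= cfg$min_lr) {
        # plateau: halve the step size and refine around the best weights;
        # the Adam moments belong to the discarded trajectory, so reset them
        lr <- lr * cfg$lr_decay
        net$weights <- best$weights
        if (!is.null(ema)) ema <- best$weights
        state <- adam_init(net$weights)
        lr_wait <- 0L
        if (verbose) message(sprintf("  plateau: learning rate -> %g", lr))
      }
    }
  }
  net$weights <- best$weights
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopped_early") <- stopped_early
  class(hist) <- c("train_history", "data.frame")
  list(network = net, history = hist)
}

#' @export
print.train_history <- function(x, ...) {
  cat("Training history: ", nrow(x), " epoch(s), best epoch ",
      attr(x, "best_epoch"), " (val MSE ",
      format(min(x$val_loss), digits = 4), ")",
      if (isTRUE(attr(x, "stopped_early"))) ", stopped early" else "",
      "\n", sep = "")
  invisible(x)
}
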