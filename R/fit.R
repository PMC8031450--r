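#' Fit a graph-convolutional binding-affinity model
#'
#' The main modelling entry point. Takes featurized pocket graphs (from
#' \code{\link{featurize_dataset}} or \code{\link{featurize_pocket}}),
#' builds the multi-block graph convolutional network matching their bin
#' count, and trains it with Adam on mean squared error with early stopping
#' on a validation set. Returns a classed fit object with the usual
#' modelling methods (\code{print}, \code{summary}, \code{coef},
#' \code{predict}, \code{fitted}, \code{residuals}, \code{plot}).
#'
#' @param train List of labelled \code{pocket_graph} objects.
#' @param validation Optional list of labelled graphs monitored for early
#'   stopping. When NULL, a random 10\% of \code{train} (at least one graph)
#'   is held out, drawn from \code{seed}.
#' @param n_bins Number of distance bins; default taken from the graphs.
#' @param config A \code{\link{network_config}}; built from \code{n_bins}
#'   and \code{seed} when NULL.
#' @param train_cfg A \code{\link{train_config}}; built from \code{seed}
#'   and the \code{...} overrides when NULL.
#' @param seed Integer seed for weight initialization, the validation
#'   holdout and training stochasticity.
#' @param verbose Print per-epoch losses.
#' @param ... Passed to \code{\link{train_config}} (e.g.
#'   \code{max_epochs}, \code{batch_size}, \code{patience},
#'   \code{learning_rate}) when \code{train_cfg} is NULL.
#' @return An object of class \code{pocket_gcn}.
#' @examples
#' \donttest{
#' params <- synth_params(seed = 7)
#' graphs <- lapply(1:60, function(i)
#'   featurize_pocket(as_pocket(generate_complex(params, i)), n_bins = 2,
#'                    label = generate_complex(params, i)$label))
#' fit <- pocket_gcn(graphs[1:50], graphs[51:60], max_epochs = 5, seed = 1)
#' predict(fit, graphs[51:60])
#' }
#' @export
pocket_gcn <- function(train, validation = NULL, n_bins = NULL,
                       config = NULL, train_cfg = NULL, seed = 1L,
                       verbose = FALSE, ...) {
  stopifnot(length(train) >= 2)
  if (is.null(n_bins)) n_bins <- train[[1]]$n_bins
  if (is.null(config)) config <- network_config(n_bins = n_bins, seed = seed)
  if (is.null(train_cfg)) train_cfg <- train_config(seed = seed, ...)
  if (is.null(validation)) {
    old <- get_rng_state()
    set.seed(seed)
    hold <- sample(length(train), max(1L, round(0.1 * length(train))))
    set_rng_state(old)
    validation <- train[hold]
    train <- train[-hold]
  }
  net <- build_network(config)
  run <- train_network(net, train, validation, train_cfg, verbose = verbose)
  fitted_train <- predict_graphs(run$network, train)
  val_pred <- predict_graphs(run$network, validation)
  val_report <- if (length(validation) >= 3 &&
                    all(is.finite(val_pred$measured)))
    evaluate_predictions(val_pred$predicted, val_pred$measured) else NULL
  structure(list(network = run$network, history = run$history,
                 config = config, train_cfg = train_cfg,
                 n_train = length(train), n_val = length(validation),
                 fitted_train = fitted_train, val_pred = val_pred,
                 val_report = val_report, call = match.call()),
            class = "pocket_gcn")
}

#' @export
print.pocket_gcn <- function(x, ...) {
  cat("Graph-convolutional binding-affinity model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Trained on %d graphs, validated on %d (%d epochs, best %d%s)\n",
              x$n_train, x$n_val, nrow(x$history),
              attr(x$history, "best_epoch"),
              if (isTRUE(attr(x$history, "stopped_early")))
                ", early stop" else ""))
  cat(sprintf("Best validation MSE: %.4f\n", min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.pocket_gcn <- function(object, ...) {
  structure(list(fit = object), class = "summary.pocket_gcn")
}

#' @export
print.summary.pocket_gcn <- function(x, ...) {
  print(x$fit)
  print(x$fit$network)
  if (!is.null(x$fit$val_report)) {
    cat("Validation metrics:\n")
    print(x$fit$val_report)
  }
  invisible(x)
}

#' @export
coef.pocket_gcn <- function(object, ...) object$network$weights

#' Predict binding affinities from a fitted model
#'
#' @param object A \code{pocket_gcn} fit.
#' @param newdata A list of \code{pocket_graph} objects (or one graph).
#'   When omitted, the training-set predictions are returned.
#' @param ... Unused.
#' @return Named numeric vector of predicted affinities (pKd/pKi scale).
#' @export
predict.pocket_gcn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    p <- object$fitted_train
  } else {
    if (inherits(newdata, "pocket_graph")) newdata <- list(newdata)
    p <- predict_graphs(object$network, newdata)
  }
  stats::setNames(p$predicted, p$id)
}

#' @export
fitted.pocket_gcn <- function(object, ...) {
  stats::setNames(object$fitted_train$predicted, object$fitted_train$id)
}

#' @export
residuals.pocket_gcn <- function(object, ...) {
  stats::setNames(object$fitted_train$measured -
                    object$fitted_train$predicted, object$fitted_train$id)
}

#' Plot training and validation loss curves
#'
#' @param x A \code{pocket_gcn} fit.
#' @param ... Passed to \code{matplot}.
#' @export
plot.pocket_gcn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE",
                    main = "Training history", ...)
  graphics::abline(v = attr(h, "best_epoch"), lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' Eval-mode predictions on labelled test graphs followed by
#' \code{\link{evaluate_predictions}}.
#'
#' @param object A \code{pocket_gcn} fit.
#' @param graphs List of labelled \code{pocket_graph} objects.
#' @return An \code{eval_report}.
#' @export
evaluate_fit <- function(object, graphs) {
  stopifnot(inherits(object, "pocket_gcn"))
  p <- predict_graphs(object$network, graphs)
  evaluate_predictions(p$predicted, p$measured)
}
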