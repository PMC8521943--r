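# Slim CNN for acoustic scene classification: four conv blocks
# (3x3 kernels, channel counts doubling from 32, each block
# conv -> batchnorm -> ReLU -> 2x2 maxpool), then a 280-unit dense layer
# with ReLU and 50% dropout, and a linear output layer with one unit per
# scene class. The numerical engine (forward/backward over mini-batches)
# is compiled code; weight initialisation, Adam and the training loop live
# here.

#' Define the scene-classifier architecture
#'
#' @param conv_filters Channel counts of the conv blocks. Default
#'   `c(32, 64, 128, 256)` (doubling from 32, 3x3 kernels throughout).
#' @param fc1_width Width of the first dense layer. Default 280.
#' @param dropout_rate Dropout probability between the dense layers.
#'   Default 0.5.
#' @param n_classes Number of output units. Default 14.
#' @return A `cnn_architecture` list.
#' @export
cnn_architecture <- function(conv_filters = c(32L, 64L, 128L, 256L),
                             fc1_width = 280L, dropout_rate = 0.5,
                             n_classes = 14L) {
  stopifnot(length(conv_filters) >= 1, all(conv_filters >= 1),
            fc1_width >= 1, dropout_rate >= 0, dropout_rate < 1,
            n_classes >= 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = c(3L, 3L), pool = c(2L, 2L),
                 fc1_width = as.integer(fc1_width),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes)),
            class = "cnn_architecture")
}

#' Instantiate a scene-classifier model
#'
#' Initialises all weights (He initialisation for conv and dense layers,
#' batchnorm at gamma = 1 / beta = 0) for a fixed input shape. The input
#' must survive one 2x2 pooling per conv block, i.e. both feature-grid
#' dimensions must be at least `2^n_blocks`.
#'
#' @param arch A [cnn_architecture()].
#' @param input_shape `c(M, T)`: rows (dictionary filters) and columns
#'   (time bins) of the spikegram input.
#' @param seed Integer seed for the weight initialisation.
#' @return A `cnn_model`: list with `arch`, `input_shape`, `params`,
#'   `running` (batchnorm running statistics), `classes` (set after
#'   training), `trained`.
#' @export
build_model <- function(arch, input_shape, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"), length(input_shape) == 2)
  nb <- length(arch$conv_filters)
  if (any(input_shape < 2^nb))
    stop(sprintf("input %dx%d too small for %d 2x2 poolings",
                 input_shape[1], input_shape[2], nb), call. = FALSE)
  with_seed(seed, {
    params <- list()
    running <- list()
    cin <- 1L
    h <- input_shape[1] %/% 1L
    w <- input_shape[2] %/% 1L
    for (l in seq_len(nb)) {
      cout <- arch$conv_filters[l]
      fan_in <- 9 * cin
      params[[paste0("Wc", l)]] <-
        matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)),
               nrow = cout)
      params[[paste0("bc", l)]] <- numeric(cout)
      params[[paste0("gamma", l)]] <- rep(1, cout)
      params[[paste0("beta", l)]] <- numeric(cout)
      running[[paste0("rm", l)]] <- numeric(cout)
      running[[paste0("rv", l)]] <- rep(1, cout)
      cin <- cout
      h <- h %/% 2L
      w <- w %/% 2L
    }
    flat <- cin * h * w
    params$Wf1 <- matrix(stats::rnorm(arch$fc1_width * flat, 0,
                                      sqrt(2 / flat)),
                         nrow = arch$fc1_width)
    params$bf1 <- numeric(arch$fc1_width)
    params$Wf2 <- matrix(stats::rnorm(arch$n_classes * arch$fc1_width, 0,
                                      sqrt(2 / arch$fc1_width)),
                         nrow = arch$n_classes)
    params$bf2 <- numeric(arch$n_classes)
    structure(list(arch = arch, input_shape = as.integer(input_shape),
                   params = params, running = running,
                   classes = NULL, trained = FALSE),
              class = "cnn_model")
  })
}

#' Number of trainable parameters of a model
#'
#' Counts conv/dense weights and biases and the batchnorm scale/shift
#' pairs (running statistics are not trainable).
#'
#' @param model A `cnn_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "CNN scene classifier: input %dx%d, conv channels [%s], fc %d, %d classes\n",
    x$input_shape[1], x$input_shape[2],
    paste(x$arch$conv_filters, collapse = ", "),
    x$arch$fc1_width, x$arch$n_classes
  ))
  cat(sprintf("  %s parameters, %strained\n",
              format(n_params(x), big.mark = ","),
              if (x$trained) "" else "not "))
  invisible(x)
}

model_dims <- function(model) {
  list(H = model$input_shape[1], W = model$input_shape[2],
       channels = model$arch$conv_filters, nclass = model$arch$n_classes)
}

# stack a list of M x T feature matrices into the engine's batch layout
# (channel rows, columns sample-major over (sample, y, x))
stack_features <- function(features) {
  hw <- dim(features[[1]])
  bad <- vapply(features, function(f)
    !all(dim(f) == hw) || !all(is.finite(f)), logical(1))
  if (any(bad)) stop("features must share one finite M x T shape",
                     call. = FALSE)
  matrix(unlist(lapply(features, function(f) as.vector(t(f)))), nrow = 1)
}

#' Forward a batch of features through a model
#'
#' Uses the batchnorm running statistics and no dropout (inference mode).
#'
#' @param model A `cnn_model`.
#' @param features List of M x T feature matrices (e.g. `spikegram$grid`).
#' @return Matrix of class probabilities, one row per feature, columns
#'   named by class when the model has been trained.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "cnn_model"))
  X <- stack_features(features)
  out <- cnn_pass(model$params, model$running, X, integer(0),
                  model_dims(model), NULL, FALSE, 0.9, FALSE)
  p <- t(out$probs)
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

#' Predict scene labels
#'
#' @inheritParams predict_proba
#' @return Character vector of predicted class labels (or integer class
#'   indices for an untrained model without label set).
#' @export
predict_label <- function(model, features) {
  p <- predict_proba(model, features)
  idx <- max.col(p, ties.method = "first")
  if (!is.null(model$classes)) model$classes[idx] else idx
}
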