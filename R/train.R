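#' Training configuration for the scene classifier
#'
#' Defaults follow the evaluation protocol: Adam, mini-batches of 24,
#' at most 250 epochs with early stopping after 10 epochs without
#' improvement of the monitored (training) loss, a stratified 70/30
#' train/test split and 10 repetitions of the whole experiment.
#'
#' @param learning_rate Adam step size. Default 1e-3.
#' @param batch_size Mini-batch size. Default 24.
#' @param max_epochs Maximum number of epochs. Default 250.
#' @param patience Early-stopping patience in epochs; must be smaller than
#'   `max_epochs`. Default 10.
#' @param min_delta Smallest decrease of the monitored loss that counts as
#'   an improvement; changes below it (floating-point noise from batch
#'   reordering) do not reset the patience counter. Default 1e-8.
#' @param train_fraction Fraction of records assigned to training.
#'   Default 0.70.
#' @param n_repetitions Number of independent train/test repetitions for
#'   [repeated_experiment()]. Default 10.
#' @param seed Base seed for all stochastic elements (split, weight
#'   initialisation, shuffling, dropout).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 24L,
                            max_epochs = 250L, patience = 10L,
                            min_delta = 1e-8,
                            train_fraction = 0.70, n_repetitions = 10L,
                            seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1,
            train_fraction > 0, train_fraction < 1,
            patience >= 1, patience < max_epochs, min_delta >= 0,
            n_repetitions >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "training_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a scene classifier
#'
#' Minimises categorical cross-entropy with Adam over shuffled
#' mini-batches. Training stops at the first epoch after `patience`
#' consecutive epochs without improvement of the monitored loss over its
#' running best, or at `max_epochs`. The monitored loss is the mean
#' training loss per epoch by default, or the loss on `monitor_features`
#' when a held-out monitor set is supplied. Identical seeds and data give
#' identical loss histories.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param features List of M x T feature matrices.
#' @param labels Factor or character vector of scene labels, one per
#'   feature.
#' @param config A [training_config()].
#' @param monitor_features,monitor_labels Optional held-out set used as
#'   the early-stopping monitor instead of the training loss.
#' @return The trained `cnn_model`, with `loss_history` (monitored loss
#'   per epoch), `epochs_run` and `classes` attached.
#' @export
train_classifier <- function(model, features, labels, config,
                             monitor_features = NULL,
                             monitor_labels = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "training_config"))
  if (length(features) == 0) stop("empty training set", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(labels) > model$arch$n_classes)
    stop("more classes in the data than model outputs", call. = FALSE)
  classes <- levels(labels)
  y_all <- as.integer(labels)
  n <- length(features)
  keep <- 1 - model$arch$dropout_rate

  with_seed(config$seed, {
    params <- model$params
    running <- model$running
    state <- adam_init(params)
    dims <- model_dims(model)
    best <- Inf
    wait <- 0L
    history <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      nbatch <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        X <- stack_features(features[idx])
        y <- y_all[idx]
        dmask <- if (keep < 1)
          matrix(stats::rbinom(model$arch$fc1_width * length(idx), 1, keep) / keep,
                 nrow = model$arch$fc1_width)
        else NULL
        out <- cnn_pass(params, running, X, y, dims, dmask, TRUE, 0.9, TRUE)
        if (!is.finite(out$loss))
          stop("training diverged: non-finite loss", call. = FALSE)
        running <- out$running
        st <- adam_step(params, out$grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + out$loss * length(idx)
        nbatch <- nbatch + 1L
      }
      monitored <- if (!is.null(monitor_features)) {
        ym <- as.integer(factor(monitor_labels, levels = classes))
        Xm <- stack_features(monitor_features)
        cnn_pass(params, running, Xm, ym, dims, NULL, FALSE, 0.9, FALSE)$loss
      } else {
        epoch_loss / n
      }
      history <- c(history, monitored)
      if (monitored < best - config$min_delta) {
        best <- monitored
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    model$params <- params
    model$running <- running
    model$classes <- classes
    model$trained <- TRUE
    model$loss_history <- history
    model$epochs_run <- length(history)
    model
  })
}
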