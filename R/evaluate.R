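#' Stratified train/test split
#'
#' Splits record indices into disjoint train and test sets, stratified by
#' class, with the overall training share equal to
#' `round(train_fraction * n)` records. Deterministic given `seed`.
#'
#' @param labels Factor or character vector of class labels.
#' @param train_fraction Training share in (0, 1). Default 0.70.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.70, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 records to split", call. = FALSE)
  n <- length(labels)
  target <- round(train_fraction * n)
  with_seed(seed, {
    per_class <- lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      idx[sample.int(length(idx))]
    })
    take <- vapply(per_class, function(idx)
      max(1L, min(length(idx) - 1L,
                  as.integer(round(train_fraction * length(idx))))),
      integer(1))
    # adjust class takes so the overall share is exactly round(f * n)
    excess <- sum(take) - target
    ord <- order(lengths(per_class), decreasing = TRUE)
    j <- 1L
    while (excess != 0) {
      k <- ord[(j - 1L) %% length(ord) + 1L]
      room_dn <- take[k] > 1L
      room_up <- take[k] < lengths(per_class)[k] - 1L
      if (excess > 0 && room_dn) {
        take[k] <- take[k] - 1L
        excess <- excess - 1L
      } else if (excess < 0 && room_up) {
        take[k] <- take[k] + 1L
        excess <- excess + 1L
      }
      j <- j + 1L
      if (j > 10L * length(ord)) break   # no feasible exact split
    }
    train <- unlist(lapply(seq_along(per_class), function(k)
      per_class[[k]][seq_len(take[k])]))
    list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
  })
}

#' Confusion matrix and accuracies from predictions
#'
#' Row r, column c counts records of true class r predicted as class c.
#' Per-class accuracy is the diagonal over the row sum; overall accuracy
#' the trace over the total.
#'
#' @param true True labels (factor/character).
#' @param predicted Predicted labels; must take values in `classes`.
#' @param classes Class set defining row/column order; default the levels
#'   of `true`.
#' @return List with `confusion` (count matrix), `per_class_accuracy`,
#'   `overall_accuracy`.
#' @export
evaluate_predictions <- function(true, predicted,
                                 classes = levels(as.factor(true))) {
  true <- factor(true, levels = classes)
  predicted <- factor(predicted, levels = classes)
  if (anyNA(true) || anyNA(predicted))
    stop("labels outside the model's class set", call. = FALSE)
  cm <- table(true = true, predicted = predicted)
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(cm)
  per_class <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(per_class) <- classes
  list(confusion = cm,
       per_class_accuracy = per_class,
       overall_accuracy = sum(diag(cm)) / sum(cm))
}

#' Evaluate a trained model on a test set
#'
#' @param model Trained `cnn_model`.
#' @param features List of feature matrices.
#' @param labels True labels.
#' @return As [evaluate_predictions()].
#' @export
evaluate_model <- function(model, features, labels) {
  if (length(features) == 0) stop("empty test set", call. = FALSE)
  pred <- predict_label(model, features)
  evaluate_predictions(labels, pred, classes = model$classes)
}

#' Repeated randomized train/test experiment
#'
#' Runs the full protocol `n_repetitions` times: a fresh stratified split,
#' fresh weight initialisation, training with early stopping, evaluation
#' on the held-out records. Reports the mean and standard deviation of the
#' row-normalised confusion matrices, per-class accuracies and the mean
#' overall accuracy across repetitions.
#'
#' @param features List of feature matrices.
#' @param labels Scene labels.
#' @param arch A [cnn_architecture()].
#' @param config A [training_config()] (its `seed` seeds the whole
#'   experiment; repetition r uses seeds derived from it).
#' @return An `evaluation_report`: list with `per_class_accuracy` (mean
#'   over repetitions), `overall_accuracy` (mean), `overall_accuracies`
#'   (per repetition), `confusion_mean`, `confusion_std` (row-normalised,
#'   elementwise over repetitions), `n_repetitions`, `epochs_run`.
#' @export
repeated_experiment <- function(features, labels, arch, config) {
  stopifnot(inherits(arch, "cnn_architecture"),
            inherits(config, "training_config"))
  labels <- as.factor(labels)
  classes <- levels(labels)
  shape <- dim(features[[1]])
  reps <- vector("list", config$n_repetitions)
  for (r in seq_len(config$n_repetitions)) {
    sp <- split_dataset(labels, config$train_fraction,
                        seed = derive_seed(config$seed, 2L * r))
    model <- build_model(arch, shape, seed = derive_seed(config$seed, 2L * r + 1L))
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 1000L + r)
    model <- train_classifier(model, features[sp$train], labels[sp$train],
                              cfg_r)
    ev <- evaluate_model(model, features[sp$test],
                         as.character(labels[sp$test]))
    rs <- rowSums(ev$confusion)
    reps[[r]] <- list(
      norm_confusion = ev$confusion / ifelse(rs > 0, rs, 1),
      per_class = ev$per_class_accuracy,
      overall = ev$overall_accuracy,
      epochs = model$epochs_run
    )
  }
  ncm <- simplify2array(lapply(reps, `[[`, "norm_confusion"))
  structure(list(
    per_class_accuracy = rowMeans(sapply(reps, `[[`, "per_class")),
    overall_accuracy = mean(vapply(reps, `[[`, numeric(1), "overall")),
    overall_accuracies = vapply(reps, `[[`, numeric(1), "overall"),
    confusion_mean = apply(ncm, c(1, 2), mean),
    confusion_std = if (config$n_repetitions == 1)
      array(0, dim(ncm)[1:2]) else apply(ncm, c(1, 2), stats::sd),
    confusion_runs = ncm,
    n_repetitions = config$n_repetitions,
    epochs_run = vapply(reps, `[[`, numeric(1), "epochs"),
    classes = classes
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Scene-classification report over %d repetition(s)\n", x$n_repetitions))
  cat(sprintf("  mean overall accuracy: %.4f\n", x$overall_accuracy))
  cat("  per-class accuracy (mean):\n")
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}

#' Encode a corpus into spikegram features
#'
#' Convenience pipeline: matching-pursuit encode every record of a corpus
#' and rasterise the codes into classifier-ready feature grids. The atom
#' budget defaults to the canonical 1024 atoms per 10 s, scaled to the
#' record duration.
#'
#' @param corpus A `scene_corpus` (or plain list of `scene_record`).
#' @param bank A [build_filterbank()] dictionary.
#' @param K Atom budget per record; default `round(1024 * duration / 10)`.
#' @param bin_width Raster bin width in samples; default 25 ms.
#' @param transform Raster amplitude transform; see [rasterize()].
#' @param verbose Print progress every 50 records.
#' @return List with `features` (list of M x T matrices), `labels`,
#'   `groups`.
#' @export
corpus_features <- function(corpus, bank, K = NULL,
                            bin_width = round(0.025 * bank$sample_rate),
                            transform = "log1p", verbose = FALSE) {
  records <- if (inherits(corpus, "scene_corpus")) corpus$records else corpus
  feats <- vector("list", length(records))
  labs <- character(length(records))
  grps <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    Ki <- if (is.null(K)) as.integer(round(1024 * r$duration / 10)) else K
    code <- matching_pursuit(r$audio, bank, K = Ki)
    feats[[i]] <- rasterize(code, bank, bin_width = bin_width,
                            transform = transform)$grid
    labs[i] <- r$label
    grps[i] <- r$group
    if (verbose && i %% 50 == 0)
      message(sprintf("encoded %d/%d records", i, length(records)))
  }
  list(features = feats, labels = labs, groups = grps)
}
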