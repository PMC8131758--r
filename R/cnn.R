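#' Configuration of the six-class CNN
#'
#' A scaled-down VGG-style stack: each block is a 3x3 same-padding
#' convolution + ReLU followed by 2x2 max-pooling, then one dense ReLU layer
#' (the penultimate feature layer used by the assisted-labeling engine) and
#' a 6-way softmax output. Depth and widths are configurable; the default
#' three blocks at widths 12/24/48 train in minutes on a single CPU while
#' retaining the architecture family of much larger stacks.
#'
#' @param input_size Square input side, pixels; must be divisible by
#'   `2^length(conv_widths)`.
#' @param n_channels Number of input channels (fixed at 2: brightfield+DNA).
#' @param conv_widths Integer vector of per-block filter counts.
#' @param penultimate Width of the dense feature layer.
#' @param n_classes Number of output classes (fixed at 6).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch cap (default 70).
#' @param patience Early-stopping patience on validation accuracy.
#' @param seed Integer seed for weight initialization and batch order.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = 64L, n_channels = 2L,
                         conv_widths = c(12L, 24L, 48L), penultimate = 48L,
                         n_classes = 6L, learning_rate = 1e-3,
                         batch_size = 32L, max_epochs = 70L, patience = 8L,
                         seed = 1L) {
  if (n_classes != 6L) stop("the MN taxonomy has exactly 6 classes")
  if (n_channels != 2L) stop("two channels (brightfield + DNA) are required")
  if (input_size %% (2^length(conv_widths)) != 0)
    stop("input_size must be divisible by 2^(number of conv blocks)")
  structure(list(input_size = as.integer(input_size),
                 n_channels = 2L,
                 conv_widths = as.integer(conv_widths),
                 penultimate = as.integer(penultimate), n_classes = 6L,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained CNN
#'
#' Weights are drawn with He-scaled Gaussian initialization from the
#' configured seed, so the same config + seed always yields the identical
#' initial model (and hence identical initial predictions).
#'
#' @param config A [model_config()].
#' @param seed Optional override of `config$seed`.
#' @return An object of class `mn_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    cw <- config$conv_widths
    cin <- c(config$n_channels, cw[-length(cw)])
    Wc <- bc <- vector("list", length(cw))
    for (l in seq_along(cw)) {
      fan_in <- cin[l] * 9L
      Wc[[l]] <- matrix(rnorm(fan_in * cw[l], 0, sqrt(2 / fan_in)),
                        fan_in, cw[l])
      bc[[l]] <- rep(0, cw[l])
    }
    side <- config$input_size / 2^length(cw)
    flat <- as.integer(side^2 * cw[length(cw)])
    W1 <- matrix(rnorm(config$penultimate * flat, 0, sqrt(2 / flat)),
                 config$penultimate, flat)
    W2 <- matrix(rnorm(config$n_classes * config$penultimate, 0,
                       sqrt(2 / config$penultimate)),
                 config$n_classes, config$penultimate)
    structure(list(config = config,
                   params = list(Wc = Wc, bc = bc, W1 = W1,
                                 b1 = rep(0, config$penultimate), W2 = W2,
                                 b2 = rep(0, config$n_classes)),
                   trained = FALSE, history = NULL),
              class = "mn_model")
  })
}

#' @export
print.mn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("mn_model: %dx%dx2 input, conv widths [%s], penultimate %d, %s\n",
              cfg$input_size, cfg$input_size,
              paste(cfg$conv_widths, collapse = ","), cfg$penultimate,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# dataset/array -> d x n matrix in the layout the C++ kernels expect
images_to_matrix <- function(x) {
  if (inherits(x, "mn_dataset")) x <- x$images
  d <- dim(x)
  if (length(d) == 3L) { x <- array(x, c(d, 1L)); d <- dim(x) }
  stopifnot(length(d) == 4L, d[3] == 2L)
  matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

labels_to_int <- function(labels) {
  f <- factor(labels, levels = mn_classes())
  if (anyNA(f)) stop("labels outside the six-class vocabulary")
  as.integer(f) - 1L
}

#' Assemble split, balanced, augmented training tensors
#'
#' Applies the standard training-set preparation: select the split members,
#' oversample minority classes to the majority size, apply a random dihedral
#' augmentation to each oversampled duplicate (originals are kept
#' unmodified), then append `augment_copies` randomly augmented copies of
#' the whole balanced set. Validation and test members are passed through
#' untouched.
#'
#' @param dataset An `mn_dataset` with per-image values already in `[0, 1]`.
#' @param split A [split_ground_truth()] assignment over the dataset's
#'   objects (or over a ground-truth subset of them).
#' @param seed Integer seed for balancing and augmentation draws.
#' @param augment_copies Number of additional randomly augmented copies of
#'   every (balanced) training image appended to the training set (default
#'   1).
#' @return List with elements `train`, `validation`, `test`, each a list of
#'   `x` (d x n matrix) and `y` (character labels).
#' @export
prepare_training_data <- function(dataset, split, seed = 1L,
                                  augment_copies = 1L) {
  stopifnot(inherits(dataset, "mn_dataset"))
  idx_of <- stats::setNames(seq_len(nrow(dataset$manifest)),
                            dataset$manifest$object_id)
  missing <- setdiff(split$object_id, names(idx_of))
  if (length(missing)) stop("split references unknown object ids")
  seeds <- derive_seeds(seed, 3L)
  out <- list()
  for (s in c("train", "validation", "test")) {
    sub <- split[split$split == s, ]
    ids <- sub$object_id
    labs <- sub$label
    if (s == "train") {
      per_class <- base::split(ids, factor(labs, levels = mn_classes()))
      per_class <- per_class[vapply(per_class, length, 1L) > 0]
      balanced <- balance_classes(per_class, seed = seeds[1])
      ids2 <- unlist(balanced, use.names = FALSE)
      labs <- rep(names(balanced), vapply(balanced, length, 1L))
      # duplicates are the entries beyond each class's original run
      dup_flags <- unlist(lapply(seq_along(balanced), function(i) {
        k <- length(balanced[[i]])
        c(rep(FALSE, length(per_class[[i]])),
          rep(TRUE, k - length(per_class[[i]])))
      }), use.names = FALSE)
      imgs <- dataset$images[, , , idx_of[ids2], drop = FALSE]
      aug_seeds <- derive_seeds(seeds[2], max(1L, sum(dup_flags)))
      j <- 0L
      for (i in which(dup_flags)) {
        j <- j + 1L
        imgs[, , , i] <- augment_image(imgs[, , , i], seed = aug_seeds[j])
      }
      # additional augmented copies of the whole balanced set
      nb <- dim(imgs)[4]
      if (augment_copies > 0) {
        copy_seeds <- derive_seeds(seeds[3], nb * augment_copies)
        all_imgs <- array(0, c(dim(imgs)[1:3], nb * (1L + augment_copies)))
        all_imgs[, , , seq_len(nb)] <- imgs
        for (cpy in seq_len(augment_copies)) {
          for (i in seq_len(nb)) {
            all_imgs[, , , cpy * nb + i] <-
              augment_image(imgs[, , , i],
                            seed = copy_seeds[(cpy - 1L) * nb + i])
          }
        }
        imgs <- all_imgs
        labs <- rep(labs, 1L + augment_copies)
      }
      out[[s]] <- list(x = images_to_matrix(imgs), y = labs)
    } else {
      imgs <- dataset$images[, , , idx_of[ids], drop = FALSE]
      out[[s]] <- list(x = images_to_matrix(imgs), y = labs)
    }
  }
  out
}

#' Train the CNN
#'
#' Minimizes the cross-entropy on the (balanced, augmented) training set
#' with Adam, evaluating validation accuracy after each epoch. Training
#' stops at `max_epochs` or when validation accuracy has not improved for
#' `patience` epochs, and the weights of the best validation epoch are
#' returned. The validation set is never used for weight updates.
#'
#' @param model An `mn_model` from [build_model()].
#' @param data A list as produced by [prepare_training_data()] (elements
#'   `train` and optionally `validation`, each with `x`, `y`).
#' @param seed Optional override of the config seed for batch shuffling.
#' @return The trained `mn_model`, with a `history` data frame of per-epoch
#'   train/validation loss and accuracy and a `best_epoch` attribute.
#' @export
train_model <- function(model, data, seed = NULL) {
  stopifnot(inherits(model, "mn_model"))
  cfg <- model$config
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(data$train) || length(data$train$y) == 0)
    stop("empty training split")
  Xtr <- data$train$x
  ytr <- labels_to_int(data$train$y)
  has_val <- !is.null(data$validation) && length(data$validation$y) > 0
  Xval <- if (has_val) data$validation$x else matrix(0, nrow(Xtr), 0)
  yval <- if (has_val) labels_to_int(data$validation$y) else integer(0)
  ntr <- ncol(Xtr)
  perms <- with_seed(seed,
    vapply(seq_len(cfg$max_epochs), function(e) sample.int(ntr),
           integer(ntr)))
  res <- cnn_train_cpp(model$params, Xtr, ytr, Xval, yval,
                       cfg$input_size, cfg$input_size, cfg$n_channels,
                       length(cfg$conv_widths), cfg$learning_rate,
                       cfg$batch_size, cfg$max_epochs, cfg$patience,
                       perms)
  model$params <- res$params
  model$trained <- TRUE
  ne <- length(res$train_loss)
  model$history <- data.frame(
    epoch = seq_len(ne),
    train_loss = res$train_loss, train_acc = res$train_acc,
    val_loss = if (has_val) res$val_loss else NA_real_,
    val_acc = if (has_val) res$val_acc else NA_real_)
  model$best_epoch <- res$best_epoch
  model
}

#' Classify objects with a trained model
#'
#' @param model A trained `mn_model`.
#' @param objects An `mn_dataset`, an image array (`h x w x 2 [x n]`) or a
#'   pre-flattened `d x n` matrix.
#' @return Data frame with `object_id` (when available), the argmax `label`,
#'   its softmax `confidence`, and one probability column per class.
#' @export
classify_objects <- function(model, objects) {
  stopifnot(inherits(model, "mn_model"))
  ids <- NULL
  if (inherits(objects, "mn_dataset")) ids <- objects$manifest$object_id
  X <- if (is.matrix(objects) && length(dim(objects)) == 2L &&
           nrow(objects) == model$config$input_size^2 * 2L) objects
       else images_to_matrix(objects)
  if (nrow(X) != model$config$input_size^2 * 2L)
    stop("image size does not match the model input size")
  cfg <- model$config
  res <- cnn_forward_cpp(model$params, X, cfg$input_size, cfg$input_size,
                         cfg$n_channels, length(cfg$conv_widths), FALSE)
  probs <- res$probs
  colnames(probs) <- mn_classes()
  lab <- mn_classes()[max.col(probs, ties.method = "first")]
  out <- data.frame(label = lab, confidence = apply(probs, 1, max),
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(object_id = ids, out)
  cbind(out, as.data.frame(probs))
}

#' Extract penultimate-layer features
#'
#' Deterministically maps each object through the network up to the dense
#' feature layer just before classification; these vectors drive the object
#' map, over-clustering and linear-model prediction of the assisted-labeling
#' engine.
#'
#' @inheritParams classify_objects
#' @return Numeric matrix, one row per object, `penultimate` columns.
#' @export
extract_features <- function(model, objects) {
  stopifnot(inherits(model, "mn_model"))
  X <- if (is.matrix(objects) && nrow(objects) == model$config$input_size^2 * 2L)
    objects else images_to_matrix(objects)
  if (nrow(X) != model$config$input_size^2 * 2L)
    stop("image size does not match the model input size")
  cfg <- model$config
  res <- cnn_forward_cpp(model$params, X, cfg$input_size, cfg$input_size,
                         cfg$n_channels, length(cfg$conv_widths), TRUE)
  res$features
}

#' Save / load a model (weights + config together)
#' @param model An `mn_model`.
#' @param path File path (`.rds`).
#' @return `write_model` returns the path invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "mn_model"))
  m
}
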