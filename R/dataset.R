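#' Min-max normalize an image to [0, 1]
#'
#' Each image is scaled independently by its own minimum and maximum, so the
#' full dynamic range of every object is used regardless of acquisition
#' scaling (8-bit, 16-bit or float input). A flat (constant) image normalizes
#' to all zeros.
#'
#' @param pixels Numeric matrix of raw intensities.
#' @return Numeric matrix with all values in `[0, 1]`.
#' @export
normalize_image <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty matrix")
  lo <- min(pixels)
  hi <- max(pixels)
  if (hi <= lo) return(matrix(0, nrow(pixels), ncol(pixels)))
  (pixels - lo) / (hi - lo)
}

# normalize every channel of every object in a dataset, in place
normalize_dataset <- function(dataset) {
  n <- dim(dataset$images)[4]
  for (i in seq_len(n))
    for (ch in 1:2)
      dataset$images[, , ch, i] <- normalize_image(dataset$images[, , ch, i])
  dataset
}

#' Sample a segment of objects for assisted labeling
#'
#' A segment is a random sample without replacement of (by default) 1500
#' object ids, the working unit of the cluster/predict labeling loop. When
#' the pool holds fewer objects than `size`, all of them are returned.
#'
#' @param object_ids Character vector of candidate object ids (or an
#'   `mn_dataset`, whose manifest ids are used).
#' @param size Segment size (default 1500).
#' @param seed Integer seed.
#' @return Character vector of distinct sampled ids.
#' @export
make_segment <- function(object_ids, size = 1500L, seed = 1L) {
  if (inherits(object_ids, "mn_dataset"))
    object_ids <- object_ids$manifest$object_id
  if (length(object_ids) == 0) stop("empty dataset: nothing to segment")
  if (anyDuplicated(object_ids)) stop("object ids must be unique")
  if (length(object_ids) <= size) return(object_ids)
  with_seed(seed, sample(object_ids, size))
}

#' Partition a dataset into disjoint segments
#'
#' Repeatedly samples segments without replacement across segments, so the
#' union of the returned segments never repeats an id.
#'
#' @inheritParams make_segment
#' @param n_segments Number of segments to draw.
#' @return List of character vectors.
#' @export
make_segments <- function(object_ids, n_segments, size = 1500L, seed = 1L) {
  if (inherits(object_ids, "mn_dataset"))
    object_ids <- object_ids$manifest$object_id
  seeds <- derive_seeds(seed, n_segments)
  out <- vector("list", n_segments)
  pool <- object_ids
  for (i in seq_len(n_segments)) {
    if (length(pool) == 0) stop("pool exhausted after ", i - 1, " segments")
    out[[i]] <- make_segment(pool, size = size, seed = seeds[i])
    pool <- setdiff(pool, out[[i]])
  }
  out
}

#' Create an empty ground-truth store
#'
#' The store maps each of the six trainable classes to a set of object ids.
#' The sets are kept pairwise disjoint: assigning an object to a class
#' removes it from any class it previously belonged to.
#'
#' @return An object of class `gt_store`.
#' @export
gt_store <- function() {
  s <- stats::setNames(vector("list", 6), mn_classes())
  for (k in mn_classes()) s[[k]] <- character(0)
  structure(list(classes = s), class = "gt_store")
}

#' Assign objects to a ground-truth class
#'
#' @param store A [gt_store()].
#' @param label One of the six trainable classes (`UNKNOWN` is rejected).
#' @param object_ids Ids to assign.
#' @return The updated store.
#' @export
assign_ground_truth <- function(store, label, object_ids) {
  stopifnot(inherits(store, "gt_store"))
  if (identical(label, "UNKNOWN"))
    stop("UNKNOWN is not a ground-truth class")
  assert_class_label(label)
  object_ids <- unique(as.character(object_ids))
  for (k in mn_classes())
    if (k != label) store$classes[[k]] <- setdiff(store$classes[[k]], object_ids)
  store$classes[[label]] <- union(store$classes[[label]], object_ids)
  store
}

#' Per-class and total sizes of a ground-truth store
#' @param store A [gt_store()].
#' @return Named integer vector with one entry per class.
#' @export
gt_counts <- function(store) {
  vapply(store$classes, length, integer(1))
}

#' Labels held in a ground-truth store
#' @param store A [gt_store()].
#' @return Data frame with columns `object_id` and `label`.
#' @export
gt_labels <- function(store) {
  data.frame(
    object_id = unlist(store$classes, use.names = FALSE),
    label = rep(names(store$classes), gt_counts(store)),
    stringsAsFactors = FALSE)
}

#' @export
print.gt_store <- function(x, ...) {
  cat("gt_store:", sum(gt_counts(x)), "objects\n")
  print(gt_counts(x))
  invisible(x)
}

#' Serialize / restore a ground-truth store as JSON
#' @param store A [gt_store()].
#' @param path File path.
#' @return `write_gt_store` returns the path invisibly; `read_gt_store`
#'   returns a `gt_store`.
#' @export
write_gt_store <- function(store, path) {
  jsonlite::write_json(store$classes, path)
  invisible(path)
}

#' @rdname write_gt_store
#' @export
read_gt_store <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- gt_store()
  for (k in intersect(names(raw), mn_classes()))
    s <- assign_ground_truth(s, k, raw[[k]])
  s
}

# allocate n into parts proportional to ratios: floor each share, then hand
# leftover units out one per split in listed (priority) order
allocate_counts <- function(n, ratios) {
  base <- floor(n * ratios)
  left <- n - sum(base)
  if (left > 0) {
    idx <- rep(seq_along(ratios), length.out = left)
    for (i in idx) base[i] <- base[i] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split of the ground truth
#'
#' Splits each class independently in the given ratios (default 80/10/10).
#' Counts are rounded by flooring each share and assigning the leftover
#' objects to the splits in priority order (train, then validation, then
#' test). Every class must have at least 3 members so that all three splits
#' can be populated.
#'
#' @param store A [gt_store()] with every class non-empty.
#' @param ratios Length-3 numeric summing to 1.
#' @param seed Integer seed for the within-class shuffles.
#' @return Data frame (class `split_assignment`) with columns `object_id`,
#'   `label`, `split` (factor: train/validation/test).
#' @export
split_ground_truth <- function(store, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(store, "gt_store"))
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three values summing to 1")
  counts <- gt_counts(store)
  if (any(counts == 0))
    stop("every class must be non-empty; missing: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (any(counts < 3))
    stop("classes with fewer than 3 members cannot populate all splits: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  seeds <- derive_seeds(seed, length(counts))
  rows <- list()
  for (i in seq_along(counts)) {
    k <- names(counts)[i]
    ids <- with_seed(seeds[i], sample(store$classes[[k]]))
    alloc <- allocate_counts(length(ids), ratios)
    # guarantee each split is non-empty
    while (any(alloc == 0)) {
      z <- which.min(alloc)
      m <- which.max(alloc)
      alloc[z] <- alloc[z] + 1L
      alloc[m] <- alloc[m] - 1L
    }
    split <- rep(c("train", "validation", "test"), alloc)
    rows[[k]] <- data.frame(object_id = ids, label = k, split = split,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$split <- factor(out$split, levels = c("train", "validation", "test"))
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Oversample minority classes to balance the training set
#'
#' Every class is brought up to the size of the largest class by resampling
#' its members with replacement; all original members are always retained.
#'
#' @param ids_per_class Named list mapping class label to the ids (or
#'   indices) of that class's training members.
#' @param seed Integer seed.
#' @return Named list of the same shape, each element of the majority size.
#' @export
balance_classes <- function(ids_per_class, seed = 1L) {
  sizes <- vapply(ids_per_class, length, integer(1))
  if (any(sizes == 0)) stop("cannot balance an empty class")
  target <- max(sizes)
  seeds <- derive_seeds(seed, length(ids_per_class))
  out <- ids_per_class
  for (i in seq_along(out)) {
    need <- target - sizes[i]
    if (need > 0) {
      extra <- with_seed(seeds[i],
        sample(ids_per_class[[i]], need, replace = TRUE))
      out[[i]] <- c(ids_per_class[[i]], extra)
    }
  }
  out
}

#' Apply a random dihedral augmentation to a two-channel image
#'
#' Draws one of the eight symmetries of the square restricted to the six
#' label-preserving transforms used here ({identity, rot90, rot180, rot270,
#' horizontal flip, vertical flip}) and applies it identically to both
#' channels. These transforms permute pixels, so they preserve the
#' connected-component structure of the object mask and therefore the truth
#' label.
#'
#' @param img Array `h x w x 2` (or an `mn_cell`).
#' @param seed Integer seed; with `transform` given, no randomness is used.
#' @param transform Optional transform name to apply deterministically.
#' @return The transformed image in the same format.
#' @export
augment_image <- function(img, seed = NULL,
                          transform = NULL) {
  choices <- c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")
  if (is.null(transform))
    transform <- with_seed(seed, sample(choices, 1))
  if (!transform %in% choices) stop("unknown transform: ", transform)
  cell <- inherits(img, "mn_cell")
  if (cell) {
    out <- img
    out$bf <- apply_dihedral(img$bf, transform)
    out$dna <- apply_dihedral(img$dna, transform)
    out$mask <- apply_dihedral(img$mask, transform)
    return(out)
  }
  out <- img
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- apply_dihedral(img[, , ch], transform)
  out
}

apply_dihedral <- function(m, transform) {
  switch(transform,
    identity = m,
    rot90 = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
    rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    rot270 = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
    flip_h = m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v = m[rev(seq_len(nrow(m))), , drop = FALSE])
}
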