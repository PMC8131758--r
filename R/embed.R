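#' Project feature vectors onto a 2D object map
#'
#' Embeds the per-object feature vectors into two dimensions for the
#' interactive object map: pairwise Euclidean distances are computed, a
#' metric (PCoA) configuration initializes a non-metric multidimensional
#' scaling, and the NMDS solution provides the map coordinates. When labels
#' are supplied they are leveraged by shrinking within-class distances
#' before embedding, which pulls objects of the same class together
#' (mildly supervised embedding). Fully seeded and deterministic.
#'
#' @param features Numeric matrix, one row per object.
#' @param labels Optional character labels (NA allowed for unlabeled
#'   objects).
#' @param seed Integer seed.
#' @param supervision_weight Factor in (0, 1] multiplying within-class
#'   distances when labels are given (smaller = stronger supervision).
#' @return Numeric matrix `n x 2` of finite map coordinates.
#' @export
reduce_to_map <- function(features, labels = NULL, seed = 1L,
                          supervision_weight = 0.35) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("at least 2 objects are required for the object map")
  d <- dist(features)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    same <- outer(labels, labels, function(a, b)
      !is.na(a) & !is.na(b) & a == b)
    d <- as.matrix(d)
    d[same] <- d[same] * supervision_weight
    diag(d) <- 0
    d <- stats::as.dist(d)
  }
  # NMDS degenerates when many distances are exactly zero (duplicated
  # feature vectors); a tiny deterministic jitter keeps it well-posed
  dv <- as.vector(d)
  if (any(dv == 0)) {
    eps <- max(dv) * 1e-6 + 1e-12
    d <- d + eps
  }
  coords <- with_seed(seed, {
    init <- cmdscale(d, k = 2)
    if (ncol(init) < 2) init <- cbind(init, 0)
    fit <- try(vegan::monoMDS(d, y = init, k = 2), silent = TRUE)
    if (inherits(fit, "try-error")) init else fit$points
  })
  coords <- unname(as.matrix(coords)[, 1:2, drop = FALSE])
  if (any(!is.finite(coords))) stop("non-finite map coordinates")
  coords
}

#' Over-cluster a segment
#'
#' Groups the objects of a segment into `5 x n_classes` clusters (capped at
#' the number of objects) so that each cluster holds substantially similar
#' images; the over-clustering factor deliberately exceeds the class count
#' so clusters stay pure enough for group assignment to ground truth.
#' k-means with seeded initialization on the feature vectors (or on the 2D
#' map coordinates, via `on`).
#'
#' @param features Numeric matrix, one row per object.
#' @param n_classes Number of model classes (default 6).
#' @param factor_k Over-clustering factor (default 5).
#' @param map_xy Optional `n x 2` coordinates; used when `on = "map"`.
#' @param on Cluster on `"features"` (default) or `"map"`.
#' @param seed Integer seed.
#' @return Integer vector of cluster ids (a partition of the segment).
#' @export
cluster_segment <- function(features, n_classes = 6L, factor_k = 5L,
                            map_xy = NULL, on = c("features", "map"),
                            seed = 1L) {
  on <- match.arg(on)
  x <- if (on == "map") {
    if (is.null(map_xy)) stop("map coordinates required when on = 'map'")
    as.matrix(map_xy)
  } else as.matrix(features)
  n <- nrow(x)
  if (n == 0) stop("empty segment")
  k <- min(factor_k * n_classes, n)
  nuniq <- nrow(unique(x))
  if (k >= nuniq) {
    # each distinct point its own cluster
    ids <- as.integer(factor(apply(x, 1, paste, collapse = "\r")))
    return(ids)
  }
  km <- with_seed(seed, kmeans(x, centers = k, nstart = 5, iter.max = 50))
  as.integer(km$cluster)
}

#' Predict classes for unlabeled segment objects
#'
#' Trains a simple linear model (multinomial logistic regression) on the
#' feature vectors of the ground-truth objects and scores every segment
#' object. Objects whose maximum class posterior falls below
#' `confidence_threshold` do not fit well into any class and are labeled
#' `"UNKNOWN"`. Each trainable class must hold at least `min_per_class`
#' (default 25) ground-truth members before prediction is allowed.
#'
#' @param features Numeric matrix of segment objects (one row per object).
#' @param gt_features Numeric matrix of ground-truth objects.
#' @param gt_labels Character labels of the ground-truth objects; the label
#'   vocabulary (its unique values, or the factor levels if a factor) defines
#'   the trainable classes, all of which must meet the minimum.
#' @param confidence_threshold Posterior below which an object is UNKNOWN
#'   (default 0.5).
#' @param min_per_class Gate on ground-truth class sizes (default 25).
#' @return Data frame with columns `label` (class or `"UNKNOWN"`) and
#'   `confidence` (maximum posterior in `[0, 1]`).
#' @export
predict_segment <- function(features, gt_features, gt_labels,
                            confidence_threshold = 0.5,
                            min_per_class = 25L) {
  features <- as.matrix(features)
  gt_features <- as.matrix(gt_features)
  if (nrow(gt_features) != length(gt_labels))
    stop("one label per ground-truth object is required")
  f <- if (is.factor(gt_labels)) gt_labels else factor(gt_labels)
  counts <- table(f)
  short <- counts < min_per_class
  if (any(short))
    stop("prediction requires a minimum of ", min_per_class,
         " ground-truth images per class; short: ",
         paste(names(counts)[short], collapse = ", "))
  if (nlevels(f) < 2) {
    return(data.frame(label = rep(levels(f), nrow(features)),
                      confidence = rep(1, nrow(features)),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(.y = f, gt_features)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                        maxit = 200, MaxNWts = 100000, decay = 1e-4)
  newdata <- as.data.frame(features)
  colnames(newdata) <- colnames(df)[-1]
  probs <- predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(probs))) {
    # predict() drops to a vector for 2 classes (per-row P(level 2)) and for
    # single-row inputs (per-class probabilities)
    probs <- if (nlevels(f) == 2) cbind(1 - probs, probs)
             else matrix(probs, nrow = 1)
  }
  colnames(probs) <- levels(f)
  conf <- apply(probs, 1, max)
  lab <- levels(f)[max.col(probs, ties.method = "first")]
  lab[conf < confidence_threshold] <- "UNKNOWN"
  data.frame(label = lab, confidence = unname(conf), stringsAsFactors = FALSE)
}

#' Build an object map for a segment
#'
#' Bundles feature extraction, 2D embedding, over-clustering and (when
#' ground truth allows) prediction into the per-segment state shown to the
#' labeler.
#'
#' @param features Feature matrix of the segment objects.
#' @param object_ids Ids of the segment objects.
#' @param gt Optional list of `features` and `labels` for the current ground
#'   truth; when every class has enough members, predictions are added.
#' @param n_classes Number of model classes.
#' @param seed Integer seed.
#' @param confidence_threshold Passed to [predict_segment()].
#' @return An object of class `object_map`: data frame with object_id, map
#'   coordinates, cluster id and (optionally) predicted label/confidence,
#'   with the feature matrix attached as attribute `"features"`.
#' @export
object_map <- function(features, object_ids, gt = NULL, n_classes = 6L,
                       seed = 1L, confidence_threshold = 0.5) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(object_ids))
  seeds <- derive_seeds(seed, 2L)
  labels <- NULL
  if (!is.null(gt) && length(gt$labels)) {
    idx <- match(object_ids, gt$ids)
    labels <- ifelse(is.na(idx), NA_character_, gt$labels[idx])
  }
  xy <- reduce_to_map(features, labels = labels, seed = seeds[1])
  cl <- cluster_segment(features, n_classes = n_classes, seed = seeds[2])
  out <- data.frame(object_id = object_ids, map_x = xy[, 1], map_y = xy[, 2],
                    cluster_id = cl, predicted = NA_character_,
                    confidence = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(gt) && length(gt$labels) &&
      all(table(factor(gt$labels, levels = mn_classes())) >= 25)) {
    pr <- predict_segment(features, gt$features, factor(gt$labels,
                                                        levels = mn_classes()),
                          confidence_threshold = confidence_threshold)
    out$predicted <- pr$label
    out$confidence <- pr$confidence
  }
  attr(out, "features") <- features
  class(out) <- c("object_map", "data.frame")
  out
}

#' Headless assisted-labeling loop
#'
#' Emulates the iterative cluster/predict ground-truth accumulation without
#' a GUI. Starting from a small manually confirmed seed per class, segments
#' are drawn in turn; once every class holds at least `min_per_class`
#' ground-truth members, segment objects are scored by [predict_segment()].
#' High-confidence predictions (`>= auto_accept`) are accepted into the
#' ground truth as-is; the remaining objects are "manually confirmed" by
#' looking up their true label in `truth` (standing in for the human
#' reviewer). The manual-confirmation count measures labeling effort.
#'
#' @param features Feature matrix for the full dataset (rows named or in the
#'   order of `object_ids`).
#' @param object_ids Ids for all objects.
#' @param truth Named character vector: true label per object id (the
#'   reviewer's answer key).
#' @param segment_size Objects per segment.
#' @param seed_per_class Size of the manually confirmed per-class seed.
#' @param auto_accept Confidence at or above which a prediction is accepted
#'   without manual confirmation.
#' @param max_segments Upper bound on segments processed.
#' @param target_total Stop once the ground truth reaches this size (default:
#'   all objects).
#' @param seed Integer seed.
#' @return List with the final `store` (a [gt_store()]), `n_manual` (objects
#'   manually confirmed), `n_total` (objects labeled) and `accuracy`
#'   (fraction of ground-truth labels agreeing with `truth`).
#' @export
assist_label_loop <- function(features, object_ids, truth,
                              segment_size = 1500L, seed_per_class = 30L,
                              auto_accept = 0.9, max_segments = 50L,
                              target_total = length(object_ids), seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(object_ids))
  rownames(features) <- object_ids
  truth <- truth[object_ids]
  assert_class_label(truth)
  seeds <- derive_seeds(seed, max_segments + 1L)
  store <- gt_store()
  n_manual <- 0L
  # seed ground truth: manually confirm a few objects of each class
  cls_present <- intersect(mn_classes(), unique(truth))
  seed_ids <- with_seed(seeds[max_segments + 1L], {
    unlist(lapply(cls_present, function(k) {
      ids <- object_ids[truth == k]
      sample(ids, min(seed_per_class, length(ids)))
    }))
  })
  for (id in seed_ids) store <- assign_ground_truth(store, truth[[id]], id)
  n_manual <- n_manual + length(seed_ids)

  pool <- setdiff(object_ids, seed_ids)
  for (s in seq_len(max_segments)) {
    if (length(pool) == 0 || sum(gt_counts(store)) >= target_total) break
    seg <- make_segment(pool, size = segment_size, seed = seeds[s])
    gl <- gt_labels(store)
    enough <- all(table(factor(gl$label, levels = cls_present)) >= 25)
    if (enough) {
      pr <- predict_segment(features[seg, , drop = FALSE],
                            features[gl$object_id, , drop = FALSE],
                            factor(gl$label, levels = cls_present))
      accept <- pr$label != "UNKNOWN" & pr$confidence >= auto_accept
      for (i in which(accept))
        store <- assign_ground_truth(store, pr$label[i], seg[i])
      for (i in which(!accept)) {
        store <- assign_ground_truth(store, truth[[seg[i]]], seg[i])
        n_manual <- n_manual + 1L
      }
    } else {
      for (id in seg) {
        store <- assign_ground_truth(store, truth[[id]], id)
        n_manual <- n_manual + 1L
      }
    }
    pool <- setdiff(pool, seg)
  }
  gl <- gt_labels(store)
  acc <- mean(gl$label == truth[gl$object_id])
  list(store = store, n_manual = n_manual, n_total = nrow(gl),
       accuracy = acc)
}

#' Serialize / restore an assist session as JSON
#'
#' Captures the resumable state of a headless labeling session: the ground
#' truth store, the current segment ids, map coordinates, cluster ids and
#' predictions.
#'
#' @param session List with elements `store` (a [gt_store()]) and optionally
#'   `map` (an [object_map()] data frame, features excluded).
#' @param path File path.
#' @return `write_assist_session` returns the path invisibly;
#'   `read_assist_session` the session list.
#' @export
write_assist_session <- function(session, path) {
  payload <- list(gt = session$store$classes)
  if (!is.null(session$map)) {
    m <- as.data.frame(session$map)
    attr(m, "features") <- NULL
    payload$map <- m
  }
  jsonlite::write_json(payload, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_assist_session
#' @export
read_assist_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  store <- gt_store()
  for (k in intersect(names(raw$gt), mn_classes()))
    store <- assign_ground_truth(store, k, raw$gt[[k]])
  out <- list(store = store)
  if (!is.null(raw$map)) out$map <- as.data.frame(raw$map)
  out
}
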