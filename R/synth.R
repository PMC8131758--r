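#' Specification of a single synthetic cell
#'
#' Describes the geometry and optics of one rendered cell: number of main
#' nuclei (1 = mononucleated, 2 = binucleated, 3--4 = polynucleated), number
#' of micronuclei (0--2), an irregular-morphology mode, the main-nucleus
#' radius in pixels, the micronucleus diameter as a fraction of the
#' main-nucleus diameter, and the blur/noise applied to the final imagery.
#'
#' Any `irregular_mode` other than `"none"` makes the cell's truth label
#' `IRREG` regardless of nucleus and micronucleus counts. The modes
#' `"overlapping_nuclei"`, `"size_mismatch"` and `"intensity_mismatch"`
#' require at least two nuclei.
#'
#' @param n_nuclei Integer 1--4.
#' @param n_mn Integer >= 0 (conventionally 0--2).
#' @param irregular_mode `"none"` or one of [irregular_modes()].
#' @param nucleus_radius Main-nucleus radius in pixels.
#' @param mn_diameter_ratio Micronucleus diameter as a fraction of the
#'   main-nucleus diameter; must lie strictly inside (0, 1).
#' @param intensity Peak DNA-channel intensity of the main nuclei, in (0, 1].
#' @param blur_sigma Gaussian blur applied to both channels, pixels.
#' @param noise_sd Additive Gaussian noise SD as a fraction of full scale.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(n_nuclei, n_mn = 0L, irregular_mode = "none",
                      nucleus_radius = 10, mn_diameter_ratio = 0.25,
                      intensity = 0.85, blur_sigma = 0.8, noise_sd = 0.03) {
  n_nuclei <- as.integer(n_nuclei)
  n_mn <- as.integer(n_mn)
  if (n_nuclei < 1L || n_nuclei > 4L) stop("n_nuclei must be in 1..4")
  if (n_mn < 0L) stop("n_mn must be >= 0")
  if (!irregular_mode %in% c("none", irregular_modes()))
    stop("unknown irregular_mode: ", irregular_mode)
  if (irregular_mode %in% c("overlapping_nuclei", "size_mismatch",
                            "intensity_mismatch") && n_nuclei < 2L)
    stop("irregular_mode '", irregular_mode, "' requires n_nuclei >= 2")
  if (mn_diameter_ratio <= 0 || mn_diameter_ratio >= 1)
    stop("mn_diameter_ratio must be strictly inside (0, 1)")
  structure(list(n_nuclei = n_nuclei, n_mn = n_mn,
                 irregular_mode = irregular_mode,
                 nucleus_radius = nucleus_radius,
                 mn_diameter_ratio = mn_diameter_ratio,
                 intensity = intensity,
                 blur_sigma = blur_sigma, noise_sd = noise_sd),
            class = "cell_spec")
}

# antialiased filled disk on an h x w pixel grid (pixel centers at 1..h)
disk_field <- function(h, w, cx, cy, r) {
  dx <- matrix(seq_len(h) - cy, h, w)
  dy <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  d <- sqrt(dx^2 + dy^2)
  pmin(pmax(r - d + 0.5, 0), 1)
}

# antialiased filled ellipse, semi-axes a >= b, rotated by theta
ellipse_field <- function(h, w, cx, cy, a, b, theta) {
  dx <- matrix(seq_len(h) - cy, h, w)
  dy <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  d <- sqrt((u / a)^2 + (v / b)^2)
  pmin(pmax((1 - d) * b + 0.5, 0), 1)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  pad <- function(x, n) x[c(rep(1L, n), seq_len(length(x)), rep(length(x), n))]
  # rows
  mp <- m[c(rep(1L, rad), seq_len(h), rep(h, rad)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + h - 1L), , drop = FALSE]
  # cols
  mp <- out[, c(rep(1L, rad), seq_len(w), rep(w, rad)), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * mp[, i:(i + w - 1L), drop = FALSE]
  out2
}

# rejection-sample a point in a disk subject to a predicate
place_point <- function(center, radius, ok, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    ang <- runif(1, 0, 2 * pi)
    rr <- radius * sqrt(runif(1))
    p <- c(center[1] + rr * cos(ang), center[2] + rr * sin(ang))
    if (ok(p)) return(p)
  }
  stop("placement error: could not place object within image bounds after ",
       max_attempts, " attempts")
}

#' Render one synthetic two-channel cell image
#'
#' Draws a cytoplasm disk on the brightfield channel and the main nuclei plus
#' micronuclei on the DNA channel, then applies Gaussian blur and additive
#' Gaussian sensor noise to both channels. The noiseless DNA image,
#' thresholded at `mask_threshold`, yields a binary mask whose
#' connected-component count equals `n_nuclei + n_mn` (except that
#' `overlapping_nuclei` cells may merge nucleus components; such cells are
#' `IRREG` by construction).
#'
#' @param spec A [cell_spec()].
#' @param image_size Side of the square image in pixels.
#' @param seed Integer seed controlling all randomness of this render.
#' @param mask_threshold Threshold applied to the noiseless DNA image to
#'   define the object mask.
#' @param mn_touching If `TRUE`, micronuclei are allowed to touch the main
#'   nuclei (emulating MN residing very close to a nucleus); by default a
#'   clearance of 2 px is enforced so each MN is a distinct component.
#' @return An object of class `mn_cell`: a list with matrices `bf`, `dna`
#'   (both in `[0, 1]`), the logical noiseless `mask`, `truth_label` and the
#'   originating `spec`.
#' @export
render_cell <- function(spec, image_size = 64L, seed = NULL,
                        mask_threshold = 0.2, mn_touching = FALSE) {
  stopifnot(inherits(spec, "cell_spec"))
  with_seed(seed, {
    h <- w <- as.integer(image_size)
    ctr <- c(w, h) / 2 + 0.5
    nr <- spec$nucleus_radius * c(1, 0.85, 0.72, 0.62)[spec$n_nuclei]
    cyto_r <- runif(1, 0.38, 0.45) * image_size
    if (cyto_r + 2 > image_size / 2)
      cyto_r <- image_size / 2 - 2
    if (nr + 6 >= cyto_r)
      stop("placement error: nucleus radius too large for image size")

    n <- spec$n_nuclei
    radii <- rep(nr, n)
    intens <- rep(spec$intensity, n)
    if (spec$irregular_mode == "size_mismatch")
      radii[sample(n, 1)] <- nr * runif(1, 0.40, 0.55)
    if (spec$irregular_mode == "intensity_mismatch")
      intens[sample(n, 1)] <- spec$intensity * runif(1, 0.30, 0.50)

    # ellipse shape parameters for irregularly shaped nuclei, with the major
    # axis capped so the nucleus stays inside the cytoplasm
    shape <- NULL
    extents <- radii
    if (spec$irregular_mode == "shape_irregular") {
      ratio <- runif(n, 2.2, 3.0)
      theta <- runif(n, 0, pi)
      a <- radii * sqrt(ratio)
      over <- a > cyto_r - 5
      if (any(over)) {
        radii[over] <- radii[over] * (cyto_r - 5) / a[over]
        a[over] <- cyto_r - 5
      }
      shape <- list(ratio = ratio, theta = theta, a = a,
                    b = radii / sqrt(ratio))
      extents <- a
    }

    gap <- 2
    centers <- matrix(NA_real_, n, 2)
    if (n == 1L) {
      centers[1, ] <- place_point(ctr, max(0, cyto_r - extents[1] - 3),
                                  function(p) TRUE)
    } else if (spec$irregular_mode == "overlapping_nuclei") {
      centers[1, ] <- place_point(ctr, max(0, cyto_r - radii[1] - 5),
                                  function(p) TRUE)
      for (i in 2:n) {
        base <- centers[i - 1, ]
        d <- runif(1, 0.6, 1.2) * (radii[i - 1] + radii[i]) / 2
        ang <- runif(1, 0, 2 * pi)
        p <- base + d * c(cos(ang), sin(ang))
        while (sqrt(sum((p - ctr)^2)) + radii[i] + 2 > cyto_r)
          p <- ctr + (p - ctr) * 0.8
        centers[i, ] <- p
      }
    } else {
      # jittered ring layout: robust non-overlapping placement of 2-4 nuclei.
      # separation uses the circle-equivalent radius; containment uses the
      # full extent (ellipse major axis for irregular shapes)
      sn <- sin(pi / n)
      ring_bounds <- function() c(
        min = (max(radii) + gap / 2) / sn,
        max = cyto_r - max(extents) - 2)
      rb <- ring_bounds()
      if (rb["min"] > rb["max"]) {
        scl <- (cyto_r - 2 - (gap / 2) / sn) /
          (max(radii) / sn + max(extents))
        if (scl <= 0.3)
          stop("placement error: nuclei cannot be placed within image bounds")
        radii <- radii * scl
        extents <- extents * scl
        if (!is.null(shape)) { shape$a <- shape$a * scl; shape$b <- shape$b * scl }
        rb <- ring_bounds()
      }
      ring_min <- rb[["min"]]
      ring_max <- max(rb[["max"]], ring_min)
      ring <- runif(1, ring_min, ring_max)
      base_ang <- runif(1, 0, 2 * pi)
      jit <- runif(n, -0.12, 0.12)
      angs <- base_ang + 2 * pi * (seq_len(n) - 1) / n + jit
      centers <- cbind(ctr[1] + ring * cos(angs), ctr[2] + ring * sin(angs))
    }

    mn_r <- pmax(0.8, spec$mn_diameter_ratio * nr)
    mn_gap <- if (mn_touching) -0.5 else 2
    mn_centers <- matrix(NA_real_, spec$n_mn, 2)
    if (spec$n_mn > 0) {
      for (i in seq_len(spec$n_mn)) {
        mn_centers[i, ] <- place_point(ctr, cyto_r - mn_r - 2, function(p) {
          dd <- sqrt(rowSums((centers - matrix(p, n, 2, byrow = TRUE))^2))
          if (any(dd < extents + mn_r + mn_gap)) return(FALSE)
          if (i > 1) {
            d2 <- sqrt(rowSums((mn_centers[seq_len(i - 1), , drop = FALSE] -
                                  matrix(p, i - 1, 2, byrow = TRUE))^2))
            if (any(d2 < 2 * mn_r + 2)) return(FALSE)
          }
          TRUE
        })
      }
      # snap MN centers to pixel centers so tiny MN still cover >= 1 pixel
      mn_centers <- round(mn_centers)
    }

    dna <- matrix(0, h, w)
    for (i in seq_len(n)) {
      f <- if (spec$irregular_mode == "shape_irregular") {
        ellipse_field(h, w, centers[i, 1], centers[i, 2],
                      shape$a[i], shape$b[i], shape$theta[i])
      } else {
        disk_field(h, w, centers[i, 1], centers[i, 2], radii[i])
      }
      dna <- pmax(dna, intens[i] * f)
    }
    mn_int <- spec$intensity * runif(max(spec$n_mn, 1), 0.85, 1.0)
    for (i in seq_len(spec$n_mn)) {
      f <- disk_field(h, w, mn_centers[i, 1], mn_centers[i, 2], mn_r)
      f[mn_centers[i, 2], mn_centers[i, 1]] <- 1  # guarantee a core pixel
      dna <- pmax(dna, mn_int[i] * f)
    }
    mask <- dna > mask_threshold

    cyto <- disk_field(h, w, ctr[1], ctr[2], cyto_r)
    bf <- 0.10 + 0.40 * cyto - 0.18 * dna

    dna_out <- gaussian_blur(dna, spec$blur_sigma)
    bf_out <- gaussian_blur(bf, spec$blur_sigma)
    if (spec$noise_sd > 0) {
      dna_out <- dna_out + rnorm(h * w, 0, spec$noise_sd)
      bf_out <- bf_out + rnorm(h * w, 0, spec$noise_sd)
    }
    structure(list(bf = pmin(pmax(bf_out, 0), 1),
                   dna = pmin(pmax(dna_out, 0), 1),
                   mask = mask,
                   truth_label = label_from_geometry(spec$n_nuclei, spec$n_mn,
                                                     spec$irregular_mode),
                   spec = spec),
              class = "mn_cell")
  })
}

#' Configuration for a labeled synthetic dataset
#'
#' @param n_objects Number of cells to generate.
#' @param class_mixture Named probability vector over [mn_classes()]
#'   (non-negative, summing to 1). Default: uniform over the six classes.
#' @param image_size Square image side, pixels.
#' @param nucleus_radius Range (min, max) of the main-nucleus radius, px.
#' @param mn_diameter_ratio Range of the MN diameter as a fraction of the
#'   main-nucleus diameter; the default `c(1/16, 1/3)` follows the standard
#'   microscopy scoring convention for MN size.
#' @param intensity Range of peak nuclear DNA intensity.
#' @param blur_sigma Range of the Gaussian blur sigma, px.
#' @param noise_sd Range of the additive noise SD.
#' @param mask_threshold DNA threshold defining the noiseless object mask.
#' @param mn_touching Allow MN to touch main nuclei.
#' @param difficulty `"default"` or `"easy"`. The easy preset uses
#'   well-separated geometry (larger MN, mild blur, low noise) and is the
#'   regime used for classifier-recovery benchmarks.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_objects, class_mixture = NULL, image_size = 64L,
                         nucleus_radius = c(8, 12),
                         mn_diameter_ratio = c(1 / 16, 1 / 3),
                         intensity = c(0.75, 0.95),
                         blur_sigma = c(0.6, 1.2),
                         noise_sd = c(0.02, 0.06),
                         mask_threshold = 0.2,
                         mn_touching = FALSE,
                         difficulty = c("default", "easy"),
                         seed = 1L) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "easy") {
    if (missing(mn_diameter_ratio)) mn_diameter_ratio <- c(0.20, 1 / 3)
    if (missing(blur_sigma)) blur_sigma <- c(0.4, 0.8)
    if (missing(noise_sd)) noise_sd <- c(0.01, 0.03)
  }
  if (is.null(class_mixture)) {
    class_mixture <- rep(1 / 6, 6)
    names(class_mixture) <- mn_classes()
  }
  if (is.null(names(class_mixture)) ||
      !setequal(names(class_mixture), mn_classes()))
    stop("class_mixture must be named with the six class labels")
  class_mixture <- class_mixture[mn_classes()]
  if (any(class_mixture < 0) || abs(sum(class_mixture) - 1) > 1e-9)
    stop("class_mixture entries must be >= 0 and sum to 1")
  if (image_size < 4 * max(nucleus_radius))
    stop("image_size too small for the configured nucleus radius")
  structure(list(n_objects = as.integer(n_objects),
                 class_mixture = class_mixture,
                 image_size = as.integer(image_size),
                 nucleus_radius = nucleus_radius,
                 mn_diameter_ratio = mn_diameter_ratio,
                 intensity = intensity, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, mask_threshold = mask_threshold,
                 mn_touching = mn_touching, difficulty = difficulty,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# draw a cell_spec consistent with a given truth label
sample_spec_for_label <- function(label, cfg) {
  ru <- function(rg) runif(1, rg[1], rg[2])
  n_mn <- 0L
  irr <- "none"
  n <- switch(label,
    MONO = 1L, MONO_MN = 1L, BN = 2L, BN_MN = 2L,
    POLY = sample(3:4, 1, prob = c(0.6, 0.4)),
    IRREG = NA_integer_)
  if (label %in% c("MONO_MN", "BN_MN"))
    n_mn <- sample(1:2, 1, prob = c(0.8, 0.2))
  if (label == "IRREG") {
    irr <- sample(irregular_modes(), 1)
    n <- if (irr == "shape_irregular") sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
         else sample(2:3, 1, prob = c(0.8, 0.2))
  }
  cell_spec(n_nuclei = n, n_mn = n_mn, irregular_mode = irr,
            nucleus_radius = ru(cfg$nucleus_radius),
            mn_diameter_ratio = ru(cfg$mn_diameter_ratio),
            intensity = ru(cfg$intensity),
            blur_sigma = ru(cfg$blur_sigma),
            noise_sd = ru(cfg$noise_sd))
}

#' Generate a labeled synthetic dataset
#'
#' Samples truth labels from the configured class mixture, renders each cell,
#' and returns an in-memory dataset with a manifest. The same configuration
#' and seed always reproduce the identical dataset, pixels included.
#'
#' @param config A [synth_config()].
#' @param file_id File identifier recorded in the manifest.
#' @param keep_masks Keep the per-object noiseless DNA masks (used by
#'   rendering invariant checks).
#' @return An object of class `mn_dataset`: list with `images` (array
#'   `h x w x 2 x n`, channel 1 = brightfield, channel 2 = DNA), `manifest`
#'   (data.frame: object_id, file_id, dose, replicate, truth_label),
#'   optionally `masks`, and the `config`.
#' @export
generate_labeled_dataset <- function(config, file_id = "synth",
                                     keep_masks = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_objects
  seeds <- derive_seeds(config$seed, n + 1L)
  labels <- with_seed(seeds[n + 1L],
    sample(mn_classes(), n, replace = TRUE, prob = config$class_mixture))
  sz <- config$image_size
  images <- array(0, c(sz, sz, 2L, n))
  masks <- if (keep_masks) array(FALSE, c(sz, sz, n)) else NULL
  for (i in seq_len(n)) {
    spec <- with_seed(seeds[i], sample_spec_for_label(labels[i], config))
    cell <- render_cell(spec, image_size = sz, seed = seeds[i] %% 2147483646L + 1L,
                        mask_threshold = config$mask_threshold,
                        mn_touching = config$mn_touching)
    images[, , 1L, i] <- cell$bf
    images[, , 2L, i] <- cell$dna
    if (keep_masks) masks[, , i] <- cell$mask
  }
  manifest <- data.frame(
    object_id = sprintf("%s_%06d", file_id, seq_len(n)),
    file_id = file_id, dose = NA_character_, replicate = NA_integer_,
    truth_label = labels, stringsAsFactors = FALSE)
  structure(list(images = images, manifest = manifest, masks = masks,
                 config = config),
            class = "mn_dataset")
}

#' @export
print.mn_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("mn_dataset: %d objects, %dx%d px, 2 channels\n", d[4], d[1], d[2]))
  print(table(x$manifest$truth_label))
  invisible(x)
}

#' Configuration for a synthetic dose-response cohort
#'
#' Describes a whole experiment: an ordered set of dose levels (the first is
#' the solvent control by default), the per-dose probability that a scorable
#' cell carries at least one micronucleus, the per-dose proliferation state,
#' and the file structure (replicate cultures x data files x events).
#'
#' In `"cytb"` (cytokinesis-block) mode `prolif_mix_per_dose` gives the
#' per-dose MONO/BN/POLY mixture among scorable cells and micronuclei are
#' induced in BN cells. In `"non_cytb"` mode cells are predominantly
#' mononucleated, micronuclei are induced in MONO cells, and
#' `relative_count_per_dose` carries the post-recovery cell count relative to
#' control used for cytotoxicity.
#'
#' @param doses Character vector of dose labels; `control` names the solvent
#'   control (default: the first dose).
#' @param mn_probability_per_dose Numeric in `[0, 1]`, one per dose.
#' @param mode `"cytb"` or `"non_cytb"`.
#' @param prolif_mix_per_dose Matrix (doses x 3, columns MONO/BN/POLY), rows
#'   summing to 1. Ignored in non-Cyt-B mode.
#' @param relative_count_per_dose Relative post-recovery cell counts
#'   (control = 1). Ignored in Cyt-B mode.
#' @param irregular_fraction Fraction of events with irregular morphology
#'   (excluded from scoring).
#' @param replicates_per_dose,files_per_replicate,events_per_file File
#'   structure counts.
#' @param control Label of the solvent control dose.
#' @param image Optional [synth_config()]-like rendering settings used when
#'   images are rendered; only its geometry/noise ranges are used.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
dose_response_config <- function(doses,
                                 mn_probability_per_dose,
                                 mode = c("cytb", "non_cytb"),
                                 prolif_mix_per_dose = NULL,
                                 relative_count_per_dose = NULL,
                                 irregular_fraction = 0.05,
                                 replicates_per_dose = 2L,
                                 files_per_replicate = 3L,
                                 events_per_file = 15000L,
                                 control = doses[1],
                                 image = synth_config(1L),
                                 seed = 1L) {
  mode <- match.arg(mode)
  nd <- length(doses)
  if (length(mn_probability_per_dose) != nd)
    stop("mn_probability_per_dose must have one entry per dose")
  if (any(mn_probability_per_dose < 0 | mn_probability_per_dose > 1))
    stop("mn probabilities must be in [0, 1]")
  if (!control %in% doses) stop("control dose not among doses")
  if (events_per_file <= 0) stop("events_per_file must be > 0")
  if (mode == "cytb") {
    if (is.null(prolif_mix_per_dose))
      prolif_mix_per_dose <- matrix(rep(c(0.40, 0.45, 0.15), nd), nd, 3,
                                    byrow = TRUE)
    if (!all(dim(prolif_mix_per_dose) == c(nd, 3)))
      stop("prolif_mix_per_dose must be doses x 3 (MONO, BN, POLY)")
    if (any(prolif_mix_per_dose < 0) ||
        any(abs(rowSums(prolif_mix_per_dose) - 1) > 1e-9))
      stop("proliferation mixtures must be >= 0 and sum to 1 per dose")
    colnames(prolif_mix_per_dose) <- c("MONO", "BN", "POLY")
  } else {
    if (is.null(relative_count_per_dose)) relative_count_per_dose <- rep(1, nd)
    if (length(relative_count_per_dose) != nd)
      stop("relative_count_per_dose must have one entry per dose")
    prolif_mix_per_dose <- matrix(rep(c(0.96, 0.03, 0.01), nd), nd, 3,
                                  byrow = TRUE,
                                  dimnames = list(NULL, c("MONO", "BN", "POLY")))
  }
  structure(list(doses = doses, mn_probability_per_dose = mn_probability_per_dose,
                 mode = mode, prolif_mix_per_dose = prolif_mix_per_dose,
                 relative_count_per_dose = relative_count_per_dose,
                 irregular_fraction = irregular_fraction,
                 replicates_per_dose = as.integer(replicates_per_dose),
                 files_per_replicate = as.integer(files_per_replicate),
                 events_per_file = as.integer(events_per_file),
                 control = control, image = image, seed = as.integer(seed)),
            class = "cohort_config")
}

# sample truth labels for one data file of a cohort
sample_file_labels <- function(cfg, dose_idx, n) {
  irr <- runif(n) < cfg$irregular_fraction
  mix <- cfg$prolif_mix_per_dose[dose_idx, ]
  base <- sample(c("MONO", "BN", "POLY"), n, replace = TRUE, prob = mix)
  p_mn <- cfg$mn_probability_per_dose[dose_idx]
  target <- if (cfg$mode == "cytb") "BN" else "MONO"
  has_mn <- runif(n) < p_mn & base == target
  lab <- base
  lab[has_mn] <- paste0(base[has_mn], "_MN")
  lab[irr] <- "IRREG"
  lab
}

#' Generate a synthetic dose-response cohort
#'
#' Produces per-dose, per-replicate data files of synthetic events with known
#' truth labels. With `render = "counts"` only the manifest (truth labels and
#' file structure) is generated, which is sufficient for exercising the assay
#' statistics at full file sizes; with `render = "images"` every event is
#' rendered and written as a multi-page TIFF per data file alongside a
#' manifest CSV (layout `out_dir/<dose>/rep<k>/`).
#'
#' @param config A [dose_response_config()].
#' @param out_dir Output directory (required when `render = "images"`).
#' @param render `"counts"` or `"images"`.
#' @return Invisibly, a list with `manifest` (all events, with dose,
#'   replicate, file and truth label) and `relative_counts` (non-Cyt-B
#'   cytotoxicity input, per dose).
#' @export
generate_dose_response_cohort <- function(config, out_dir = NULL,
                                          render = c("counts", "images")) {
  stopifnot(inherits(config, "cohort_config"))
  render <- match.arg(render)
  if (render == "images" && is.null(out_dir))
    stop("out_dir is required when rendering images")
  nd <- length(config$doses)
  n_files <- nd * config$replicates_per_dose * config$files_per_replicate
  seeds <- derive_seeds(config$seed, n_files)
  rows <- list()
  fi <- 0L
  for (d in seq_len(nd)) {
    for (r in seq_len(config$replicates_per_dose)) {
      for (f in seq_len(config$files_per_replicate)) {
        fi <- fi + 1L
        file_id <- sprintf("%s_rep%d_file%d", config$doses[d], r, f)
        labels <- with_seed(seeds[fi],
          sample_file_labels(config, d, config$events_per_file))
        man <- data.frame(
          object_id = sprintf("%s_%06d", file_id, seq_along(labels)),
          file_id = file_id, dose = config$doses[d], replicate = r,
          truth_label = labels, stringsAsFactors = FALSE)
        if (render == "images") {
          img_cfg <- config$image
          img_cfg$n_objects <- length(labels)
          dir <- file.path(out_dir, config$doses[d], sprintf("rep%d", r))
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          ds <- render_labels_to_dataset(labels, img_cfg, seeds[fi], file_id)
          ds$manifest$dose <- config$doses[d]
          ds$manifest$replicate <- r
          write_dataset(ds, dir, basename = sprintf("file%d", f))
          man <- ds$manifest
        }
        rows[[fi]] <- man
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rel <- config$relative_count_per_dose
  if (!is.null(rel)) names(rel) <- config$doses
  invisible(structure(list(manifest = manifest, relative_counts = rel,
                           config = config),
                      class = "mn_cohort"))
}

# render a fixed label sequence (used by cohort generation)
render_labels_to_dataset <- function(labels, cfg, seed, file_id) {
  n <- length(labels)
  seeds <- derive_seeds(seed, n)
  sz <- cfg$image_size
  images <- array(0, c(sz, sz, 2L, n))
  for (i in seq_len(n)) {
    spec <- with_seed(seeds[i], sample_spec_for_label(labels[i], cfg))
    cell <- render_cell(spec, image_size = sz,
                        seed = seeds[i] %% 2147483646L + 1L,
                        mask_threshold = cfg$mask_threshold,
                        mn_touching = cfg$mn_touching)
    images[, , 1L, i] <- cell$bf
    images[, , 2L, i] <- cell$dna
  }
  manifest <- data.frame(
    object_id = sprintf("%s_%06d", file_id, seq_len(n)),
    file_id = file_id, dose = NA_character_, replicate = NA_integer_,
    truth_label = labels, stringsAsFactors = FALSE)
  structure(list(images = images, manifest = manifest, masks = NULL,
                 config = cfg),
            class = "mn_dataset")
}

#' Write a dataset as multi-page TIFF plus manifest CSV
#'
#' Each data file becomes one multi-page TIFF with two pages per object
#' (brightfield page first, DNA page second, in manifest order) and a
#' `*_manifest.csv` with columns object_id, file_id, dose, replicate,
#' truth_label.
#'
#' @param dataset An `mn_dataset`.
#' @param dir Output directory.
#' @param basename File stem (default: the dataset's file_id).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, basename = NULL) {
  stopifnot(inherits(dataset, "mn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(basename)) basename <- dataset$manifest$file_id[1]
  n <- dim(dataset$images)[4]
  pages <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    pages[[2L * i - 1L]] <- dataset$images[, , 1L, i]
    pages[[2L * i]] <- dataset$images[, , 2L, i]
  }
  tif <- file.path(dir, paste0(basename, ".tiff"))
  csv <- file.path(dir, paste0(basename, "_manifest.csv"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L, compression = "deflate")
  write.csv(dataset$manifest, csv, row.names = FALSE)
  invisible(c(tiff = tif, manifest = csv))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param tif Path to the multi-page TIFF.
#' @param manifest Path to the manifest CSV (default: derived from `tif`).
#' @return An `mn_dataset` (pixel values as stored; 16-bit TIFFs come back in
#'   `[0, 1]`).
#' @export
read_dataset <- function(tif, manifest = NULL) {
  if (is.null(manifest))
    manifest <- sub("\\.tiff?$", "_manifest.csv", tif)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  n <- nrow(man)
  if (length(pages) != 2L * n)
    stop("TIFF page count does not match manifest (expected 2 per object)")
  sz <- dim(pages[[1]])
  images <- array(0, c(sz[1], sz[2], 2L, n))
  for (i in seq_len(n)) {
    images[, , 1L, i] <- pages[[2L * i - 1L]]
    images[, , 2L, i] <- pages[[2L * i]]
  }
  structure(list(images = images, manifest = man, masks = NULL, config = NULL),
            class = "mn_dataset")
}
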