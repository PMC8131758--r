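#' Score one data file from per-object class predictions
#'
#' Tallies the six classes plus `UNKNOWN` for one data file and derives the
#' assay frequencies. Cells with irregular morphology and unknown
#' predictions must be excluded from scoring, so they never enter any
#' denominator; the scorable cells are MONO, MONO_MN, BN, BN_MN and POLY.
#'
#' Derived quantities (percent):
#' \itemize{
#'   \item `pct_mn_bn`   = 100 BN_MN / (BN + BN_MN) — the Cyt-B genotoxicity
#'     endpoint;
#'   \item `pct_mn_mono` = 100 MONO_MN / (MONO + MONO_MN) — the non-Cyt-B
#'     endpoint;
#'   \item `pct_bn`      = percentage of BN (+BN_MN) cells among scorable
#'     cells.
#' }
#'
#' A QC flag records whether the file reaches the configured minimum of
#' scored BN cells (default 1000 per culture, per the guideline).
#'
#' @param predictions Character vector of predicted labels for one file
#'   (six classes or `"UNKNOWN"`), or a data frame with a `label` column.
#' @param file_id,dose,replicate Metadata recorded in the score.
#' @param min_bn QC minimum for BN + BN_MN (default 1000).
#' @return An object of class `sample_score` (one-row data frame with counts
#'   and derived frequencies).
#' @export
score_sample <- function(predictions, file_id = "file", dose = NA_character_,
                         replicate = NA_integer_, min_bn = 1000L) {
  if (is.data.frame(predictions)) predictions <- predictions$label
  if (length(predictions) == 0) stop("empty file: nothing to score")
  assert_class_label(predictions, allow_unknown = TRUE)
  counts <- table(factor(predictions, levels = c(mn_classes(), "UNKNOWN")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  bn_tot <- counts[["BN"]] + counts[["BN_MN"]]
  mono_tot <- counts[["MONO"]] + counts[["MONO_MN"]]
  scorable <- mono_tot + bn_tot + counts[["POLY"]]
  out <- data.frame(
    file_id = file_id, dose = dose, replicate = replicate,
    n_MONO = counts[["MONO"]], n_MONO_MN = counts[["MONO_MN"]],
    n_BN = counts[["BN"]], n_BN_MN = counts[["BN_MN"]],
    n_POLY = counts[["POLY"]], n_IRREG = counts[["IRREG"]],
    n_UNKNOWN = counts[["UNKNOWN"]], n_scorable = scorable,
    pct_mn_bn = if (bn_tot > 0) 100 * counts[["BN_MN"]] / bn_tot else NA_real_,
    pct_mn_mono = if (mono_tot > 0) 100 * counts[["MONO_MN"]] / mono_tot
                  else NA_real_,
    pct_bn = if (scorable > 0) 100 * bn_tot / scorable else NA_real_,
    qc_pass = bn_tot >= min_bn,
    stringsAsFactors = FALSE)
  class(out) <- c("sample_score", "data.frame")
  out
}

#' CBPI and cytostasis (Cyt-B cytotoxicity)
#'
#' The cytokinesis-block proliferation index of a culture counted into
#' mononucleated, binucleated and polynucleated cells is
#' `CBPI = (N_mono + 2 N_bn + 3 N_poly) / N_total`, bounded in `[1, 3]`.
#' Cytotoxicity (percent cytostasis) of a treated culture against its
#' control is `100 - 100 (CBPI_T - 1) / (CBPI_C - 1)`; it is negative when
#' the treated culture proliferates faster than the control. The result is
#' flagged when it exceeds the upper edge (60%) of the recommended
#' 55 +/- 5% top-dose cytotoxicity band.
#'
#' @param treated,control Numeric length-3 vectors of MONO/BN/POLY counts
#'   (micronucleated cells are pooled into their nucleus-count class before
#'   calling, e.g. BN + BN_MN).
#' @return An object of class `cytotox_result`: list with `mode = "cbpi"`,
#'   `cbpi_treated`, `cbpi_control`, `cytotoxicity` (percent) and
#'   `exceeds_limit`.
#' @export
cytostasis_cbpi <- function(treated, control) {
  stopifnot(length(treated) == 3, length(control) == 3)
  if (any(treated < 0) || any(control < 0)) stop("counts must be >= 0")
  if (sum(treated) == 0 || sum(control) == 0)
    stop("totals must be > 0")
  cbpi <- function(x) sum(x * 1:3) / sum(x)
  ct <- cbpi(treated)
  cc <- cbpi(control)
  if (cc <= 1)
    stop("CBPI of the control equals 1 (all mononucleated): cytostasis undefined")
  cyto <- 100 - 100 * (ct - 1) / (cc - 1)
  structure(list(mode = "cbpi", cbpi_treated = ct, cbpi_control = cc,
                 cytotoxicity = cyto, exceeds_limit = cyto > 60),
            class = "cytotox_result")
}

#' Relative-count cytotoxicity (non-Cyt-B)
#'
#' In the unblocked assay, cytotoxicity is taken from post-recovery cell
#' counts: `100 (1 - treated / control)`. Negative values (treated culture
#' outgrowing the control) are permitted.
#'
#' @param treated,control Post-recovery cell counts (control > 0).
#' @return An object of class `cytotox_result` with `mode =
#'   "relative_count"`.
#' @export
relative_count_cytotoxicity <- function(treated, control) {
  if (length(treated) != 1 || length(control) != 1)
    stop("scalar counts expected")
  if (control <= 0) stop("control count must be > 0")
  cyto <- 100 * (1 - treated / control)
  structure(list(mode = "relative_count", cytotoxicity = cyto,
                 exceeds_limit = cyto > 60),
            class = "cytotox_result")
}

#' @export
print.cytotox_result <- function(x, ...) {
  cat(sprintf("cytotoxicity (%s): %.1f%%%s\n", x$mode, x$cytotoxicity,
              if (x$exceeds_limit) " [exceeds 55+/-5% band]" else ""))
  invisible(x)
}

#' One-sided Fisher exact test for MN induction
#'
#' Tests whether the dosed group carries more MN-bearing cells than the
#' control, conditional on the margins of the 2x2 table: the p-value is the
#' exact upper hypergeometric tail probability of observing at least
#' `mn_dosed` MN-bearing cells among the dosed cells. No normal
#' approximation is used.
#'
#' @param mn_dosed,n_dosed MN-bearing count and total scorable cells in the
#'   dosed group.
#' @param mn_control,n_control Same for the solvent control.
#' @return Exact one-sided p-value.
#' @export
fisher_exact_one_sided <- function(mn_dosed, n_dosed, mn_control, n_control) {
  counts <- c(mn_dosed, n_dosed, mn_control, n_control)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_dosed == 0 || n_control == 0) stop("degenerate margins (n = 0)")
  if (mn_dosed > n_dosed || mn_control > n_control)
    stop("mn count exceeds group size")
  m <- mn_dosed + mn_control         # total successes in the population
  # P(X >= mn_dosed), X ~ Hypergeom(successes m, failures n_d+n_c-m, draws n_d)
  phyper(mn_dosed - 1, m, n_dosed + n_control - m, n_dosed,
         lower.tail = FALSE)
}

#' Dose-response genotoxicity analysis
#'
#' Summarizes per-file scores by dose: mean and sample SD of the MN
#' frequency across a dose's replicate data files, plus a one-sided Fisher
#' exact test of each dose against the solvent control on cell counts
#' pooled across the dose's files (pooling keeps the test exact and uses
#' all scored cells; per-file testing is available via `pool = FALSE`,
#' which takes the maximum per-file p, i.e. every file must reach
#' significance).
#'
#' @param scores A data frame of [score_sample()] rows (one per data file).
#' @param control Dose label of the solvent control.
#' @param endpoint `"mn_bn"` (Cyt-B) or `"mn_mono"` (non-Cyt-B).
#' @param alpha Significance level (default 0.001).
#' @param pool Pool counts across a dose's files before testing (default).
#' @return An object of class `genotox_result`: data frame with one row per
#'   dose (control first) carrying `n_files`, `mean_mn_pct`, `sd_mn_pct`,
#'   `p_value` and `significant`.
#' @export
dose_response_analysis <- function(scores, control, endpoint = c("mn_bn",
                                   "mn_mono"), alpha = 0.001, pool = TRUE) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.data.frame(scores))
  if (!control %in% scores$dose)
    stop("control dose '", control, "' not present in scores")
  mn_col <- if (endpoint == "mn_bn") "n_BN_MN" else "n_MONO_MN"
  base_col <- if (endpoint == "mn_bn") "n_BN" else "n_MONO"
  pct_col <- if (endpoint == "mn_bn") "pct_mn_bn" else "pct_mn_mono"
  doses <- unique(c(control, scores$dose))
  pooled <- function(d) {
    sub <- scores[scores$dose == d, ]
    c(mn = sum(sub[[mn_col]]), n = sum(sub[[mn_col]]) + sum(sub[[base_col]]))
  }
  ctl <- pooled(control)
  rows <- lapply(doses, function(d) {
    sub <- scores[scores$dose == d, ]
    mn_pct <- sub[[pct_col]]
    if (d == control) {
      p <- NA_real_
    } else if (pool) {
      dd <- pooled(d)
      p <- fisher_exact_one_sided(dd["mn"], dd["n"], ctl["mn"], ctl["n"])
    } else {
      p <- max(vapply(seq_len(nrow(sub)), function(i) {
        mn <- sub[[mn_col]][i]
        n <- mn + sub[[base_col]][i]
        fisher_exact_one_sided(mn, n, ctl["mn"], ctl["n"])
      }, numeric(1)))
    }
    data.frame(dose = d, n_files = nrow(sub),
               mean_mn_pct = mean(mn_pct),
               sd_mn_pct = if (nrow(sub) > 1) sd(mn_pct) else 0,
               p_value = unname(p),
               significant = !is.na(p) & p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genotox_result", "data.frame")
  out
}

#' Per-dose assay summary with cytotoxicity
#'
#' Joins the genotoxicity analysis with per-dose cytotoxicity: CBPI-based
#' cytostasis from pooled MONO/BN/POLY counts in Cyt-B mode, or
#' relative post-recovery cell counts in non-Cyt-B mode.
#'
#' @param scores Per-file [score_sample()] rows.
#' @param control Solvent-control dose label.
#' @param mode `"cytb"` or `"non_cytb"`.
#' @param relative_counts Named per-dose relative cell counts (non-Cyt-B).
#' @param alpha Significance level.
#' @return Data frame, one row per dose: genotoxicity columns plus
#'   `cytotoxicity_pct` and `exceeds_limit`.
#' @export
assay_summary <- function(scores, control, mode = c("cytb", "non_cytb"),
                          relative_counts = NULL, alpha = 0.001) {
  mode <- match.arg(mode)
  endpoint <- if (mode == "cytb") "mn_bn" else "mn_mono"
  gen <- dose_response_analysis(scores, control, endpoint, alpha = alpha)
  cyto <- vapply(gen$dose, function(d) {
    if (mode == "cytb") {
      sub <- scores[scores$dose == d, ]
      ctl <- scores[scores$dose == control, ]
      tri <- function(s) c(sum(s$n_MONO) + sum(s$n_MONO_MN),
                           sum(s$n_BN) + sum(s$n_BN_MN), sum(s$n_POLY))
      if (d == control) 0 else cytostasis_cbpi(tri(sub), tri(ctl))$cytotoxicity
    } else {
      if (is.null(relative_counts)) return(NA_real_)
      if (d == control) 0 else
        relative_count_cytotoxicity(relative_counts[[d]],
                                    relative_counts[[control]])$cytotoxicity
    }
  }, numeric(1))
  gen$cytotoxicity_pct <- unname(cyto)
  gen$exceeds_limit <- !is.na(cyto) & cyto > 60
  gen
}

#' Plain-text dose-response report
#'
#' @param summary An [assay_summary()] data frame.
#' @param title Report heading.
#' @return Character vector of report lines (also printed when assigned to
#'   a file via `writeLines`).
#' @export
format_assay_report <- function(summary, title = "MN assay dose-response") {
  lines <- c(title, strrep("-", nchar(title)),
             sprintf("%-12s %7s %10s %8s %12s %6s %10s",
                     "dose", "files", "mean MN%", "SD", "p (Fisher)", "sig",
                     "cytotox%"))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf("%-12s %7d %10.3f %8.3f %12s %6s %10.1f",
      r$dose, r$n_files, r$mean_mn_pct, r$sd_mn_pct,
      if (is.na(r$p_value)) "-" else formatC(r$p_value, format = "e", digits = 2),
      ifelse(isTRUE(r$significant), "*", ""),
      if (is.na(r$cytotoxicity_pct)) NA else r$cytotoxicity_pct))
  }
  lines
}
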