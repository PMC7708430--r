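#' Per-class positivity thresholds
#'
#' Defaults are the published operating points chosen from ROC curves:
#' acinar 0.3, ADM 0.5, dysplasia 0.7. Positivity is inclusive
#' (`probability >= threshold`).
#'
#' @param acinar,adm,dysplasia Thresholds in (0, 1).
#' @return Object of class `class_thresholds`.
#' @export
class_thresholds <- function(acinar = 0.3, adm = 0.5, dysplasia = 0.7) {
  for (v in c(acinar, adm, dysplasia)) assert_scalar_in(v, 0, 1, "threshold", strict = TRUE)
  structure(list(acinar = acinar, adm = adm, dysplasia = dysplasia),
            class = "class_thresholds")
}

#' Fuse per-class probability maps into a single label map
#'
#' Priority rules: a near-white pixel (all RGB > `bg_threshold`) is
#' background regardless of any prediction; otherwise acinar predictions
#' override ADM and dysplasia, ADM overrides dysplasia, and any of the
#' three overrides plain tissue, which is labeled "other" (the
#' DAPI-positive remainder).
#'
#' @param prob_acinar,prob_adm,prob_dysplasia H x W probability matrices.
#' @param image The H x W x 3 image the maps refer to (for the background
#'   rule), 0-255.
#' @param thresholds A [class_thresholds()].
#' @param bg_threshold Background intensity threshold (strict `>`).
#' @return Integer H x W label matrix of class `panseg_labels` (codes as in
#'   [label_codes()]).
#' @export
fuse <- function(prob_acinar, prob_adm, prob_dysplasia, image,
                 thresholds = class_thresholds(), bg_threshold = 200) {
  assert_image(image)
  for (p in list(prob_acinar, prob_adm, prob_dysplasia)) {
    assert_prob_map(p)
    if (!identical(dim(p), dim(image)[1:2])) abort("probability map shape mismatch")
  }
  bg <- background_mask(image, bg_threshold)
  labels <- matrix(PANSEG_CODES[["other"]], nrow(bg), ncol(bg))
  labels[prob_dysplasia >= thresholds$dysplasia] <- PANSEG_CODES[["dysplasia"]]
  labels[prob_adm >= thresholds$adm] <- PANSEG_CODES[["adm"]]
  labels[prob_acinar >= thresholds$acinar] <- PANSEG_CODES[["acinar"]]
  labels[bg] <- PANSEG_CODES[["background"]]
  structure(labels, class = c("panseg_labels", class(labels)))
}

#' Quantify per-class areas of a label map
#'
#' Counts pixels per class by exhaustive tally and reports fractions of the
#' cellular region (all non-background pixels). When the map has no
#' cellular pixels the fractions are `NA`, not zero.
#'
#' @param labels Label matrix (codes as in [label_codes()]).
#' @param sample_id Optional identifier carried into the report.
#' @return Tibble of class `panseg_area_report` with one row per class
#'   (`background`, `other`, `acinar`, `adm`, `dysplasia`): `sample_id`,
#'   `class`, `pixels`, `fraction` (background's fraction is `NA`; class
#'   fractions are of the cellular region). Attribute `cellular_total`
#'   holds the cellular pixel count. See [stain_equivalents()] for the
#'   immunofluorescence-equivalent groupings.
#' @export
quantify <- function(labels, sample_id = NA_integer_) {
  if (!is.matrix(labels) || !all(labels %in% PANSEG_CODES)) {
    abort("`labels` must be a matrix with codes 0..4 (see label_codes())")
  }
  counts <- vapply(PANSEG_CODES, function(code) sum(labels == code), numeric(1))
  cellular <- sum(counts[names(counts) != "background"])
  out <- tibble(
    sample_id = sample_id,
    class = names(PANSEG_CODES),
    pixels = as.numeric(counts),
    fraction = ifelse(names(PANSEG_CODES) == "background", NA_real_,
                      if (cellular > 0) counts / cellular else NA_real_)
  )
  attr(out, "cellular_total") <- cellular
  class(out) <- c("panseg_area_report", class(out))
  out
}

#' Immunofluorescence-equivalent area fractions of a report
#'
#' Groups label-map fractions the way the IF panel stains: `amy_equiv` =
#' acinar (amylase marks acini), `pank_equiv` = ADM + dysplasia
#' (pan-keratin marks both and cannot separate them), `other_equiv` = other
#' tissue (DAPI minus AMY and panK overlap).
#'
#' @param report A [quantify()] result.
#' @return One-row tibble: `sample_id`, `amy_equiv`, `pank_equiv`,
#'   `other_equiv`, `cellular_total`.
#' @export
stain_equivalents <- function(report) {
  if (!inherits(report, "panseg_area_report")) abort("`report` must come from quantify()")
  fr <- setNames(report$fraction, report$class)
  tibble(sample_id = report$sample_id[1],
         amy_equiv = fr[["acinar"]],
         pank_equiv = fr[["adm"]] + fr[["dysplasia"]],
         other_equiv = fr[["other"]],
         cellular_total = attr(report, "cellular_total"))
}

#' ROC curve of a probability map against a binary truth mask
#'
#' Sensitivity/specificity over a threshold sweep, with the degenerate
#' endpoints included: threshold 0 calls everything positive (sensitivity
#' 1) and a threshold above 1 calls everything negative (sensitivity 0).
#'
#' @param prob Numeric probabilities in \[0, 1\] (matrix or vector).
#' @param truth Binary mask of the same length.
#' @param n_points Number of interior thresholds (evenly spaced).
#' @return Tibble of class `panseg_roc`: `threshold`, `sensitivity`,
#'   `specificity`, with attribute `auc` (trapezoidal).
#' @export
roc_curve <- function(prob, truth, n_points = 101L) {
  p <- as.vector(prob); y <- as.logical(truth)
  if (length(p) != length(y)) abort("`prob` and `truth` must have equal length")
  if (any(p < 0 | p > 1)) abort("`prob` must be within [0, 1]")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("`truth` must contain at least one positive and one negative pixel")
  }
  thr <- c(0, seq(0, 1, length.out = n_points), 1 + 1e-9)
  thr <- sort(unique(thr))
  sens <- vapply(thr, function(t) sum(p >= t & y) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(p < t & !y) / n_neg, numeric(1))
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - out$specificity
  ord <- order(fpr, out$sensitivity)
  auc <- sum(diff(fpr[ord]) * (head(out$sensitivity[ord], -1) + tail(out$sensitivity[ord], -1)) / 2)
  attr(out, "auc") <- abs(auc)
  class(out) <- c("panseg_roc", class(out))
  out
}
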