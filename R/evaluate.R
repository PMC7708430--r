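#' Segment one image with a set of trained per-class models
#'
#' The full inference pipeline: crop-wise stain normalization to the
#' training reference, tile-level prediction for each class model,
#' overlap-averaged stitching, and priority-rule fusion into a label map.
#'
#' @param image H x W x 3 array, 0-255 (raw, un-normalized).
#' @param models Named list with elements `acinar`, `adm`, `dysplasia`
#'   (from [train_model()]).
#' @param ref Reinhard reference statistics used at training time.
#' @param thresholds A [class_thresholds()].
#' @param crop_size,overlap Normalization crop parameters; default from the
#'   acinar model's training configuration.
#' @param stride Tiling stride for prediction.
#' @param bg_threshold Background threshold.
#' @param balance_white Apply [white_balance()] before background masking
#'   and normalization (default `TRUE`), anchoring the absolute background
#'   rule to the slide's white level.
#' @return List: `labels` (fused label map), `probs` (named list of
#'   probability maps), `normalized` (the normalized image).
#' @export
segment_image <- function(image, models, ref, thresholds = class_thresholds(),
                          crop_size = NULL, overlap = NULL, stride = NULL,
                          bg_threshold = 200, balance_white = TRUE) {
  if (!all(PANSEG_CLASSES %in% names(models))) {
    abort("`models` must contain acinar, adm and dysplasia entries")
  }
  cfg <- models$acinar$config
  crop_size <- crop_size %||% cfg$crop_size
  overlap <- overlap %||% cfg$overlap
  if (balance_white) image <- white_balance(image)
  norm <- normalize_by_crops(image, ref, crop_size = crop_size,
                             overlap = overlap, bg_threshold = bg_threshold,
                             quiet = TRUE)
  probs <- purrr::map(models[PANSEG_CLASSES], function(m) {
    predict_image(m, norm, stride = stride)
  })
  labels <- fuse(probs$acinar, probs$adm, probs$dysplasia, norm,
                 thresholds = thresholds, bg_threshold = bg_threshold)
  list(labels = labels, probs = probs, normalized = norm)
}

#' Stain-perturbation self-consistency of the trained models
#'
#' Applies `n_perturbations` seeded synthetic stain perturbations (random
#' per-channel shifts up to `max_shift`, Gaussian noise) to the image, runs
#' the full normalize-predict-fuse pipeline on each, and computes per-class
#' Dice of each perturbed label map against the unperturbed one. With no
#' perturbation the Dice is 1 by construction.
#'
#' @inheritParams segment_image
#' @param n_perturbations Number of perturbed replicates (>= 1).
#' @param max_shift Maximum relative channel shift in \[0, 0.5\].
#' @param noise_sigma Gaussian noise standard deviation (8-bit units).
#' @param seed Integer seed controlling the perturbation draws.
#' @return List: `summary` (tibble `class`, `mean_dice`) and `draws`
#'   (tibble `perturbation`, `class`, `dice`; `n_perturbations * 3` rows).
#' @export
perturbation_consistency <- function(models, image, ref, n_perturbations = 5L,
                                     max_shift = 0.25, noise_sigma = 5,
                                     thresholds = class_thresholds(), seed = 1L,
                                     crop_size = NULL, overlap = NULL,
                                     stride = NULL, bg_threshold = 200) {
  if (n_perturbations < 1) abort("`n_perturbations` must be >= 1")
  base <- segment_image(image, models, ref, thresholds, crop_size, overlap,
                        stride, bg_threshold)$labels
  seeds <- withr::with_seed(seed, sample.int(1e8, n_perturbations))
  draws <- purrr::map_dfr(seq_len(n_perturbations), function(i) {
    pert <- perturb_stain(image, max_shift, noise_sigma, seed = seeds[i])
    lab <- segment_image(pert, models, ref, thresholds, crop_size, overlap,
                         stride, bg_threshold)$labels
    purrr::map_dfr(PANSEG_CLASSES, function(cls) {
      code <- PANSEG_CODES[[cls]]
      tibble(perturbation = i, class = cls, dice = dice(lab == code, base == code))
    })
  })
  summary <- dplyr::summarise(dplyr::group_by(draws, class),
                              mean_dice = mean(dice), .groups = "drop")
  list(summary = summary, draws = draws)
}

#' Correlate predicted and reference area fractions across a cohort
#'
#' Spearman correlation per immunofluorescence-equivalent channel between
#' predicted area fractions and reference (stain-derived) fractions, over a
#' cohort of images. Optionally also windowed SSIM between each sample's
#' predicted binary mask and its reference mask treated as images (with a
#' small Gaussian pre-blur, since nearly aligned masks differ at the pixel
#' level).
#'
#' @param cohort Tibble with columns `sample_id`, `amy_pred`, `pank_pred`,
#'   `other_pred`, `amy_ref`, `pank_ref`, `other_ref`; fractions in
#'   \[0, 1\], at least 3 samples.
#' @param pred_masks,ref_masks Optional named lists (per channel) of lists
#'   of binary masks, parallel to the cohort rows, for the SSIM report.
#' @param ssim_pre_blur Pre-blur sigma for the mask SSIM (default 1).
#' @return List: `correlations` (tibble `channel`, `spearman`, `n`) and
#'   `ssim` (tibble `sample_id`, `channel`, `ssim`, or `NULL`).
#' @export
evaluate_cohort <- function(cohort, pred_masks = NULL, ref_masks = NULL,
                            ssim_pre_blur = 1) {
  need <- c("sample_id", "amy_pred", "pank_pred", "other_pred",
            "amy_ref", "pank_ref", "other_ref")
  if (!all(need %in% names(cohort))) {
    abort(sprintf("`cohort` must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(cohort) < 3) abort("need at least 3 samples")
  vals <- unlist(cohort[setdiff(need, "sample_id")])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) abort("fractions must be in [0, 1]")
  channels <- c(amy = "amy", pank = "pank", other = "other")
  correlations <- purrr::map_dfr(channels, function(chn) {
    tibble(channel = chn,
           spearman = spearman_cor(cohort[[paste0(chn, "_pred")]],
                                   cohort[[paste0(chn, "_ref")]]),
           n = nrow(cohort))
  })
  ssim_tbl <- NULL
  if (!is.null(pred_masks) && !is.null(ref_masks)) {
    ssim_tbl <- purrr::map_dfr(names(pred_masks), function(chn) {
      purrr::map_dfr(seq_along(pred_masks[[chn]]), function(i) {
        tibble(sample_id = cohort$sample_id[i], channel = chn,
               ssim = ssim(pred_masks[[chn]][[i]] * 1.0,
                           ref_masks[[chn]][[i]] * 1.0,
                           pre_blur_sigma = ssim_pre_blur))
      })
    })
  }
  list(correlations = correlations, ssim = ssim_tbl)
}
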