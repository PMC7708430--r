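#' Train the three per-class models on a cohort of samples
#'
#' End-to-end training stage: computes the Reinhard reference from the
#' first sample (unless given), normalizes every image crop-wise, tiles
#' images and per-class truth masks, splits tiles into class-relevant and
#' other, composes each class's training set (80% relevant + a small
#' negative-control slice, 20% of relevant held out), and trains one
#' binary UNet per class.
#'
#' @param samples List of `panseg_sample` objects (or lists with `image`
#'   and `truth`).
#' @param config A [training_config()]; [desk_scale_config()] for small runs.
#' @param classes Character vector of classes to train (default all three).
#' @param reference Optional `reinhard_stats` to normalize against; default
#'   is computed from the first sample, the designated reference image.
#' @return List of class `panseg_model_set`: `models` (named list of
#'   [train_model()] results), `ref`, `config`.
#' @export
train_cohort_models <- function(samples, config = desk_scale_config(),
                                classes = PANSEG_CLASSES, reference = NULL) {
  if (length(samples) == 0) abort("`samples` must be non-empty")
  ref <- reference %||% reinhard_stats(white_balance(samples[[1]]$image))
  normalized <- purrr::map(samples, function(s) {
    normalize_by_crops(white_balance(s$image), ref, crop_size = config$crop_size,
                       overlap = config$overlap, quiet = TRUE)
  })
  models <- list()
  for (cls in classes) {
    relevant <- list(); other <- list()
    for (i in seq_along(samples)) {
      grid <- plan_grid(dim(normalized[[i]])[1], dim(normalized[[i]])[2],
                        tile_size = config$tile_size, stride = config$stride,
                        quiet = TRUE)
      img_tiles <- cut_tiles(normalized[[i]] / 255, grid)
      mask_tiles <- cut_tiles((samples[[i]]$truth == PANSEG_CODES[[cls]]) * 1, grid)
      for (k in seq_along(img_tiles)) {
        item <- list(tile = img_tiles[[k]], mask = mask_tiles[[k]])
        if (mean(item$mask) >= config$min_class_fraction) {
          relevant[[length(relevant) + 1L]] <- item
        } else {
          other[[length(other) + 1L]] <- item
        }
      }
    }
    if (length(relevant) == 0) {
      abort(sprintf("no tiles contain class '%s' at min_class_fraction = %g",
                    cls, config$min_class_fraction))
    }
    split <- compose_training_set(relevant, other, config)
    models[[cls]] <- train_model(split$train, split$heldout, config, cls)
  }
  structure(list(models = models, ref = ref, config = config),
            class = "panseg_model_set")
}

#' Evaluate trained models on unseen samples
#'
#' Runs the full segmentation pipeline on each sample and computes
#' per-class Dice of the fused label map against the ground truth, plus
#' the area report per sample.
#'
#' @param model_set A [train_cohort_models()] result.
#' @param samples List of `panseg_sample` objects unseen during training.
#' @param thresholds A [class_thresholds()].
#' @return List: `dice` (tibble `sample_id`, `class`, `dice`), `reports`
#'   (combined [quantify()] tibble), `labels` (list of fused label maps).
#' @export
evaluate_on_samples <- function(model_set, samples, thresholds = class_thresholds()) {
  labels <- vector("list", length(samples))
  dice_rows <- list(); report_rows <- list()
  for (i in seq_along(samples)) {
    seg <- segment_image(samples[[i]]$image, model_set$models, model_set$ref,
                         thresholds = thresholds)
    labels[[i]] <- seg$labels
    truth <- samples[[i]]$truth
    for (cls in PANSEG_CLASSES) {
      code <- PANSEG_CODES[[cls]]
      dice_rows[[length(dice_rows) + 1L]] <-
        tibble(sample_id = i, class = cls,
               dice = dice(seg$labels == code, truth == code))
    }
    report_rows[[i]] <- quantify(seg$labels, sample_id = i)
  }
  list(dice = dplyr::bind_rows(dice_rows),
       reports = dplyr::bind_rows(report_rows),
       labels = labels)
}
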