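#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained segmentation model's training history
#'
#' @param x A [train_model()] result.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_bce`, `val_bce`,
#'   `val_dice`, plus the model's `class` column.
#' @export
tidy.panseg_model <- function(x, ...) {
  dplyr::mutate(x$log, class = x$class_name, .before = 1)
}

#' One-row summary of a trained segmentation model
#'
#' @param x A [train_model()] result.
#' @param ... Unused.
#' @return One-row tibble: `class`, `best_epoch`, `val_bce`, `val_dice`,
#'   `epochs`, `parameters`.
#' @export
glance.panseg_model <- function(x, ...) {
  best <- x$log[x$log$epoch == x$best_epoch, ]
  n_par <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), numeric(1)))
  tibble(class = x$class_name, best_epoch = x$best_epoch,
         val_bce = if (nrow(best)) best$val_bce else NA_real_,
         val_dice = if (nrow(best)) best$val_dice else NA_real_,
         epochs = nrow(x$log), parameters = n_par)
}

#' @export
print.panseg_model <- function(x, ...) {
  cat(sprintf("<panseg_model> class '%s': depth %d, base %d channels, %d px tiles\n",
              x$class_name, x$depth, x$base, x$input_size))
  cat(sprintf("  best epoch %d/%d (selection: %s)\n", x$best_epoch,
              nrow(x$log), x$config$selection))
  invisible(x)
}

#' @export
print.panseg_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d x %d, fractions %s, seed %d\n",
              x$height, x$width,
              paste(sprintf("%s=%.2f", names(x$target_fractions),
                            x$target_fractions), collapse = " "),
              x$seed))
  invisible(x)
}
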