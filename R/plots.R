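# ggplot2 displays for the result types. Images/label maps are rasterized
# into long tibbles first; everything else is already tabular.

labels_to_tbl <- function(labels) {
  code_names <- names(PANSEG_CODES)[match(as.vector(labels), PANSEG_CODES)]
  tibble(row = rep(seq_len(nrow(labels)), times = ncol(labels)),
         col = rep(seq_len(ncol(labels)), each = nrow(labels)),
         class = factor(code_names, levels = names(PANSEG_CODES)))
}

panseg_palette <- c(background = "grey95", other = "#f2c4cf",
                    acinar = "#b265a8", adm = "#e398c2", dysplasia = "#5e2a6e")

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_abline scale_fill_manual scale_y_reverse coord_fixed labs
#'   theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a fused label map
#'
#' @param object A label matrix (from [fuse()] or [read_label_map()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panseg_labels <- function(object, ...) {
  ggplot(labels_to_tbl(object), aes(.data$col, .data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = panseg_palette, drop = FALSE) +
    scale_y_reverse() + coord_fixed() +
    labs(x = NULL, y = NULL, fill = "tissue") + theme_minimal()
}

#' Plot per-class area fractions of an area report
#'
#' @param object A [quantify()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panseg_area_report <- function(object, ...) {
  d <- object[object$class != "background", ]
  ggplot(d, aes(.data$class, .data$fraction, fill = .data$class)) +
    geom_col() +
    scale_fill_manual(values = panseg_palette, guide = "none") +
    labs(x = NULL, y = "fraction of cellular area") + theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panseg_roc <- function(object, ...) {
  ggplot(object, aes(1 - .data$specificity, .data$sensitivity)) +
    geom_line() +
    geom_abline(linetype = "dashed", color = "grey60") +
    coord_fixed() +
    labs(x = "1 - specificity", y = "sensitivity",
         subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    theme_minimal()
}

#' Plot the training history of a trained model
#'
#' @param object A [train_model()] result.
#' @param ... Unused.
#' @return A ggplot object showing train/held-out BCE per epoch.
#' @export
autoplot.panseg_model <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, c("train_bce", "val_bce"),
                           names_to = "series", values_to = "bce")
  ggplot(d, aes(.data$epoch, .data$bce, color = .data$series)) +
    geom_line() +
    labs(y = "binary cross-entropy", color = NULL,
         subtitle = sprintf("class '%s', best epoch %d",
                            object$class_name, object$best_epoch)) +
    theme_minimal()
}

#' Render a synthetic sample's image as a ggplot raster
#'
#' @param sample A [generate_sample()] result.
#' @return A ggplot object.
#' @export
plot_sample <- function(sample) {
  img <- sample$image / 255
  hexes <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  d <- tibble(row = rep(seq_len(dim(img)[1]), times = dim(img)[2]),
              col = rep(seq_len(dim(img)[2]), each = dim(img)[1]),
              fill = hexes)
  ggplot(d, aes(.data$col, .data$row)) +
    geom_raster(fill = d$fill) +
    scale_y_reverse() + coord_fixed() +
    labs(x = NULL, y = NULL) + theme_minimal()
}
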