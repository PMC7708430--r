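#' Seeded specifications for a synthetic cohort with varying composition
#'
#' Draws per-sample target compositions across the biologically relevant
#' range (acinar-dominated through lesion-rich), plus small inter-image
#' color shifts, emulating a murine cohort at mixed disease stages.
#'
#' @param n Number of samples.
#' @param image_size Image edge in pixels.
#' @param seed Integer seed.
#' @param noise_sigma,unevenness_amplitude Passed to [synthetic_spec()].
#' @return List of [synthetic_spec()] objects.
#' @export
cohort_specs <- function(n, image_size = 192L, seed = 1L, noise_sigma = 3,
                         unevenness_amplitude = 0.15) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      adm <- runif(1, 0.08, 0.32)
      dys <- runif(1, 0.05, 0.25)
      acinar <- runif(1, 0.15, 0.95 - adm - dys - 0.10)
      other <- 1 - acinar - adm - dys
      synthetic_spec(
        height = image_size, width = image_size,
        target_fractions = c(acinar = acinar, adm = adm, dysplasia = dys, other = other),
        n_lesions = sample(2:4, 1),
        lumen_fraction = runif(1, 0.2, 0.3),
        unevenness_amplitude = unevenness_amplitude,
        color_shift = runif(3, -0.1, 0.1),
        noise_sigma = noise_sigma,
        seed = sample.int(1e8, 1)
      )
    })
  })
}

#' Run the end-to-end pipeline and write its artifacts
#'
#' Generate (or accept) a cohort, train the three per-class models on the
#' training split, segment the test split, quantify areas, and evaluate
#' (per-class Dice against truth, per-channel Spearman against the
#' synthetic IF fractions). All artifacts are declared up front and written
#' under `out_dir`; identical config and seed reproduce identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param samples Optional pre-built list of `panseg_sample` objects of
#'   length `n_train + n_test`; defaults to a generated synthetic cohort.
#' @return List: `models`, `evaluation` (list with `dice`, `correlations`),
#'   `area_reports` (tibble), `log` (tibble of stages), `paths` (artifact
#'   manifest).
#' @export
run_pipeline <- function(config, out_dir, samples = NULL) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    manifest = file.path(out_dir, "cohort_manifest.csv"),
    area_report = file.path(out_dir, "area_report.csv"),
    evaluation = file.path(out_dir, "evaluation.json"),
    log = file.path(out_dir, "run_log.csv"),
    labels_dir = file.path(out_dir, "labels"),
    images_dir = file.path(out_dir, "images")
  )
  dir.create(paths$labels_dir, showWarnings = FALSE)
  dir.create(paths$images_dir, showWarnings = FALSE)
  log_rows <- list()
  stage <- function(name, seed, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      stage = name, seed = seed,
      wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  n_total <- config$n_train + config$n_test
  cohort <- stage("generate", config$seed, {
    if (is.null(samples)) {
      specs <- cohort_specs(n_total, config$image_size, seed = config$seed)
      generate_cohort(specs)
    } else {
      if (length(samples) != n_total) {
        abort(sprintf("expected %d samples (n_train + n_test), got %d",
                      n_total, length(samples)))
      }
      list(samples = samples,
           manifest = purrr::map_dfr(seq_along(samples), function(i) {
             realized_fractions(samples[[i]]$truth, sample_id = i)
           }))
    }
  })
  utils::write.csv(cohort$manifest, paths$manifest, row.names = FALSE)
  for (i in seq_along(cohort$samples)) {
    write_image(cohort$samples[[i]]$image,
                file.path(paths$images_dir, sprintf("sample_%02d.png", i)))
  }

  train_idx <- seq_len(config$n_train)
  test_idx <- config$n_train + seq_len(config$n_test)
  model_set <- stage("train", config$training$seed, {
    train_cohort_models(cohort$samples[train_idx], config$training)
  })

  test_samples <- cohort$samples[test_idx]
  evaluation <- stage("evaluate", config$seed, {
    evaluate_on_samples(model_set, test_samples, thresholds = config$thresholds)
  })
  for (i in seq_along(test_samples)) {
    write_label_map(evaluation$labels[[i]],
                    file.path(paths$labels_dir, sprintf("test_%02d_labels.png", i)))
  }
  utils::write.csv(evaluation$reports, paths$area_report, row.names = FALSE)

  ctab <- cohort_fraction_table(evaluation, test_samples)
  cohort_eval <- if (nrow(ctab) >= 3) evaluate_cohort(ctab) else {
    list(correlations = NULL) # rank correlation is meaningless below n = 3
  }
  jsonlite::write_json(
    list(dice = evaluation$dice, correlations = cohort_eval$correlations,
         config_hash = rlang::hash(unclass(config))),
    paths$evaluation, dataframe = "rows", auto_unbox = TRUE, digits = NA)

  log <- dplyr::bind_rows(log_rows)
  utils::write.csv(log, paths$log, row.names = FALSE)
  list(models = model_set, evaluation = list(dice = evaluation$dice,
                                             correlations = cohort_eval$correlations),
       area_reports = evaluation$reports, log = log, paths = paths)
}

# Pair predicted area fractions with the synthetic-IF reference fractions.
cohort_fraction_table <- function(evaluation, samples) {
  purrr::map_dfr(seq_along(samples), function(i) {
    rep_i <- evaluation$reports[evaluation$reports$sample_id == i, ]
    class(rep_i) <- c("panseg_area_report", class(rep_i))
    attr(rep_i, "cellular_total") <- sum(rep_i$pixels[rep_i$class != "background"])
    eq <- stain_equivalents(rep_i)
    truth <- samples[[i]]$truth
    cellular <- sum(samples[[i]]$if_dapi)
    tibble(sample_id = i,
           amy_pred = eq$amy_equiv, pank_pred = eq$pank_equiv,
           other_pred = eq$other_equiv,
           amy_ref = sum(samples[[i]]$if_amy) / cellular,
           pank_ref = sum(samples[[i]]$if_pank) / cellular,
           other_ref = sum(truth == PANSEG_CODES[["other"]]) / cellular)
  })
}
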