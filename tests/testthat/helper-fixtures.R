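# Shared fixtures. The desk-scale model set is expensive (~3 min) and is
# trained once per test run, lazily, then reused by every test that needs
# trained models.

panseg_cache <- new.env(parent = emptyenv())

test_training_cohort <- function() {
  if (is.null(panseg_cache$cohort)) {
    specs <- cohort_specs(15, image_size = 192, seed = 42)
    panseg_cache$cohort <- generate_cohort(specs)
  }
  panseg_cache$cohort
}

test_model_set <- function() {
  if (is.null(panseg_cache$models)) {
    cohort <- test_training_cohort()
    cfg <- desk_scale_config(seed = 7)
    panseg_cache$models <- train_cohort_models(cohort$samples[1:10], cfg)
  }
  panseg_cache$models
}

# evaluation of the model set on the 5 unseen samples of the training cohort
test_heldout_evaluation <- function() {
  if (is.null(panseg_cache$eval)) {
    cohort <- test_training_cohort()
    panseg_cache$eval <- evaluate_on_samples(test_model_set(),
                                             cohort$samples[11:15])
  }
  panseg_cache$eval
}

# small random tissue-like image (values kept below the background
# threshold so every pixel is tissue unless stated otherwise)
random_tissue_image <- function(h = 32, w = 32, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(runif(h * w * 3, 20, 190), c(h, w, 3))
    round(arr)
  })
}
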