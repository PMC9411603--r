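# Shared fixtures: all data is generated in code at test time.

# A small deterministic record with rich structure (not a valid ECG, but
# exercises IO paths).
fixture_record <- function(L = 500, seed = 11, label = "RBBB") {
  sig <- with_fixed_seed(seed, matrix(stats::rnorm(12 * L), 12, L))
  ecg_record(sig, fs = 500, age = 46, sex = "female", label = label,
             record_id = sprintf("FX%04d", seed))
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Reduced network for desk-scale training tests: 256-sample input (slices
# decimated 32x), 4 blocks, 4-8 channels.
reduced_model_config <- function(dropout = 0, seed = 1) {
  model_config(input_len = 256, kernel = 8, channels = c(4, 8),
               blocks_per_stage = 2, dropout = dropout, head_hidden = 16,
               seed = seed)
}

# Noise-free well-separated 3-class records -> preprocessed slices.
separable_slices <- function(classes = c("Normal", "LBBB", "STE"),
                             per_class = 8) {
  cfg <- noise_free_config()
  recs <- unlist(lapply(classes, function(cl) {
    lapply(seq_len(per_class), function(i) {
      synth_record(cl, cfg, seed = i + 100 * match(cl, ecg_classes()),
                   record_id = sprintf("%s%02d", cl, i))
    })
  }), recursive = FALSE)
  unlist(lapply(recs, preprocess_record), recursive = FALSE)
}

# Random label vectors -> confusion fixture.
random_confusion <- function(n = 200, seed = 42) {
  with_fixed_seed(seed, {
    refs <- sample(ecg_classes(), n, replace = TRUE)
    preds <- ifelse(stats::runif(n) < 0.6, refs,
                    sample(ecg_classes(), n, replace = TRUE))
    confusion(refs, preds)
  })
}
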