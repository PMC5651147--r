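# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code from fixed seeds; no files ship with the
# tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# a handful of rendered phantoms with the default study conditions
fixture_radiographs <- function(n = 6, seed0 = 300, noise = 5) {
  cached(sprintf("rgs_%d_%d_%g", n, seed0, noise), function() {
    lapply(seq_len(n), function(s) {
      render_radiograph(generate_spine_spec(seed = seed0 + s),
                        noise_level = noise, seed = seed0 + 100 + s)
    })
  })
}

# noise-free renders for pixel-exact geometry checks
fixture_clean_radiograph <- function(seed = 42) {
  cached(sprintf("clean_rg_%d", seed), function() {
    render_radiograph(generate_spine_spec(seed = seed), noise_level = 0,
                      seed = 1)
  })
}

# a small but genuinely trained network shared by end-to-end tests:
# 40 phantoms x 17 vertebrae x 15 jittered patches, default architecture
fixture_model <- function() {
  cached("model", function() {
    rgs <- lapply(1:40, function(s) {
      render_radiograph(generate_spine_spec(seed = 700 + s),
                        noise_level = 5, seed = 800 + s)
    })
    tr <- sample_training_patches(rgs, patches_per_vertebra = 15,
                                  jitter_radius = 15, seed = 7)
    cfg <- training_config(pretrain_epochs = 15, finetune_epochs = 40,
                           seed = 11)
    train_slope_dnn(tr, cfg)
  })
}

# small synthetic patch matrix (structured, labeled) for network unit tests
fixture_patchset <- function(n_rg = 3, per_v = 4, seed = 5) {
  cached(sprintf("ps_%d_%d_%d", n_rg, per_v, seed), function() {
    rgs <- fixture_radiographs(n_rg)
    sample_training_patches(rgs, per_v, 10, seed = seed)
  })
}

# tiny hand-built network: patch length 4, PCA dim 2, h2 = h3 = 2
toy_params <- function() {
  cobbnet:::new_dnn_parameters(
    W1 = matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 2, byrow = TRUE),
    b1 = c(1, 2, 0, 0),
    W2 = matrix(c(1, -1, 2, 0), nrow = 2, byrow = TRUE), b2 = c(0.5, -0.5),
    W3 = matrix(c(1, 1, -1, 2), nrow = 2, byrow = TRUE), b3 = c(0, 1),
    W4 = matrix(c(3, -2), nrow = 1), b4 = 0.25,
    config = NULL
  )
}
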