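# Shared fixtures, all generated in code.

# A sinusoid recording for filter tests.
sine_rec <- function(freq, fs = 1000, seconds = 2, n_channels = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  data <- matrix(rep(sin(2 * pi * freq * t), n_channels),
                 nrow = n_channels, byrow = TRUE)
  emg_recording(data, fs = fs, subject_id = "sine")
}

rms <- function(x) sqrt(mean(x^2))

# A small labeled recording with known block labels.
blocky_rec <- function(fs = 1000, block_ms = 400, n_blocks = 4,
                       n_channels = 2, subject = "S1", seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  len <- round(block_ms * fs / 1000)
  labels <- rep(seq_len(n_blocks) - 1L, each = len)
  data <- withr_seed(matrix(rnorm(n_channels * length(labels)), n_channels))
  emg_recording(data, fs = fs, subject_id = subject, labels = labels)
}

# A tiny model configuration that keeps forward/backward passes fast.
tiny_config <- function(n_channels = 3, window_len = 16, n_classes = 3,
                        shots = 2, dropout = 0.3) {
  model_config(n_channels = n_channels, window_len = window_len,
               n_classes = n_classes, shots = shots, conv_filters = 4,
               fc_hidden = 8, dropout = dropout)
}

# A labeled window set drawn from class-dependent Gaussians, linearly
# separable in channel-mean space.
tiny_windows <- function(n_per_class = 12, cfg = tiny_config(), seed = 1,
                         subject = "S1") {
  set.seed(seed)
  C <- cfg$n_classes
  n <- n_per_class * C
  arr <- array(0, c(cfg$n_channels, cfg$window_len, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    c <- (i - 1L) %% C
    labels[i] <- c
    mu <- numeric(cfg$n_channels)
    mu[(c %% cfg$n_channels) + 1L] <- 2
    arr[, , i] <- matrix(rnorm(cfg$n_channels * cfg$window_len), cfg$n_channels) * 0.3 + mu
  }
  window_set(arr, labels, rep(subject, n),
             starts = (seq_len(n) - 1L) * cfg$window_len, fs = 1000)
}

tiny_templates <- function(ws, cfg = tiny_config(), seed = 1) {
  init_templates(ws, cfg$n_classes, shots = cfg$shots, seed = seed)
}

# Fast training configuration for unit tests.
tiny_train_config <- function(aux_epochs = 2, finetune_epochs = 2, ...) {
  train_config(epochs = 4, warmup_epochs = 2, batch_size = 8, lr0 = 0.01,
               aux_epochs = aux_epochs, finetune_epochs = finetune_epochs,
               max_train_windows = Inf, ...)
}

# The default study cohort at the scale used by the acceptance properties.
study_cohort <- function(seed) generate_cohort(cohort_config(seed = seed))

study_train_config <- function(seed) train_config(seed = seed, aux_epochs = 5)
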