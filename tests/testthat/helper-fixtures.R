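# Shared fixtures: tiny configurations and signal builders used across tests.

tiny_deformer_config <- function(fs = 64, ...) {
  deformer_config(fs = fs, n_filters = 4L, n_hct_layers = 2L, n_heads = 2L,
                  d_k = 2L, mlp_hidden = 3L, dropout = 0, temporal_kernel = 5L,
                  sfe_pool = 4L, sfe_stride = 2L, fine_kernel = 3L,
                  out_dim = 3L, ...)
}

tiny_bca_config <- function(...) {
  bca_config(n_layers = 2L, heads = 2L, d_k = 2L, conv_kernel = 3L,
             dilations = c(1L, 2L), ffn_hidden = 5L, dropout = 0, ...)
}

tiny_tcn_config <- function(...) {
  tcn_config(n_blocks = 2L, kernel_sizes = c(3L, 3L), dilations = c(1L, 2L),
             filters = 4L, dropout = 0, ...)
}

tiny_model <- function(variant = "C2G-DF-BCA-TCN", n_classes = 3L) {
  c2g_model(rep(1L, 9), n_classes, tiny_deformer_config(), tiny_bca_config(),
            tiny_tcn_config(), mlp_hidden = 4L, rnn_hidden = 3L, dropout = 0,
            variant = variant)
}

# one tiny trial: 9 single-channel clusters, T windows of S samples
tiny_trial <- function(T_ = 3L, S = 64L, n_cl = 9L) {
  lapply(seq_len(n_cl), function(l) array(stats::rnorm(T_ * S), dim = c(T_, S, 1L)))
}

sine_recording <- function(freqs, amps, fs = 128, seconds = 8, n_channels = length(freqs),
                           labels = paste0("ch", seq_len(n_channels))) {
  tt <- seq_len(fs * seconds) / fs
  data <- t(vapply(seq_len(n_channels),
                   function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                   numeric(length(tt))))
  raw_recording(data, fs, labels,
                ratings = list(valence = 5, arousal = 5, dominance = 5))
}

# FFT amplitude of a single frequency component (edges trimmed)
fft_amplitude <- function(x, fs, freq, trim_seconds = 1) {
  n0 <- round(trim_seconds * fs)
  x <- x[(n0 + 1):(length(x) - n0)]
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  k <- round(freq * n / fs) + 1L
  max(sp[max(1, k - 1):min(n, k + 1)])
}

# finite-difference gradient of a scalar-valued function of a parameter tree
numeric_gradient <- function(lossf, p, eps = 1e-5) {
  g <- p
  paths <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    if (is.list(x)) for (nm in names(x)) walk(x[[nm]], c(path, nm))
  }
  walk(p, character(0))
  for (pa in paths) {
    acc <- paste0(vapply(pa, function(s) paste0("[['", s, "']]"), ""), collapse = "")
    w <- eval(parse(text = paste0("p", acc)))
    gw <- w * 0
    for (i in seq_along(w)) {
      p1 <- p; eval(parse(text = paste0("p1", acc, "[i] <- w[i] + eps")))
      p2 <- p; eval(parse(text = paste0("p2", acc, "[i] <- w[i] - eps")))
      gw[i] <- (lossf(p1) - lossf(p2)) / (2 * eps)
    }
    eval(parse(text = paste0("g", acc, " <- gw")))
  }
  g
}

max_tree_diff <- function(a, b) {
  m <- 0
  rec <- function(x, y) {
    if (is.numeric(x)) { m <<- max(m, max(abs(x - y))); return(invisible()) }
    if (is.list(x)) for (nm in names(x)) rec(x[[nm]], y[[nm]])
  }
  rec(a, b)
  m
}
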