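#' Train the stacked sparse autoencoder denoiser
#'
#' A two-layer encoder / two-layer decoder autoencoder over per-channel
#' one-second signal segments, trained with a mean-squared reconstruction
#' loss plus an L1 sparsity penalty on the hidden code. Trained on clean
#' windows, it learns the oscillatory manifold of artifact-free EEG; at
#' denoising time each segment is replaced by its reconstruction, which
#' attenuates transients (blinks, motion) the clean manifold cannot express.
#'
#' @param clean_windows a [window_set()] of artifact-free training windows.
#' @param hidden integer vector of the two encoder widths.
#' @param seg_seconds segment length fed to the autoencoder.
#' @param epochs,learning_rate,l1_weight training hyperparameters.
#' @param batch_size segments per Adam step.
#' @param verbose print the per-epoch loss.
#' @return An `ssae_denoiser`: parameters, `fs`, segment length and the
#'   per-epoch `loss_curve` (reconstruction MSE + sparsity penalty).
#' @export
train_ssae <- function(clean_windows, hidden = c(64L, 32L), seg_seconds = 1,
                       epochs = 50L, learning_rate = 1e-3, l1_weight = 1e-4,
                       batch_size = 64L, verbose = FALSE) {
  if (any(hidden < 1)) stop("hidden layer sizes must be positive")
  if (n_windows(clean_windows) < 1) stop("need at least one training window")
  fs <- clean_windows$fs
  seg <- round(seg_seconds * fs)
  X <- windows_to_segments(clean_windows$windows, seg)
  if (stats::sd(X) < 1e-12) stop("degenerate all-constant training input")
  p <- list(enc1 = init_linear(seg, hidden[1]), enc2 = init_linear(hidden[1], hidden[2]),
            dec1 = init_linear(hidden[2], hidden[1]), dec2 = init_linear(hidden[1], seg))
  opt <- adam_state(p)
  n <- nrow(X)
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      f <- ssae_fwd(xb, p)
      resid <- f$out - xb
      m <- length(resid)
      loss <- mean(resid^2) + l1_weight * mean(abs(f$code))
      g <- 2 * resid / m
      gr <- ssae_bwd(g, f, l1_weight)
      p <- adam_step(p, gr, opt, lr = learning_rate)
      ep_loss <- ep_loss + loss * length(idx)
    }
    loss_curve[ep] <- ep_loss / n
    if (verbose) message(sprintf("ssae epoch %3d  loss %.5f", ep, loss_curve[ep]))
  }
  structure(list(params = p, fs = fs, seg_samples = seg, hidden = hidden,
                 loss_curve = loss_curve),
            class = "ssae_denoiser")
}

windows_to_segments <- function(w, seg) {
  d <- dim(w)
  n_seg <- d[3] %/% seg
  if (n_seg < 1) stop("windows shorter than one autoencoder segment")
  out <- matrix(0, d[1] * d[2] * n_seg, seg)
  r <- 0L
  for (i in seq_len(d[1])) for (c in seq_len(d[2])) for (s in seq_len(n_seg)) {
    r <- r + 1L
    out[r, ] <- w[i, c, ((s - 1L) * seg + 1L):(s * seg)]
  }
  out
}

ssae_fwd <- function(x, p) {
  e1 <- linear_fwd(x, p$enc1); h1 <- tanh(e1$out)
  e2 <- linear_fwd(h1, p$enc2); h2 <- tanh(e2$out)
  d1 <- linear_fwd(h2, p$dec1); h3 <- tanh(d1$out)
  d2 <- linear_fwd(h3, p$dec2)
  list(out = d2$out, code = h2,
       cache = list(e1 = e1, h1 = h1, e2 = e2, h2 = h2, d1 = d1, h3 = h3, d2 = d2))
}

ssae_bwd <- function(g, f, l1_weight) {
  ca <- f$cache
  gd2 <- linear_bwd(g, ca$d2$cache)
  gh3 <- gd2$dx * (1 - ca$h3^2)
  gd1 <- linear_bwd(gh3, ca$d1$cache)
  gh2 <- gd1$dx + l1_weight * sign(ca$h2) / length(ca$h2)
  gh2 <- gh2 * (1 - ca$h2^2)
  ge2 <- linear_bwd(gh2, ca$e2$cache)
  gh1 <- ge2$dx * (1 - ca$h1^2)
  ge1 <- linear_bwd(gh1, ca$e1$cache)
  list(enc1 = ge1$grads, enc2 = ge2$grads, dec1 = gd1$grads, dec2 = gd2$grads)
}

#' Apply the autoencoder denoiser to a recording
#'
#' Each channel is cut into consecutive segments of the denoiser's training
#' length and replaced by its reconstruction; a trailing remainder shorter
#' than one segment is passed through unchanged. `enabled = FALSE` returns
#' the input untouched.
#'
#' @param recording a [raw_recording()].
#' @param denoiser a trained [train_ssae()] model.
#' @param enabled logical switch.
#' @return A denoised `raw_recording` of identical shape.
#' @export
ssae_denoise <- function(recording, denoiser, enabled = TRUE) {
  if (!enabled) return(recording)
  if (!inherits(denoiser, "ssae_denoiser")) stop("denoiser must come from train_ssae()")
  if (!isTRUE(all.equal(denoiser$fs, recording$fs))) {
    stop(sprintf("denoiser trained at %g Hz, recording is %g Hz",
                 denoiser$fs, recording$fs))
  }
  seg <- denoiser$seg_samples
  n <- ncol(recording$data)
  n_seg <- n %/% seg
  if (n_seg < 1) stop("recording shorter than one denoiser segment")
  out <- recording$data
  for (ch in seq_len(nrow(out))) {
    segs <- matrix(out[ch, seq_len(n_seg * seg)], n_seg, seg, byrow = TRUE)
    rec <- ssae_fwd(segs, denoiser$params)$out
    out[ch, seq_len(n_seg * seg)] <- as.vector(t(rec))
  }
  raw_recording(out, recording$fs, recording$channel_labels,
                recording$subject_id, recording$trial_id, recording$ratings)
}
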