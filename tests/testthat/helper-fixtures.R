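# Shared fixtures, built in code.

tiny_train_cfg <- function(epochs = 2, seed = 1) {
  train_config(epochs = epochs, batch_size = 8, seed = seed)
}

# Direct double-sum convolution with zero padding; the independent oracle for
# blur(). Implemented as an explicit sum over kernel taps of shifted copies
# of the zero-padded image (no transforms involved).
brute_convolve <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  r <- (nrow(k) - 1) / 2
  pad <- matrix(0, h + 2 * r, w + 2 * r)
  pad[r + seq_len(h), r + seq_len(w)] <- x
  out <- matrix(0, h, w)
  for (a in -r:r) for (b in -r:r)   # true convolution: kernel flipped
    out <- out + k[r + 1 - a, r + 1 - b] *
      pad[r + seq_len(h) + a, r + seq_len(w) + b]
  out
}

# Frequency-domain Wiener/regularized inverse of a zero-padded convolution.
wiener_deblur <- function(blurred, kernel, eps = 1e-4) {
  h <- nrow(blurred); w <- ncol(blurred)
  r <- (nrow(kernel) - 1) / 2
  ph <- h + 2 * r; pw <- w + 2 * r
  B <- matrix(0, ph, pw); B[(r + 1):(r + h), (r + 1):(r + w)] <- blurred
  K <- matrix(0, ph, pw)
  K[1:nrow(kernel), 1:ncol(kernel)] <- kernel
  # center kernel at (1,1) circularly
  K <- K[c((r + 1):ph, 1:r), c((r + 1):pw, 1:r)]
  FB <- stats::fft(B); FK <- stats::fft(K)
  X <- stats::fft(FB * Conj(FK) / (Mod(FK)^2 + eps), inverse = TRUE) / (ph * pw)
  Re(X)[(r + 1):(r + h), (r + 1):(r + w)]
}

expect_no_mask_overlap <- function(m1, m2) {
  expect_equal(sum(m1 == 1 & m2 == 1), 0)
}
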