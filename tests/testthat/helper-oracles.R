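# independent oracles used across tests; deliberately naive implementations

rand_fmap <- function(h, w, c, n, sd = 1) {
  array(rnorm(h * w * c * n, sd = sd), dim = c(h, w, c, n))
}

# brute-force patchwise weighted mean with symmetric bottom/right padding:
# plain loops, no shared code with the implementation
oracle_smooth <- function(x, wts, k) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  mirror <- function(p, n) {
    t <- (p - 1) %% (2 * n)
    if (t < n) t + 1 else 2 * n - t
  }
  out <- array(0, dim = d)
  nbh <- ceiling(H / k); nbw <- ceiling(W / k)
  for (n in seq_len(N)) for (c in seq_len(C)) {
    for (bh in seq_len(nbh)) for (bw in seq_len(nbw)) {
      s <- 0
      for (kw in seq_len(k)) for (kh in seq_len(k)) {
        p <- kh + k * (kw - 1)
        ih <- mirror((bh - 1) * k + kh, H)
        iw <- mirror((bw - 1) * k + kw, W)
        s <- s + wts[p, c, n] * x[ih, iw, c, n]
      }
      for (kw in seq_len(k)) for (kh in seq_len(k)) {
        ih <- (bh - 1) * k + kh; iw <- (bw - 1) * k + kw
        if (ih <= H && iw <= W) out[ih, iw, c, n] <- s
      }
    }
  }
  out
}

# exhaustive concordant-pair AUC (Mann-Whitney form, ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# spectral band energy of the gray channel around frequency f (cycles/image)
oracle_band_power <- function(img_gray, f, halfwidth = 1) {
  S <- nrow(img_gray)
  sp <- Mod(stats::fft(img_gray - mean(img_gray)))^2
  fx <- c(0:(S %/% 2), -((S - S %/% 2 - 1):1))
  r <- sqrt(outer(fx^2, fx^2, `+`))
  sum(sp[abs(r - f) <= halfwidth])
}

make_small_fit_data <- function(n_per_class = 8, size = 32, seed = 11) {
  synth_generate(synthetic_spec(num_classes = 4, samples_per_class = n_per_class,
                                image_size = size, seed = seed))
}
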