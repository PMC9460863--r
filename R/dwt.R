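# Periodized Daubechies-4 discrete wavelet transform and wavelet-shrinkage
# denoising. The 4-tap Daubechies filter is the shortest one with a vanishing
# moment beyond Haar, enough to pass the slow tonic component of a
# skin-conductance trace untouched while isolating broadband noise in the
# detail bands.

.db4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_g <- c(.db4_h[4], -.db4_h[3], .db4_h[2], -.db4_h[1])

# One periodized analysis step; x must have even length >= 4.
dwt_step <- function(x) {
  n <- length(x)
  i <- 2L * (seq_len(n %/% 2L) - 1L)           # 0-based even positions
  at <- function(off) x[((i + off) %% n) + 1L]
  a <- .db4_h[1] * at(0L) + .db4_h[2] * at(1L) +
       .db4_h[3] * at(2L) + .db4_h[4] * at(3L)
  d <- .db4_g[1] * at(0L) + .db4_g[2] * at(1L) +
       .db4_g[3] * at(2L) + .db4_g[4] * at(3L)
  list(approx = a, detail = d)
}

# Inverse of dwt_step (periodized synthesis).
idwt_step <- function(a, d) {
  n <- 2L * length(a)
  x <- numeric(n)
  i <- 2L * (seq_along(a) - 1L)
  for (k in 0:3) {
    p <- ((i + k) %% n) + 1L
    x[p] <- x[p] + .db4_h[k + 1L] * a + .db4_g[k + 1L] * d
  }
  x
}

# Multi-level periodized DWT. Length of x must be a multiple of 2^levels.
dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details, levels = levels)
}

idwt_db4 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a
}

soft_threshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)

# Wavelet-shrinkage denoising with the universal threshold
# sigma * sqrt(2 log n), sigma estimated robustly (MAD) from the finest
# detail band. The input is reflection-padded on the right to a multiple of
# 2^levels so arbitrary lengths are supported; output is truncated back.
wavelet_denoise <- function(x, levels = 5L) {
  n <- length(x)
  if (n < 8L) stop_emg("input_too_short", "need at least 8 samples to denoise")
  levels <- min(levels, max(1L, floor(log2(n / 4))))
  block <- 2L^levels
  n_pad <- ceiling(n / block) * block
  pad <- n_pad - n
  xp <- if (pad > 0L) c(x, x[n - seq_len(pad) + 1L]) else x
  dec <- dwt_db4(xp, levels)
  sigma <- stats::mad(dec$details[[1L]])
  thr <- sigma * sqrt(2 * log(n_pad))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  idwt_db4(dec)[seq_len(n)]
}
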