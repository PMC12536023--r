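# Shared fixtures for the test suite; everything is generated in code.

# A clean spectrum with a known alpha peak, on the default 0.2 Hz grid.
peak_psd <- function(center = 10, amplitude = 0.35, width = 1.2,
                     exponent = 1.2, noise_sd = 0, seed = NULL) {
  synth_psd(spectral_params(exponent = exponent, peak_center = center,
                            peak_amplitude = amplitude, peak_width = width,
                            noise_sd = noise_sd), seed = seed)
}

# Brute-force Gaussian peak search on a flattened spectrum: for every
# (center, width) pair on a fine grid the optimal amplitude is solved in
# closed form (the model is linear in amplitude), giving an independent
# oracle for the nonlinear least-squares fit.
grid_search_peak <- function(flat, band = c(7, 13),
                             center_step = 0.01,
                             widths = seq(0.2, 3, by = 0.05)) {
  keep <- flat$freqs >= band[1] & flat$freqs <= band[2]
  f <- flat$freqs[keep]
  y <- flat$ratio[keep] - 1
  centers <- seq(band[1], band[2], by = center_step)
  best <- list(sse = Inf)
  for (w in widths) {
    G <- exp(-outer(f, centers, "-")^2 / (2 * w^2))  # nf x nc basis
    num <- crossprod(y, G)                            # <y, g> per center
    den <- colSums(G^2)
    a <- pmax(0, as.numeric(num) / den)
    sse <- sum(y^2) - 2 * a * as.numeric(num) + a^2 * den
    i <- which.min(sse)
    if (sse[i] < best$sse)
      best <- list(sse = sse[i], center = centers[i], amplitude = a[i],
                   width = w)
  }
  best
}

# Micro-level estimate table over the full region map for one subject.
micro_table <- function(map, paf = 9.8, subject = "S001",
                        condition = "DR", diagnosis = "TD") {
  data.frame(subject = subject, diagnosis = diagnosis,
             condition = condition, micro = map$micro, paf_hz = paf,
             stringsAsFactors = FALSE)
}
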