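# Small-scale configurations used across tests. Fixtures are always built
# in code, never stored.

tiny_config <- function(...) {
  args <- list(n_subjects = 5, n_timepoints = 120, grid = c(8, 8, 6),
               n_wm = 60, n_csf = 40,
               networks = default_networks(voxels_per_parcel = 10))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Noise-free, nuisance-free configuration with unit coupling everywhere.
noiseless_config <- function(...) {
  conds <- default_conditions()
  nets <- default_networks(voxels_per_parcel = 10)
  a <- matrix(1, length(nets), nrow(conds),
              dimnames = list(names(nets), conds$name))
  sim_config(n_subjects = 3, n_timepoints = 120, grid = c(8, 8, 6),
             n_wm = 60, n_csf = 40, networks = nets, coupling = a,
             sigma_subject = 0, sigma_voxel = 0,
             nuisance = list(drift = 0, motion = 0, compartment = 0,
                             n_noise_rois = 2), ...)
}

# Brute-force periodogram via the explicit DFT sum (independent of fft()).
brute_periodogram <- function(x) {
  n <- length(x)
  t <- seq_len(n) - 1
  vapply(0:(n - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * t / n)))^2
  }, 0)
}

# Hand-executed Benjamini-Hochberg step-up rule: reject the hypotheses with
# the i smallest p values, where i is the largest index with
# p_(i) <= i * q / m.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

# Brute-force leave-one-out Pearson ISC via explicit sums.
loo_isc_oracle <- function(Z) {
  N <- nrow(Z)
  vapply(seq_len(N), function(i) {
    x <- Z[i, ]
    y <- colMeans(Z[-i, , drop = FALSE])
    xc <- x - mean(x)
    yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }, 0)
}
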