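# Shared fixtures: all synthetic, generated in code at test time.

# small bivariate-Gaussian sample with known mutual information
gaussian_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    list(x = x, y = y, mi_bits = -0.5 * log2(1 - rho^2))
  })
}

# delayed noisy copy: y_i = x_{i - delay} + noise
delayed_copy <- function(n, delay, noise_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n + delay)
    y <- x[seq_len(n)] + rnorm(n, sd = noise_sd)
    list(x = timeseries(x[(delay + 1):(delay + n)], dt = 0.001),
         y = timeseries(y, dt = 0.001))
  })
}

# write a small delimited fixture and return its path
write_fixture <- function(lines, ext = "txt") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}
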