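# Independent oracles and small fixture builders used across the suite.

# golden-section minimizer, independent of stats::optimize
golden_section <- function(f, lower, upper, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - gr * (b - a); d <- a + gr * (b - a)
  }
  (a + b) / 2
}

# exhaustive longest-run distribution for N fair coin flips
enumerate_longest_run <- function(N) {
  counts <- integer(N)  # counts[c] = number of sequences with max run == c
  for (x in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(x))[1:N]
    r <- rle(bits)
    counts[max(r$lengths)] <- counts[max(r$lengths)] + 1L
  }
  counts
}

# tiny synthetic instance shared by several tests
tiny_instance <- function(seed = 1, n = 3, sigma = 1) {
  lib <- make_profile_library(n, q = seq(0.01, 0.4, length.out = 40),
                              seed = seed)
  w <- rep(1, n) / n
  sim <- simulate_measurement(lib, seq_len(n), w,
                              noise_spec(sigma_scale = sigma,
                                         seed = seed + 100L))
  list(library = lib, curve = sim$curve, truth = sim$truth)
}

expect_simplex <- function(w, tol = 1e-9) {
  expect_true(all(w >= -tol))
  expect_lt(abs(sum(w) - 1), tol)
}
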