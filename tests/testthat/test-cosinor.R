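# Independent oracle: dense grid search over (M, A, phi) for the
# least-squares cosinor surface.
grid_search_sse <- function(t, y, period = 24,
                            M_grid, A_grid, phi_grid) {
  best <- Inf
  for (A in A_grid) {
    for (phi in phi_grid) {
      pred0 <- A * cos(2 * pi * (t - phi) / period)
      for (M in M_grid) {
        sse <- sum((y - M - pred0)^2)
        if (sse < best) best <- sse
      }
    }
  }
  best
}

sse_at <- function(t, y, M, A, phi, period = 24) {
  sum((y - M - A * cos(2 * pi * (t - phi) / period))^2)
}

test_that("constant input gives zero amplitude; planted cosinor is recovered exactly", {
  f0 <- fit_cosinor(seq(0, 47, by = 2), rep(5, 24))
  expect_equal(f0$mesor, 5)
  expect_equal(f0$amplitude, 0, tolerance = 1e-12)

  t <- 0:47
  y <- 10 + 2 * cos(2 * pi * (t - 8) / 24)
  f <- fit_cosinor(t, y)
  expect_equal(f$mesor, 10, tolerance = 1e-9)
  expect_equal(f$amplitude, 2, tolerance = 1e-9)
  expect_equal(f$acrophase, 8, tolerance = 1e-9)
  expect_lt(f$p_zero_amplitude, 1e-10)
})

test_that("closed-form fit never loses to a dense grid search", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(12:48, 1)
    t <- sort(runif(n, 0, 48))
    M <- runif(1, -5, 15); A <- runif(1, 0, 5); phi <- runif(1, 0, 24)
    y <- M + A * cos(2 * pi * (t - phi) / 24) + rnorm(n, 0, runif(1, 0.2, 2))
    f <- fit_cosinor(t, y)
    sse_fit <- sse_at(t, y, f$mesor, f$amplitude, f$acrophase)
    sse_grid <- grid_search_sse(
      t, y,
      M_grid = seq(min(y), max(y), length.out = 25),
      A_grid = seq(0, diff(range(y)), length.out = 25),
      phi_grid = seq(0, 24, length.out = 49)[-49])
    expect_lte(sse_fit, sse_grid + 1e-9)
  }
})

test_that("acrophase is shift-equivariant and amplitude mean-invariant", {
  set.seed(55)
  t <- sort(runif(30, 0, 48))
  y <- 3 + 1.5 * cos(2 * pi * (t - 17) / 24) + rnorm(30, 0, 0.5)
  f <- fit_cosinor(t, y)
  for (s in c(1.5, 7, 13)) {
    fs <- fit_cosinor(t + s, y)
    expect_equal(fs$acrophase, (f$acrophase + s) %% 24, tolerance = 1e-9)
    expect_equal(fs$amplitude, f$amplitude, tolerance = 1e-9)
    expect_equal(fs$mesor, f$mesor, tolerance = 1e-9)
  }
  fc <- fit_cosinor(t, y + 100)
  expect_equal(fc$mesor, f$mesor + 100, tolerance = 1e-9)
  expect_equal(fc$amplitude, f$amplitude, tolerance = 1e-9)
  expect_equal(fc$acrophase, f$acrophase, tolerance = 1e-9)
})

test_that("degenerate or short designs are rejected", {
  expect_error(fit_cosinor(c(0, 12, 24), c(1, 2, 3)), ">= 4 distinct")
  # all timestamps congruent modulo tau/2: rank-deficient design
  expect_error(fit_cosinor(c(0, 12, 24, 36, 48), rnorm(5)), "degenerate")
  expect_error(fit_cosinor(c(0, 1, 2, 3), rnorm(4)), "span")
})

test_that("zero-amplitude F-test holds its nominal type-I error", {
  set.seed(77)
  n_rep <- 400
  p <- replicate(n_rep, {
    t <- seq(0, 47, by = 2)
    fit_cosinor(t, rnorm(length(t)))$p_zero_amplitude
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("amplitude correlations recover planted shared profiles", {
  # identical per-subject amplitude profiles in two channels -> R2 = 100
  amp <- runif(6, 1, 3)
  fits <- tidyr::expand_grid(subject = paste0("S", 1:6),
                             channel = c("light", "hr")) |>
    dplyr::mutate(window_start = 0,
                  amplitude = rep(amp, each = 2),
                  acrophase = 10)
  ac <- amplitude_phase_correlation(fits, "amplitude")
  expect_equal(ac$r2_percent, 100, tolerance = 1e-9)

  # a zero-variance amplitude vector is skipped and flagged
  fits2 <- dplyr::mutate(fits,
                         amplitude = ifelse(channel == "hr", 2, amplitude))
  ac2 <- amplitude_phase_correlation(fits2, "amplitude")
  expect_false(ac2$tested)
  expect_true(is.na(ac2$p_bonferroni))
})

test_that("phase correlation recovers a planted 3 h offset across subjects", {
  set.seed(88)
  phi1 <- runif(12, 0, 24)
  phi2 <- (phi1 + 3) %% 24
  fits <- dplyr::bind_rows(
    tibble::tibble(subject = paste0("S", 1:12), channel = "light",
                   window_start = 0, amplitude = 1, acrophase = phi1),
    tibble::tibble(subject = paste0("S", 1:12), channel = "map",
                   window_start = 0, amplitude = 1, acrophase = phi2))
  pc <- amplitude_phase_correlation(fits, "phase")
  expect_gt(pc$r, 0.999)
  expect_equal(pc$offset_h, 3, tolerance = 1e-6)
  # noisy version still close
  fits$acrophase[fits$channel == "map"] <-
    (phi2 + rnorm(12, 0, 0.3)) %% 24
  pcn <- amplitude_phase_correlation(fits, "phase")
  expect_gt(pcn$r, 0.7)
  expect_equal(pcn$offset_h, 3, tolerance = 0.5)
  expect_lt(pcn$p_bonferroni, 0.05)
})
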