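flat_spectrum <- function(level = 5, n = 200) {
  tibble::tibble(specimen = "s1", replicate = 1L,
                 trace = list(tibble::tibble(mz = seq(2000, by = 1,
                                                      length.out = n),
                                             intensity = rep(level, n))))
}

test_that("SNIP equals the loop oracle and never exceeds the signal", {
  set.seed(91)
  for (i in 1:5) {
    y <- abs(rnorm(300, 10, 3)) + 50 * exp(-(seq_len(300) - 150)^2 / 20)
    b <- snip_baseline(y, 15)
    expect_equal(b, snip_oracle(y, 15), tolerance = 1e-12)
    expect_true(all(b <= y + 1e-12))
  }
  # flat signal: the baseline is the signal itself
  expect_equal(snip_baseline(rep(3, 100)), rep(3, 100))
})

test_that("narrow peaks survive the baseline step almost untouched", {
  n <- 400
  y <- rep(0, n)
  apex <- 200; half <- 6
  y[(apex - half):(apex + half)] <- c(seq(0, 30, length.out = half + 1),
                                      seq(30, 0, length.out = half + 1)[-1])
  b <- snip_baseline(y, 15)
  corrected <- y - b
  expect_gt(corrected[apex], 0.99 * y[apex])  # within 1% at the apex
})

test_that("preprocessing trims, normalises to unit TIC and reports noise", {
  sim <- simulate_spectra(n_specimens = 2, n_replicates = 2, seed = 92)
  pp <- preprocess(sim$spectra)
  for (tr in pp$trace) {
    expect_true(all(tr$mz >= 2000 & tr$mz <= 20000))
    expect_equal(sum(tr$intensity), 1, tolerance = 1e-9)
    expect_true(all(tr$intensity >= 0))
  }
  expect_true(all(pp$noise > 0))
  # too few points in range -> error
  short <- flat_spectrum(n = 10)
  expect_error(preprocess(short), "too few points")
})

test_that("replicate averaging is the pointwise mean", {
  grid <- seq(2000, 2004, by = 1)
  tr <- function(v) tibble::tibble(mz = grid, intensity = v)
  sp <- tibble::tibble(
    specimen = c("a", "a", "b"),
    replicate = c(1L, 2L, 1L),
    trace = list(tr(c(0, 2, 0, 2, 0)), tr(c(2, 0, 2, 0, 2)), tr(rep(1, 5))),
    noise = c(0.1, 0.3, 0.2))
  avg <- suppressMessages(average_technical_replicates(sp))
  expect_equal(avg$trace[[which(avg$specimen == "a")]]$intensity, rep(1, 5))
  expect_equal(avg$n_replicates, c(2L, 1L))
  expect_equal(avg$noise[avg$specimen == "a"], 0.2)
  # single replicate passes through unchanged
  expect_equal(avg$trace[[which(avg$specimen == "b")]]$intensity, rep(1, 5))

  # identical replicates average to themselves
  sp2 <- sp; sp2$trace <- list(tr(1:5), tr(1:5), tr(rep(1, 5)))
  avg2 <- suppressMessages(average_technical_replicates(sp2))
  expect_equal(avg2$trace[[which(avg2$specimen == "a")]]$intensity, 1:5)
})

test_that("peak detection finds isolated maxima above the SNR floor", {
  n <- 600
  grid <- seq(2000, by = 1, length.out = n)
  noise_level <- 0.5
  y <- rep(0, n)
  y[300] <- 20 * noise_level * 8        # lone spike, far above 8 x noise
  sp <- tibble::tibble(specimen = "s", trace = list(
    tibble::tibble(mz = grid, intensity = y)), noise = noise_level)
  pk <- detect_peaks(sp, snr = 8, half_window = 20)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, grid[300])

  # flat spectrum: nothing
  spf <- tibble::tibble(specimen = "s", trace = list(
    tibble::tibble(mz = grid, intensity = rep(1, n))), noise = 1)
  expect_equal(nrow(detect_peaks(spf)), 0)

  # two Gaussians 10 points apart within one 20-point window: taller wins
  y2 <- 10 * exp(-(seq_len(n) - 300)^2 / 8) + 6 * exp(-(seq_len(n) - 310)^2 / 8)
  sp2 <- tibble::tibble(specimen = "s", trace = list(
    tibble::tibble(mz = grid, intensity = y2)), noise = 0.1)
  pk2 <- detect_peaks(sp2, snr = 8, half_window = 20)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$mz, grid[300])
})

test_that("binning groups close peaks across specimens, splits within", {
  pk <- tibble::tibble(specimen = c("a", "b"), mz = c(5000.0, 5000.5),
                       intensity = c(1, 2))
  im <- bin_peaks(pk)
  expect_equal(ncol(as.matrix(im)), 1)
  expect_equal(im$bins$ref_mz, 5000.25)

  pk2 <- tibble::tibble(specimen = c("a", "b"), mz = c(5000, 6000),
                        intensity = c(1, 2))
  expect_equal(ncol(as.matrix(bin_peaks(pk2))), 2)

  # strict rule: same-specimen peaks always split, however close
  pk3 <- tibble::tibble(specimen = c("a", "a"), mz = c(5000.0, 5000.5),
                        intensity = c(1, 2))
  expect_equal(ncol(as.matrix(bin_peaks(pk3))), 2)

  expect_error(bin_peaks(pk, tolerance = 0), "tolerance")
})

test_that("binning is idempotent and ignores specimen input order", {
  set.seed(93)
  pk <- tibble::tibble(
    specimen = rep(sprintf("s%02d", 1:8), each = 5),
    mz = as.vector(vapply(1:8, function(i) {
      c(3000, 4500, 7000, 9000, 15000) * (1 + rnorm(5, 0, 5e-4))
    }, numeric(5))),
    intensity = runif(40))
  im <- bin_peaks(pk)
  # re-bin the binned representation: same bins back
  again <- tidy(im) |> dplyr::filter(.data$intensity > 0) |>
    dplyr::rename(mz = "bin")
  im2 <- bin_peaks(again)
  expect_equal(ncol(as.matrix(im2)), ncol(as.matrix(im)))

  shuf <- pk[sample(nrow(pk)), ]
  im3 <- bin_peaks(shuf)
  expect_equal(as.matrix(im3), as.matrix(im))
})

test_that("the noise floor zeroes sub-threshold cells only", {
  m <- matrix(c(1.0, 1.1, 0.5, 2.0), 2, 2,
              dimnames = list(c("a", "b"), c("3000.0000", "5000.0000")))
  im <- popconnect:::new_intensity_matrix(
    m, bins = tibble::tibble(ref_mz = c(3000, 5000), n_members = 2L),
    tolerance = 0.002)
  out <- suppressMessages(noise_floor_filter(im, noise_levels = c(0.5, 0.7)))
  # threshold = 1.75 * 0.6 = 1.05
  expect_equal(unname(as.matrix(out)[, 1]), c(0, 1.1))
  expect_equal(unname(as.matrix(out)[, 2]), c(0, 2.0))
  ident <- suppressMessages(noise_floor_filter(im, c(0.5, 0.7), factor = 0))
  expect_equal(as.matrix(ident), m)
})

test_that("Hellinger rows have unit sum of squares and match hand values", {
  m <- matrix(c(4, 1, 4), 1, 3,
              dimnames = list("a", c("3000.0000", "4000.0000", "5000.0000")))
  im <- popconnect:::new_intensity_matrix(
    m, bins = tibble::tibble(ref_mz = 3:5 * 1000, n_members = 1L),
    tolerance = 0.002)
  h <- hellinger(im)
  expect_equal(unname(as.matrix(h)[1, ]), c(2, 1, 2) / 3, tolerance = 1e-12)

  set.seed(94)
  m2 <- matrix(rexp(60), 6, 10)
  rownames(m2) <- paste0("s", 1:6); colnames(m2) <- sprintf("%.4f", 1:10 * 900 + 2000)
  im2 <- popconnect:::new_intensity_matrix(
    m2, bins = tibble::tibble(ref_mz = 1:10 * 900 + 2000, n_members = 1L),
    tolerance = 0.002)
  h2 <- hellinger(im2)
  expect_equal(unname(rowSums(as.matrix(h2)^2)), rep(1, 6), tolerance = 1e-9)
  # Euclidean distance on transformed rows = Hellinger distance on proportions
  p <- m2 / rowSums(m2)
  expect_equal(as.numeric(dist(as.matrix(h2))),
               as.numeric(dist(sqrt(p))), tolerance = 1e-9)

  # one-hot rows are fixed points; zero rows warn
  m3 <- rbind(a = c(0, 1, 0), b = c(0, 0, 0))
  colnames(m3) <- sprintf("%.4f", c(3000, 4000, 5000))
  im3 <- popconnect:::new_intensity_matrix(
    m3, bins = tibble::tibble(ref_mz = c(3000, 4000, 5000), n_members = 1L),
    tolerance = 0.002)
  expect_warning(h3 <- hellinger(im3), "all-zero")
  expect_equal(unname(as.matrix(h3)["a", ]), c(0, 1, 0))
  expect_equal(unname(as.matrix(h3)["b", ]), c(0, 0, 0))

  im3$intensity[1, 1] <- -1
  expect_error(hellinger(im3), "nonnegative")
})
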