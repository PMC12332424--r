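# MALDI-TOF spectral processing: trim, variance stabilisation, smoothing,
# SNIP baseline, TIC normalisation, peak detection, strict binning,
# noise floor and Hellinger transform.

#' Preprocess raw spectra
#'
#' Fixed pipeline order per spectrum: trim to the mass range -> square
#' root of intensities (variance stabilisation) -> Savitzky-Golay
#' smoothing (polynomial order `sg_order`, half-window `sg_half_window`
#' grid points) -> SNIP baseline estimation (`snip_iterations` clipping
#' passes with window equal to the iteration index) subtracted with
#' negative residuals clipped to zero -> total-ion-current normalisation
#' (divide by the intensity sum). The per-spectrum noise level is the
#' scaled median absolute deviation (factor 1.4826) of the final
#' baseline-corrected, TIC-normalised intensities.
#'
#' @param spectra Spectra tibble from [read_spectra()] (columns
#'   `specimen`, `replicate`, `trace`).
#' @param mass_range Numeric length-2 m/z window (default 2000-20000 Da).
#' @param sg_half_window Savitzky-Golay half-window in points (default 10).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param snip_iterations SNIP clipping passes (default 15).
#' @return The spectra tibble with processed `trace` and a `noise` column.
#' @export
preprocess <- function(spectra, mass_range = c(2000, 20000),
                       sg_half_window = 10, sg_order = 3,
                       snip_iterations = 15) {
  out <- spectra
  done <- purrr::map(spectra$trace, preprocess_trace,
                     mass_range = mass_range,
                     sg_half_window = sg_half_window, sg_order = sg_order,
                     snip_iterations = snip_iterations)
  out$trace <- purrr::map(done, "trace")
  out$noise <- purrr::map_dbl(done, "noise")
  out
}

preprocess_trace <- function(trace, mass_range, sg_half_window, sg_order,
                             snip_iterations) {
  keep <- trace$mz >= mass_range[1] & trace$mz <= mass_range[2]
  mz <- trace$mz[keep]
  y <- trace$intensity[keep]
  if (length(y) < 2 * sg_half_window + 1) {
    abort("too few points in the mass range for the smoothing window")
  }
  y <- sqrt(y)
  y <- signal::sgolayfilt(y, p = sg_order, n = 2 * sg_half_window + 1)
  base <- snip_baseline(y, iterations = snip_iterations)
  y <- pmax(y - base, 0)
  tot <- sum(y)
  if (tot > 0) y <- y / tot
  noise <- mad(y, constant = 1.4826)
  list(trace = tibble::tibble(mz = mz, intensity = y), noise = noise)
}

#' SNIP baseline estimate
#'
#' Statistics-sensitive nonlinear iterative peak clipping: starting from
#' the signal itself, each pass replaces every point by the minimum of
#' itself and the mean of its neighbours at distance `w`, with the
#' clipping window `w` growing with the iteration index (`w = i` for pass
#' `i`, capped at `iterations`). Indices beyond the ends are clamped. The
#' estimate is pointwise <= the input signal at every pass by
#' construction.
#'
#' @param y Numeric signal.
#' @param iterations Number of clipping passes (default 15).
#' @return Baseline vector of the same length.
#' @export
snip_baseline <- function(y, iterations = 15) {
  n <- length(y)
  b <- y
  for (i in seq_len(iterations)) {
    w <- min(i, iterations)
    left <- b[pmax(seq_len(n) - w, 1)]
    right <- b[pmin(seq_len(n) + w, n)]
    b <- pmin(b, (left + right) / 2)
  }
  b
}

#' Average technical replicates per specimen
#'
#' Pointwise mean of replicate traces. Replicates measured on different
#' m/z grids are first resampled to the union grid by linear
#' interpolation. Noise levels are averaged alongside; the replicate
#' count per specimen is logged.
#'
#' @param spectra Processed spectra tibble (see [preprocess()]).
#' @return A tibble with one row per specimen: `specimen`, `trace`,
#'   `noise`, `n_replicates`.
#' @export
average_technical_replicates <- function(spectra) {
  out <- spectra |>
    dplyr::group_by(.data$specimen) |>
    dplyr::summarise(
      trace = list(average_traces(.data$trace)),
      noise = if ("noise" %in% names(spectra)) mean(.data$noise) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop")
  inform(paste0("averaged replicates for ", nrow(out), " specimens (",
                paste(range(out$n_replicates), collapse = "-"),
                " replicates each)"))
  out
}

average_traces <- function(traces) {
  if (length(traces) == 1) return(traces[[1]])
  grids <- purrr::map(traces, "mz")
  same <- all(purrr::map_lgl(grids[-1], ~ identical(.x, grids[[1]])))
  if (same) {
    grid <- grids[[1]]
    ints <- purrr::map(traces, "intensity")
  } else {
    grid <- sort(unique(unlist(grids)))
    ints <- purrr::map(traces, function(tr) {
      stats::approx(tr$mz, tr$intensity, xout = grid, rule = 2)$y
    })
  }
  tibble::tibble(mz = grid,
                 intensity = Reduce(`+`, ints) / length(ints))
}

#' Detect peaks in processed spectra
#'
#' A point is a peak when it attains the maximum of its +-`half_window`
#' neighbourhood (ties resolved towards the lower m/z) and its intensity
#' exceeds `snr` times the spectrum's noise level.
#'
#' @param spectra Tibble with `specimen`, `trace`, `noise` columns
#'   (replicate-averaged or not).
#' @param snr Signal-to-noise threshold (default 8).
#' @param half_window Neighbourhood half-width in grid points (default 20).
#' @return A long tibble of peaks: `specimen`, `mz`, `intensity`.
#' @export
detect_peaks <- function(spectra, snr = 8, half_window = 20) {
  assert_that("noise" %in% names(spectra),
              "spectra must carry a noise column; run preprocess() first")
  purrr::pmap_dfr(spectra[c("specimen", "trace", "noise")],
                  function(specimen, trace, noise) {
    idx <- local_maxima(trace$intensity, half_window)
    idx <- idx[trace$intensity[idx] > snr * noise]
    tibble::tibble(specimen = specimen,
                   mz = trace$mz[idx],
                   intensity = trace$intensity[idx])
  })
}

local_maxima <- function(x, half_window) {
  n <- length(x)
  rmax <- x
  for (s in seq_len(half_window)) {
    rmax <- pmax(rmax,
                 x[pmax(seq_len(n) - s, 1)],
                 x[pmin(seq_len(n) + s, n)])
  }
  cand <- which(x == rmax & x > 0)
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    j <- cand[i]
    if (j - last <= half_window) next   # tie plateau: keep the leftmost
    keep[i] <- TRUE
    last <- j
  }
  cand[keep]
}

#' Bin peaks across specimens into shared features
#'
#' Pools all detected peaks, sorts by m/z, and recursively bisects at the
#' largest relative gap until every bin satisfies the strict rule: all
#' member peaks lie within `tolerance` (relative deviation) of the bin's
#' mean m/z, and no two peaks in a bin come from the same specimen. The
#' pass is repeated until the number of bins is stable, so the output is
#' a fixed point of re-binning. Bin reference = mean m/z of members.
#'
#' @param peaks Long peak tibble from [detect_peaks()].
#' @param tolerance Relative m/z tolerance (default 0.002).
#' @return An `intensity_matrix` (pre-Hellinger): specimens x bins, cell =
#'   member peak intensity or 0.
#' @export
bin_peaks <- function(peaks, tolerance = 0.002) {
  assert_that(tolerance > 0, "tolerance must be positive")
  assert_that(nrow(peaks) > 0, "no peaks to bin")
  pk <- peaks[order(peaks$mz, peaks$specimen), ]
  n_prev <- -1L
  repeat {
    bins <- split_bins(pk$mz, pk$specimen, tolerance)
    if (length(unique(bins)) == n_prev) break
    n_prev <- length(unique(bins))
  }
  pk$bin <- bins
  refs <- tapply(pk$mz, pk$bin, mean)
  ord <- order(refs)
  specimens <- sort(unique(pk$specimen))
  m <- matrix(0, length(specimens), length(refs),
              dimnames = list(specimens,
                              sprintf("%.4f", refs[ord])))
  bin_col <- match(pk$bin, names(refs)[ord])
  m[cbind(match(pk$specimen, specimens), bin_col)] <- pk$intensity
  new_intensity_matrix(m,
                       bins = tibble::tibble(
                         ref_mz = unname(refs[ord]),
                         n_members = as.integer(table(pk$bin)[ord])),
                       tolerance = tolerance)
}

# Recursive bisection over a sorted m/z vector; returns a bin id per peak.
split_bins <- function(mz, specimen, tolerance) {
  out <- character(length(mz))
  recurse <- function(idx, label) {
    m <- mz[idx]
    ok <- all(abs(m - mean(m)) / mean(m) <= tolerance) &&
      !anyDuplicated(specimen[idx])
    if (ok || length(idx) == 1) {
      out[idx] <<- label
      return(invisible())
    }
    gaps <- diff(m) / m[-length(m)]
    cut <- which.max(gaps)
    recurse(idx[seq_len(cut)], paste0(label, "L"))
    recurse(idx[(cut + 1):length(idx)], paste0(label, "R"))
  }
  recurse(seq_along(mz), "b")
  out
}

new_intensity_matrix <- function(m, bins, tolerance, hellinger = FALSE) {
  structure(list(intensity = m, bins = bins, tolerance = tolerance,
                 hellinger = hellinger),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("<intensity_matrix> ", nrow(x$intensity), " specimens x ",
      ncol(x$intensity), " binned peaks",
      if (x$hellinger) " (Hellinger-transformed)", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$intensity

#' @method tidy intensity_matrix
#' @export
tidy.intensity_matrix <- function(x, ...) {
  tibble::as_tibble(x$intensity, rownames = "specimen") |>
    tidyr::pivot_longer(-"specimen", names_to = "bin",
                        values_to = "intensity") |>
    dplyr::mutate(bin = as.numeric(.data$bin))
}

#' Zero out peaks below the spectral noise floor
#'
#' The floor is `factor` times the average of the per-spectrum noise
#' levels; matrix cells below it are set to zero. The count of zeroed
#' cells is reported.
#'
#' @param im An `intensity_matrix`.
#' @param noise_levels Per-spectrum noise estimates from [preprocess()].
#' @param factor Floor multiplier (default 1.75). `0` is the identity.
#' @param per_spectrum If `TRUE`, floor each specimen's row by its own
#'   noise level instead of the global mean.
#' @return The filtered `intensity_matrix`.
#' @export
noise_floor_filter <- function(im, noise_levels, factor = 1.75,
                               per_spectrum = FALSE) {
  m <- im$intensity
  if (per_spectrum) {
    assert_that(length(noise_levels) == nrow(m),
                "per-spectrum flooring needs one noise level per row")
    thr <- factor * noise_levels
    zero <- sweep(m, 1, thr, `<`)
  } else {
    thr <- factor * mean(noise_levels)
    zero <- m < thr
  }
  zero <- zero & m > 0
  m[zero] <- 0
  inform(paste0("noise floor zeroed ", sum(zero), " matrix cells"))
  im$intensity <- m
  im
}

#' Hellinger transform of an intensity matrix
#'
#' Row-wise `h = sqrt(x / rowSums(x))`; transformed rows have unit sum of
#' squares, so Euclidean distances on them equal Hellinger distances on
#' the raw proportions. All-zero rows are left at zero with a warning.
#'
#' @param im An `intensity_matrix` (nonnegative).
#' @return The transformed `intensity_matrix`.
#' @export
hellinger <- function(im) {
  m <- im$intensity
  assert_that(all(m >= 0), "Hellinger transform needs nonnegative input")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn(paste0(sum(rs == 0), " all-zero rows left at zero"))
  }
  nz <- rs > 0
  m[nz, ] <- sqrt(m[nz, , drop = FALSE] / rs[nz])
  im$intensity <- m
  im$hellinger <- TRUE
  im
}
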