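# Synthetic-data generators with known truth. They emulate the
# statistical structure the analysis tracks assume: deeply diverged
# heteroplasmic mtDNA lineages within one species, weakly differentiated
# admixed nuclear genotypes with basin-structured ancestry, and
# two-group mass spectra differing in relative peak intensity only.

SIM_BASINS_NORTH <- c("WEB", "GUB", "CVB")
SIM_BASINS_SOUTH <- c("AB", "CB")
SIM_BASIN_MIXED <- "BB"

# Fraction of sites to mutate so that the realised K2P distance between
# two sequences hits a target, under uniform substitution (Jukes-Cantor
# inversion; with random target bases transitions:transversions are 1:2
# and K2P reduces to the JC correction in expectation).
sites_for_distance <- function(d) 0.75 * (1 - exp(-4 * d / 3))

mutate_sites <- function(seq_chars, n_sites) {
  if (n_sites == 0) return(seq_chars)
  pos <- sample.int(length(seq_chars), n_sites)
  bases <- c("A", "C", "G", "T")
  seq_chars[pos] <- vapply(seq_chars[pos], function(b) {
    sample(setdiff(bases, b), 1)
  }, character(1))
  seq_chars
}

#' Simulate heteroplasmic mitochondrial sequences
#'
#' Emulates doubly uniparental inheritance: one ancestral sequence is
#' mutated along two deep branches into an F-type and an M-type root
#' separated by the target K2P divergence; specimens carry star-shaped
#' within-lineage variation around their root and emit either their F- or
#' their M-type sequence. Females always emit F; M-emitting specimens are
#' male.
#'
#' @param n_specimens Number of specimens (default 100).
#' @param seq_length Aligned length in bp (default 615, a standard COI
#'   barcode fragment).
#' @param divergence Target F/M K2P divergence (default 0.25; divergences
#'   above 0.7 are saturated and rejected).
#' @param within Target within-lineage pairwise K2P diversity
#'   (default 0.02).
#' @param m_fraction Fraction of specimens emitting the M-type
#'   (default 0.25).
#' @param marker Marker label for the alignment (default `"COI"`).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return List with `alignment` (an `aligned_sequences` tibble) and
#'   `truth` (tibble: `specimen`, `sex`, `lineage`, `basin`); the seed is
#'   recorded as an attribute of both.
#' @export
simulate_heteroplasmic_sequences <- function(n_specimens = 100,
                                             seq_length = 615,
                                             divergence = 0.25,
                                             within = 0.02,
                                             m_fraction = 0.25,
                                             marker = "COI",
                                             seed = 1) {
  assert_that(divergence <= 0.7,
              "divergence above 0.7 is saturated and unattainable")
  assert_that(divergence > within,
              "divergence must exceed within-lineage diversity")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root_f <- sample(bases, seq_length, replace = TRUE)
  root_m <- mutate_sites(root_f,
                         round(seq_length * sites_for_distance(divergence)))
  # Star phylogeny: each tip gets half the pairwise within-lineage
  # distance on its own branch.
  tip_sites <- sites_for_distance(within / 2)
  emit_m <- runif(n_specimens) < m_fraction
  sex <- ifelse(emit_m, "male",
                sample(c("female", "male"), n_specimens, replace = TRUE))
  basin <- sample(c(SIM_BASINS_NORTH, SIM_BASINS_SOUTH, SIM_BASIN_MIXED),
                  n_specimens, replace = TRUE)
  ids <- sprintf("sp%03d", seq_len(n_specimens))
  residues <- vapply(seq_len(n_specimens), function(i) {
    root <- if (emit_m[i]) root_m else root_f
    paste(mutate_sites(root, rbinom(1, seq_length, tip_sites)),
          collapse = "")
  }, character(1))
  aln <- as_aligned_sequences(
    tibble::tibble(specimen = ids, residues = residues), marker = marker)
  truth <- tibble::tibble(specimen = ids, sex = sex,
                          lineage = ifelse(emit_m, "M", "F"),
                          basin = basin)
  attr(aln, "seed") <- seed
  attr(truth, "seed") <- seed
  list(alignment = aln, truth = truth)
}

#' Simulate admixed diploid genotypes under a Balding-Nichols model
#'
#' Ancestral allele frequencies are Uniform(0.1, 0.9); each of `K` source
#' populations draws its frequency from a Balding-Nichols Beta,
#' `Beta(p (1-f)/f, (1-p) (1-f)/f)`, with the draw parameter `f`
#' calibrated (`f = K fst / (K - 1 + fst)`) so that the `fst` argument is
#' the expected G_ST measured among the sampled sources — i.e. the
#' differentiation an estimator should recover, not the raw Beta
#' dispersion. Individual i samples genotypes
#' `Binomial(2, sum_k Q_ik p_kl)`. A configurable fraction of individuals
#' is admixed (ancestry `Beta(2, 2)` between the sources for K = 2,
#' symmetric Dirichlet otherwise); the rest are unadmixed and split
#' evenly between sources. Basins are attached so that source-1
#' individuals sit in northern basins, source-2 individuals in southern
#' ones, and admixed individuals in the mixed basin, emulating
#' basin-structured ancestry. Missing calls are injected completely at
#' random, plus an optional block of high-missingness individuals to
#' exercise the filters.
#'
#' @param n_individuals Number of individuals (default 100).
#' @param n_loci Number of biallelic loci (default 1000).
#' @param K Number of source populations (default 2).
#' @param fst Balding-Nichols differentiation F (default 0.10; `0`
#'   collapses the sources onto shared frequencies, with a warning).
#' @param admixed_fraction Fraction of admixed individuals (default 0.3).
#' @param missing_rate Completely-at-random missingness (default 0.02).
#' @param n_high_missing Individuals given `high_missing_rate`
#'   missingness (default 0).
#' @param high_missing_rate Missingness of that block (default 0.85).
#' @param seed Integer seed.
#' @return List with `genotypes` (a `genotype_table`) and `truth`
#'   (tibble: `specimen`, `basin`, `admixed`, ancestry columns `Q1..QK`).
#' @export
simulate_admixed_genotypes <- function(n_individuals = 100, n_loci = 1000,
                                       K = 2, fst = 0.10,
                                       admixed_fraction = 0.3,
                                       missing_rate = 0.02,
                                       n_high_missing = 0,
                                       high_missing_rate = 0.85,
                                       seed = 1) {
  set.seed(seed)
  p_anc <- runif(n_loci, 0.1, 0.9)
  if (fst == 0) {
    warn("fst = 0: source populations collapse to shared frequencies")
    P <- matrix(rep(p_anc, each = K), K, n_loci)
  } else {
    # Calibrate the Balding-Nichols draw so that `fst` is the expected
    # G_ST measured AMONG the K sampled sources: K sources drawn with
    # parameter f have expected G_ST f(1-1/K)/(1-f/K), so invert it.
    f_draw <- K * fst / (K - 1 + fst)
    shape <- (1 - f_draw) / f_draw
    P <- t(vapply(p_anc, function(p) {
      rbeta(K, p * shape, (1 - p) * shape)
    }, numeric(K)))
    P <- t(P)
  }
  n_adm <- round(admixed_fraction * n_individuals)
  admixed <- seq_len(n_individuals) <= n_adm
  Q <- matrix(0, n_individuals, K)
  if (n_adm > 0) {
    if (K == 2) {
      q1 <- rbeta(n_adm, 2, 2)
      Q[admixed, ] <- cbind(q1, 1 - q1)
    } else {
      Q[admixed, ] <- t(vapply(seq_len(n_adm), function(i) {
        g <- stats::rgamma(K, 2); g / sum(g)
      }, numeric(K)))
    }
  }
  src <- rep(seq_len(K), length.out = n_individuals - n_adm)
  Q[!admixed, ][cbind(seq_len(n_individuals - n_adm), src)] <- 1
  pi_ <- Q %*% P
  G <- matrix(rbinom(n_individuals * n_loci, 2, pi_),
              n_individuals, n_loci)
  miss <- matrix(runif(n_individuals * n_loci) < missing_rate,
                 n_individuals, n_loci)
  if (n_high_missing > 0) {
    rows <- seq_len(min(n_high_missing, n_individuals))
    miss[rows, ] <- matrix(runif(length(rows) * n_loci) < high_missing_rate,
                           length(rows), n_loci)
  }
  G[miss] <- NA_integer_
  storage.mode(G) <- "integer"
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  loci <- sprintf("tag%04d:1", seq_len(n_loci))
  dominant <- max.col(Q)
  basin <- character(n_individuals)
  basin[admixed] <- SIM_BASIN_MIXED
  basin[!admixed & dominant == 1] <-
    sample(SIM_BASINS_NORTH, sum(!admixed & dominant == 1), replace = TRUE)
  basin[!admixed & dominant != 1] <-
    sample(SIM_BASINS_SOUTH, sum(!admixed & dominant != 1), replace = TRUE)
  g <- genotype_table(
    dosage = G, individuals = ids, loci = loci,
    sites = tibble::tibble(chrom = sprintf("tag%04d", seq_len(n_loci)),
                           pos = 1L, ref = "A", alt = "T"))
  truth <- tibble::tibble(specimen = ids, basin = basin, admixed = admixed)
  truth[paste0("Q", seq_len(K))] <- as.data.frame(Q)
  attr(truth, "seed") <- seed
  list(genotypes = g, truth = truth)
}

#' Simulate two-group MALDI-TOF spectra
#'
#' All specimens share one peak set (Gaussian peaks at log-spaced m/z
#' positions with TOF-like mass-proportional widths); a group-informative
#' subset has its amplitude scaled by `shift` in group B, so the groups
#' differ in relative peak intensity, never in peak presence. An
#' exponentially decaying chemical baseline and Gaussian detector noise
#' are added, and each technical replicate gets small multiplicative
#' amplitude jitter and sub-tolerance mass jitter.
#'
#' @param n_specimens Number of specimens, split evenly into groups A and
#'   B (default 120).
#' @param n_peaks Size of the shared peak set (default 40).
#' @param n_informative Peaks whose amplitude differs between groups
#'   (default 13; must not exceed `n_peaks`).
#' @param shift Amplitude factor applied to informative peaks in group B
#'   (default 3; `1` means no group signal).
#' @param noise_sd Detector noise standard deviation (default 1, versus
#'   baseline peak amplitudes around 60).
#' @param n_replicates Technical replicates per specimen (default 3).
#' @param mz_range m/z range of the grid (default 2000-20000, 1-Da
#'   spacing).
#' @param grid_step Grid spacing in Da (default 1).
#' @param seed Integer seed.
#' @return List with `spectra` (raw spectra tibble: `specimen`,
#'   `replicate`, `trace`) and `truth` (tibble: `specimen`, `group`).
#' @export
simulate_spectra <- function(n_specimens = 120, n_peaks = 40,
                             n_informative = 13, shift = 3,
                             noise_sd = 1, n_replicates = 3,
                             mz_range = c(2000, 20000), grid_step = 1,
                             seed = 1) {
  assert_that(n_informative <= n_peaks,
              "n_informative cannot exceed n_peaks")
  set.seed(seed)
  grid <- seq(mz_range[1], mz_range[2], by = grid_step)
  pos <- exp(seq(log(mz_range[1] * 1.1), log(mz_range[2] * 0.9),
                 length.out = n_peaks))
  widths <- pos * 0.0008            # TOF-like mass-proportional width
  amp <- exp(rnorm(n_peaks, log(60), 0.3))
  informative <- sample.int(n_peaks, n_informative)
  ids <- sprintf("sp%03d", seq_len(n_specimens))
  group <- rep(c("A", "B"), length.out = n_specimens)
  baseline <- 20 * exp(-(grid - mz_range[1]) / 4000)

  rows <- purrr::map(seq_len(n_specimens), function(i) {
    amp_i <- amp * exp(rnorm(n_peaks, 0, 0.15))
    if (group[i] == "B") {
      amp_i[informative] <- amp_i[informative] * shift
    }
    purrr::map(seq_len(n_replicates), function(r) {
      amp_r <- amp_i * exp(rnorm(n_peaks, 0, 0.05))
      pos_r <- pos * (1 + rnorm(n_peaks, 0, 0.0003))
      y <- baseline + rnorm(length(grid), 0, noise_sd)
      for (j in seq_len(n_peaks)) {
        win <- which(abs(grid - pos_r[j]) < 6 * widths[j])
        y[win] <- y[win] +
          amp_r[j] * exp(-(grid[win] - pos_r[j])^2 / (2 * widths[j]^2))
      }
      tibble::tibble(mz = grid, intensity = pmax(y, 0))
    })
  })
  spectra <- tibble::tibble(
    specimen = rep(ids, each = n_replicates),
    replicate = rep(seq_len(n_replicates), n_specimens),
    trace = purrr::flatten(rows))
  truth <- tibble::tibble(specimen = ids, group = group)
  attr(truth, "seed") <- seed
  list(spectra = spectra, truth = truth)
}
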