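# Genotype QC: missingness filters, polymorphism/singleton removal,
# LD pruning and mode imputation.

#' Filter a genotype table on missingness and polymorphism
#'
#' Applies, in order: (1) drop individuals whose fraction of missing calls
#' exceeds `ind_miss`; (2) drop loci whose missingness, computed on the
#' retained individuals, exceeds `loc_miss`; (3) drop non-polymorphic
#' loci; (4) drop singleton loci (minor allele observed exactly once).
#' Every step is recorded in a filter log whose removed + retained counts
#' reconcile with the input.
#'
#' @param g A `genotype_table` (see [read_genotype_vcf()]).
#' @param ind_miss Individual missingness ceiling (default 0.75).
#' @param loc_miss Locus missingness ceiling (default 0.20).
#' @return A `filtered_genotypes`: list with `dosage`, `individuals`,
#'   `loci`, `log` (tibble of per-rule counts), and empty LD-pruning slots.
#' @export
filter_genotypes <- function(g, ind_miss = 0.75, loc_miss = 0.20) {
  d <- g$dosage
  log <- list()
  note <- function(step, unit, removed, retained) {
    tibble::tibble(step = step, unit = unit,
                   removed = removed, retained = retained)
  }

  imiss <- rowMeans(is.na(d))
  keep_i <- imiss <= ind_miss
  log[[1]] <- note("individual_missingness", "individual",
                   sum(!keep_i), sum(keep_i))
  d <- d[keep_i, , drop = FALSE]

  lmiss <- colMeans(is.na(d))
  keep_l <- lmiss <= loc_miss
  log[[2]] <- note("locus_missingness", "locus", sum(!keep_l), sum(keep_l))
  d <- d[, keep_l, drop = FALSE]

  mac <- minor_allele_count(d)
  keep_p <- mac > 0
  log[[3]] <- note("non_polymorphic", "locus", sum(!keep_p), sum(keep_p))
  d <- d[, keep_p, drop = FALSE]
  mac <- mac[keep_p]

  keep_s <- mac != 1
  log[[4]] <- note("singleton", "locus", sum(!keep_s), sum(keep_s))
  d <- d[, keep_s, drop = FALSE]

  if (nrow(d) == 0 || ncol(d) == 0) {
    abort("all individuals or loci removed by filtering")
  }
  structure(list(dosage = d, individuals = rownames(d), loci = colnames(d),
                 log = dplyr::bind_rows(log), pruned = NULL, r2 = NULL),
            class = "filtered_genotypes")
}

minor_allele_count <- function(d) {
  alt <- colSums(d, na.rm = TRUE)
  total <- 2 * colSums(!is.na(d))
  pmin(alt, total - alt)
}

#' @export
print.filtered_genotypes <- function(x, ...) {
  cat("<filtered_genotypes> ", length(x$individuals), " individuals x ",
      length(x$loci), " loci\n", sep = "")
  print(x$log)
  if (!is.null(x$pruned)) {
    cat("LD-pruned subset: ", length(x$pruned), " loci (r2 <= ",
        x$r2, ")\n", sep = "")
  }
  invisible(x)
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy scan in locus order with a positional sliding window: a locus is
#' removed if its squared Pearson correlation of dosages (pairwise
#' complete) with any retained locus within the preceding `window`
#' positions exceeds `r2`. Deterministic given locus order; tag-based
#' loci without genome coordinates are handled by position in the table.
#'
#' @param fg A `filtered_genotypes`.
#' @param r2 Squared-correlation threshold (default 0.2).
#' @param window Window size in loci (default 50; must be >= 2).
#' @return `fg` with the retained subset recorded in `$pruned` and the
#'   threshold in `$r2`.
#' @export
prune_ld <- function(fg, r2 = 0.2, window = 50) {
  assert_that(window >= 2, "window must be at least 2 loci")
  d <- fg$dosage
  L <- ncol(d)
  kept <- logical(L)
  kept_idx <- integer(0)
  for (l in seq_len(L)) {
    cand <- kept_idx[kept_idx > l - window]
    drop <- FALSE
    for (k in cand) {
      r <- suppressWarnings(
        cor(d[, l], d[, k], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2) { drop <- TRUE; break }
    }
    if (!drop) { kept[l] <- TRUE; kept_idx <- c(kept_idx, l) }
  }
  fg$pruned <- fg$loci[kept]
  fg$r2 <- r2
  fg$window <- window
  fg
}

#' Impute missing genotypes by the per-locus modal dosage
#'
#' Each missing call is replaced by the most frequent dosage at its locus;
#' ties are broken towards the lower dosage. Deterministic and auditable,
#' which avoids feeding a model-based completion into the admixture model
#' that follows.
#'
#' @param fg A `filtered_genotypes`.
#' @param use_pruned If `TRUE` (default) and LD pruning has been run,
#'   impute only the pruned locus subset.
#' @return A complete individuals x loci numeric matrix with attribute
#'   `"n_imputed"`.
#' @export
impute_missing <- function(fg, use_pruned = TRUE) {
  loci <- if (use_pruned && !is.null(fg$pruned)) fg$pruned else fg$loci
  d <- fg$dosage[, loci, drop = FALSE]
  n_imp <- 0L
  for (l in seq_len(ncol(d))) {
    x <- d[, l]
    miss <- is.na(x)
    if (all(miss)) abort(paste0("locus fully missing: ", loci[l]))
    if (any(miss)) {
      counts <- tabulate(x[!miss] + 1L, nbins = 3L)
      mode_dosage <- which(counts == max(counts))[1] - 1L  # tie -> lower
      d[miss, l] <- mode_dosage
      n_imp <- n_imp + sum(miss)
    }
  }
  storage.mode(d) <- "double"
  attr(d, "n_imputed") <- n_imp
  d
}
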