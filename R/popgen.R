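# Differentiation statistics and discriminant analysis: Nei distances,
# Nei-Chesser corrected F_ST, Ward clustering and DAPC.

#' Nei's standard genetic distance
#'
#' `D = -ln(Jxy / sqrt(Jx Jy))` with the gene identities `Jx`, `Jy`,
#' `Jxy` accumulated over both alleles of all loci typed in both members
#' of a pair (pairwise-complete). At the individual level allele
#' frequencies are dosages/2; at the population level they are
#' group-level frequencies over a grouping vector. A pair with `Jxy = 0`
#' is flagged undefined (infinite distance).
#'
#' @param dosage Individuals x loci dosage matrix (`NA` = missing).
#' @param level `"individual"` or `"population"`.
#' @param groups For `level = "population"`, a grouping vector along the
#'   rows of `dosage` (e.g. basin labels).
#' @return A `pairdist` with `kind = "nei"`.
#' @export
nei_distance <- function(dosage, level = c("individual", "population"),
                         groups = NULL) {
  level <- match.arg(level)
  if (level == "individual") {
    p <- dosage / 2
    ids <- rownames(dosage) %||% paste0("ind", seq_len(nrow(dosage)))
  } else {
    assert_that(!is.null(groups), "population level needs a grouping vector")
    assert_that(length(groups) == nrow(dosage),
                "groups must match the rows of dosage")
    ids <- sort(unique(as.character(groups)))
    p <- t(vapply(ids, function(g) {
      colMeans(dosage[groups == g, , drop = FALSE], na.rm = TRUE) / 2
    }, numeric(ncol(dosage))))
    p[is.nan(p)] <- NA_real_
  }
  n <- nrow(p)
  d <- matrix(0, n, n)
  eff <- matrix(0L, n, n)
  undef <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ok <- !is.na(p[i, ]) & !is.na(p[j, ])
      eff[i, j] <- eff[j, i] <- sum(ok)
      if (!any(ok)) { undef[i, j] <- undef[j, i] <- TRUE; next }
      pi_ <- p[i, ok]; pj <- p[j, ok]
      jx <- sum(pi_^2 + (1 - pi_)^2)
      jy <- sum(pj^2 + (1 - pj)^2)
      jxy <- sum(pi_ * pj + (1 - pi_) * (1 - pj))
      if (jxy == 0) {
        d[i, j] <- d[j, i] <- Inf
        undef[i, j] <- undef[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx * jy))
      }
    }
  }
  diag(eff) <- rowSums(!is.na(p))
  new_pairdist(ids, d, eff, "nei", undefined = undef)
}

#' Pairwise Nei-Chesser corrected F_ST
#'
#' For each pair of groups and each locus, the unbiased gene-diversity
#' estimators of Nei & Chesser (1983) with harmonic-mean sample size
#' `n~`:
#' `Hs = n~/(n~-1) (1 - mean_s sum_a p_sa^2 - Ho/(2 n~))` and
#' `Ht = 1 - sum_a pbar_a^2 + Hs/(n~ s) - Ho/(2 n~ s)` with `s = 2`
#' groups and `Ho` the mean observed heterozygosity. The multi-locus
#' estimate is the ratio of averages `1 - mean(Hs)/mean(Ht)`; small
#' negative values are a legitimate outcome of the sample-size correction
#' and are retained.
#'
#' Loci with fewer than two typed individuals in either group are skipped
#' for that pair. A pair monomorphic across all usable loci gets 0 with a
#' warning.
#'
#' @param dosage Individuals x loci dosage matrix (`NA` = missing).
#' @param groups Grouping vector along the rows (>= 2 groups, each pair
#'   needing >= 2 typed individuals per locus to contribute).
#' @return A symmetric matrix of class `fst_matrix` with group dimnames.
#' @export
fst_nei_chesser <- function(dosage, groups) {
  groups <- as.character(groups)
  assert_that(length(groups) == nrow(dosage),
              "groups must match the rows of dosage")
  gl <- sort(unique(groups))
  assert_that(length(gl) >= 2, "need at least two groups")
  out <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (a in seq_along(gl)) {
    for (b in seq_len(a - 1)) {
      out[a, b] <- out[b, a] <-
        fst_pair(dosage[groups == gl[a], , drop = FALSE],
                 dosage[groups == gl[b], , drop = FALSE],
                 label = paste(gl[a], gl[b], sep = "-"))
    }
  }
  structure(out, class = c("fst_matrix", "matrix", "array"))
}

fst_pair <- function(da, db, label = "") {
  na_ <- colSums(!is.na(da))
  nb_ <- colSums(!is.na(db))
  use <- na_ >= 2 & nb_ >= 2
  if (!any(use)) {
    warn(paste0("no usable loci for pair ", label, "; F_ST set to 0"))
    return(0)
  }
  da <- da[, use, drop = FALSE]; db <- db[, use, drop = FALSE]
  na_ <- na_[use]; nb_ <- nb_[use]
  pa <- colMeans(da, na.rm = TRUE) / 2
  pb <- colMeans(db, na.rm = TRUE) / 2
  ho <- (colMeans(da == 1, na.rm = TRUE) + colMeans(db == 1, na.rm = TRUE)) / 2
  ntilde <- 2 / (1 / na_ + 1 / nb_)
  hs_obs <- 1 - ((pa^2 + (1 - pa)^2) + (pb^2 + (1 - pb)^2)) / 2
  hs <- ntilde / (ntilde - 1) * (hs_obs - ho / (2 * ntilde))
  pbar <- (pa + pb) / 2
  ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (2 * ntilde) - ho / (4 * ntilde)
  mean_ht <- mean(ht)
  if (mean_ht <= 0) {
    warn(paste0("pair ", label, " monomorphic across usable loci; F_ST = 0"))
    return(0)
  }
  1 - mean(hs) / mean_ht
}

#' @method tidy fst_matrix
#' @export
tidy.fst_matrix <- function(x, ...) {
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(group_a = rownames(x)[ut[, 1]],
                 group_b = colnames(x)[ut[, 2]],
                 fst = x[ut])
}

#' Ward clustering of Nei distances followed by DAPC
#'
#' Cuts a classic Ward ("ward.D" update on the distance matrix as given)
#' dendrogram of individual-level Nei distances into `n_clusters` groups,
#' then runs a discriminant analysis of principal components: PCA of the
#' centered dosage matrix, linear discriminant analysis of the top
#' `n_pc` PC scores onto the Ward clusters, and per-individual scores on
#' `n_df` discriminant axes.
#'
#' @param nei_ind An individual-level `pairdist` from [nei_distance()].
#' @param X Complete dosage matrix (same individuals, same order as the
#'   distance ids after name matching).
#' @param n_clusters Number of Ward clusters (default 3).
#' @param n_pc Retained principal components (default 10; must be fewer
#'   than the number of individuals).
#' @param n_df Discriminant functions (default 2; capped at
#'   `n_clusters - 1`).
#' @return A `dapc_fit`: list with `clusters` (tibble), `scores` (tibble
#'   of discriminant coordinates), `pca`, `lda`, and the parameters used.
#' @export
ward_dapc <- function(nei_ind, X, n_clusters = 3, n_pc = 10, n_df = 2) {
  assert_that(!any(nei_ind$undefined), "distance matrix has undefined pairs")
  hc <- hclust(as.dist(nei_ind$d), method = "ward.D")
  labels <- cutree(hc, k = n_clusters)
  if (n_clusters == 1) {
    abort("DAPC needs at least two clusters; Ward labels are a single group")
  }
  n <- nrow(X)
  assert_that(n_pc < n, "n_pc must be smaller than the number of individuals")
  X <- X[nei_ind$ids, , drop = FALSE]
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$x))
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]
  n_df <- min(n_df, n_clusters - 1)
  fit <- MASS::lda(scores, grouping = factor(labels))
  ld <- predict(fit, scores)$x[, seq_len(n_df), drop = FALSE]
  structure(list(
    clusters = tibble::tibble(specimen = nei_ind$ids,
                              cluster = paste0("C", labels)),
    scores = tibble::as_tibble(ld) |>
      dplyr::mutate(specimen = nei_ind$ids, .before = 1),
    hclust = hc, pca = pca, lda = fit,
    n_clusters = n_clusters, n_pc = n_pc, n_df = n_df),
    class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("<dapc_fit> ", nrow(x$clusters), " individuals, ",
      x$n_clusters, " Ward clusters, ", x$n_pc, " PCs, ",
      x$n_df, " discriminant functions\n", sep = "")
  print(table(x$clusters$cluster))
  invisible(x)
}

#' @method tidy dapc_fit
#' @export
tidy.dapc_fit <- function(x, ...) {
  dplyr::left_join(x$clusters, x$scores, by = "specimen")
}

#' Basin-level connectivity table
#'
#' Summarises an admixture ensemble and an F_ST matrix at basin level for
#' connectivity maps: per basin the mean ancestry vector and sample size,
#' per basin pair the F_ST and a line weight `1 / max(F_ST, eps)` so that
#' weakly differentiated basins draw thick connections.
#'
#' @param ensemble An `admixture_ensemble`.
#' @param K Which K's mean ancestry to summarise.
#' @param fst An `fst_matrix` over basins.
#' @param metadata Tibble with `specimen` and `basin` columns.
#' @param basin_coords Optional tibble with `basin`, `lon`, `lat`;
#'   basins without coordinates are kept with a warning.
#' @param eps Differentiation floor for the weight (default 1e-4).
#' @return List of two tibbles: `basins` (mean ancestry, n, coordinates)
#'   and `pairs` (fst, weight).
#' @export
connectivity_map_data <- function(ensemble, K, fst, metadata,
                                  basin_coords = NULL, eps = 1e-4) {
  b <- ensemble$by_k[[paste0("K", K)]]
  assert_that(!is.null(b), paste0("ensemble has no K = ", K))
  Q <- b$Q_mean
  meta <- metadata[match(rownames(Q), metadata$specimen), ]
  assert_that(!anyNA(meta$specimen), "metadata missing some individuals")
  basins <- tibble::as_tibble(Q, rownames = "specimen") |>
    dplyr::mutate(basin = meta$basin) |>
    dplyr::group_by(.data$basin) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("K"), mean),
                     n = dplyr::n(), .groups = "drop")
  if (!is.null(basin_coords)) {
    missing <- setdiff(basins$basin, basin_coords$basin)
    if (length(missing) > 0) {
      warn(paste0("no coordinates for basins: ",
                  paste(missing, collapse = ", ")))
    }
    basins <- dplyr::left_join(basins, basin_coords, by = "basin")
  }
  pairs <- tidy.fst_matrix(fst) |>
    dplyr::mutate(weight = 1 / pmax(.data$fst, eps))
  list(basins = basins, pairs = pairs)
}
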