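# Multivariate analysis of the binned intensity matrix: hierarchical
# clustering, k-means/BIC group finding (DAPC-style) and random-forest
# classification with permutation importances.

#' Cluster specimens from a Hellinger-transformed intensity matrix
#'
#' Builds (1) a hierarchical-clustering dendrogram on Euclidean distances
#' between specimen rows and (2) DAPC-style k-means groups: PCA of the
#' matrix, k-means for k = 1..`k_max` on all PC scores with `nstart`
#' restarts each, and the Bayesian Information Criterion
#' `BIC_k = n log(WSS_k / n) + k log(n)` to pick the reported optimum.
#'
#' @param im An `intensity_matrix` (>= 3 specimens).
#' @param linkage Hierarchical linkage (default `"complete"`).
#' @param k_max Largest k tried (default 10; clipped below n with a
#'   warning).
#' @param nstart Random restarts per k (default 50).
#' @param seed Seed for the k-means restarts.
#' @return A `maldi_clustering`: list with `hclust`, `bic` (tibble of k,
#'   WSS, BIC), `k_opt`, `groups` (tibble of k-means labels at the
#'   optimum), `pca`.
#' @export
cluster_specimens <- function(im, linkage = "complete", k_max = 10,
                              nstart = 50, seed = 1) {
  m <- as.matrix(im)
  n <- nrow(m)
  assert_that(n >= 3, "need at least three specimens")
  n_distinct <- nrow(unique(m))
  k_hi <- min(n - 1, n_distinct)
  if (k_max > k_hi) {
    warn(paste0("k_max clipped from ", k_max, " to ", k_hi))
    k_max <- k_hi
  }
  hc <- hclust(dist(m), method = linkage)
  pca <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pca$x                        # all min(n-1, features) PCs
  set.seed(seed)
  fits <- purrr::map(seq_len(k_max), function(k) {
    suppressWarnings(kmeans(scores, centers = k, nstart = nstart,
                            iter.max = 100))
  })
  wss <- purrr::map_dbl(fits, "tot.withinss")
  bic <- n * log(wss / n) + seq_len(k_max) * log(n)
  k_opt <- which.min(bic)
  structure(list(
    hclust = hc,
    bic = tibble::tibble(k = seq_len(k_max), wss = wss, bic = bic),
    k_opt = k_opt,
    groups = tibble::tibble(specimen = rownames(m),
                            group = paste0("G", fits[[k_opt]]$cluster)),
    pca = pca),
    class = "maldi_clustering")
}

#' @export
print.maldi_clustering <- function(x, ...) {
  cat("<maldi_clustering> ", length(x$hclust$order),
      " specimens; BIC optimum k = ", x$k_opt, "\n", sep = "")
  print(table(x$groups$group))
  invisible(x)
}

#' @method glance maldi_clustering
#' @export
glance.maldi_clustering <- function(x, ...) {
  tibble::tibble(n = length(x$hclust$order), k_opt = x$k_opt,
                 bic_min = min(x$bic$bic))
}

#' Write the dendrogram of a clustering as Newick
#'
#' @param clustering A `maldi_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Random-forest classification of specimens into groups
#'
#' Fits a random forest on the intensity matrix, reporting the out-of-bag
#' error, per-specimen out-of-bag class probabilities, and unscaled
#' permutation importances (mean decrease in out-of-bag accuracy when a
#' feature is permuted). Top peaks are the features whose importance
#' exceeds `cutoff`, in rank order, capped at `max_top`.
#'
#' @param im An `intensity_matrix`.
#' @param groups Group label per specimen (named by specimen, or in the
#'   row order of the matrix); >= 2 groups with >= 3 members each.
#' @param trees Number of trees (default 10000).
#' @param vars_per_split Variables tried per split (default 22; clipped to
#'   the feature count with a warning).
#' @param seed Seed for the forest.
#' @param cutoff Importance cutoff for the selected peak set
#'   (default 0.0006).
#' @param max_top Cap on the number of selected peaks (default 13).
#' @return A `classifier_report`: list with `oob_error`, `probabilities`
#'   (tibble), `importance` (tibble, rank order), `top_peaks`, `forest`.
#' @export
rf_classify <- function(im, groups, trees = 10000, vars_per_split = 22,
                        seed = 1, cutoff = 0.0006, max_top = 13) {
  m <- as.matrix(im)
  if (!is.null(names(groups))) groups <- groups[rownames(m)]
  y <- factor(groups)
  assert_that(length(y) == nrow(m), "one group label per specimen required")
  tab <- table(y)
  assert_that(length(tab) >= 2, "need at least two groups")
  assert_that(all(tab >= 3), "every group needs at least three members")
  if (vars_per_split > ncol(m)) {
    warn(paste0("vars_per_split clipped from ", vars_per_split, " to ",
                ncol(m)))
    vars_per_split <- ncol(m)
  }
  colnames(m) <- make.names(colnames(m))
  set.seed(seed)
  rf <- randomForest::randomForest(m, y, ntree = trees,
                                   mtry = vars_per_split,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  imp_tbl <- tibble::tibble(
    bin = as.numeric(sub("^X", "", names(imp))),
    importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  top <- imp_tbl |>
    dplyr::filter(.data$importance > cutoff) |>
    dplyr::slice_head(n = max_top)
  structure(list(
    oob_error = unname(rf$err.rate[trees, "OOB"]),
    probabilities = tibble::as_tibble(rf$votes, rownames = "specimen"),
    importance = imp_tbl,
    top_peaks = top,
    cutoff = cutoff,
    forest = rf),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> OOB error ", sprintf("%.3f", x$oob_error), "; ",
      nrow(x$top_peaks), " peaks above the importance cutoff of ",
      x$cutoff, "\n", sep = "")
  invisible(x)
}

#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) x$importance

#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(oob_error = x$oob_error,
                 n_top_peaks = nrow(x$top_peaks),
                 trees = x$forest$ntree,
                 mtry = x$forest$mtry)
}
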