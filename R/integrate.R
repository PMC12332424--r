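# Cross-track concordance: do mitotypes line up with nuclear or proteomic
# groupings? The overlay itself is visual; the association statistic here
# (Cramer's V with a permutation p-value) quantifies it.

#' Cross-tabulate two specimen labellings and test association
#'
#' Builds the contingency table of two label vectors over their shared
#' specimens, excluding indeterminate labels (categories with a single
#' member), and reports the chi-square statistic, Cramer's V and a
#' permutation p-value obtained by shuffling the second labelling.
#'
#' @param labels_a,labels_b Named character vectors (names = specimen ids)
#'   or two-column data frames (`specimen`, label).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed for the permutations.
#' @return A `concordance` object: list with `table`, `chisq`,
#'   `cramers_v`, `p_value`, `n_perm`, `seed`, `n`.
#' @export
crosstab <- function(labels_a, labels_b, n_perm = 9999, seed = 1) {
  a <- as_label_vector(labels_a)
  b <- as_label_vector(labels_b)
  shared <- intersect(names(a), names(b))
  assert_that(length(shared) > 0, "no shared specimen ids")
  a <- a[shared]; b <- b[shared]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  # Indeterminate categories: singletons on either margin are excluded,
  # as single-specimen lineages carry no population-level signal.
  a_ok <- names(which(table(a) > 1))
  b_ok <- names(which(table(b) > 1))
  keep <- a %in% a_ok & b %in% b_ok
  a <- a[keep]; b <- b[keep]
  assert_that(length(unique(a)) >= 2 && length(unique(b)) >= 2,
              "need at least two categories on both margins")
  tab <- table(a, b)
  stat <- cramer_stats(tab)
  set.seed(seed)
  perm_v <- replicate(n_perm, cramer_stats(table(a, sample(b)))$chisq)
  p <- (1 + sum(perm_v >= stat$chisq)) / (n_perm + 1)
  structure(list(table = tab, chisq = stat$chisq,
                 cramers_v = stat$v, p_value = p,
                 n_perm = n_perm, seed = seed, n = length(a)),
            class = "concordance")
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    assert_that("specimen" %in% names(x),
                "label data frames need a 'specimen' column")
    lab_col <- setdiff(names(x), "specimen")[1]
    return(setNames(as.character(x[[lab_col]]), x$specimen))
  }
  assert_that(!is.null(names(x)), "label vectors must be named by specimen")
  as.character(x) |> setNames(names(x))
}

cramer_stats <- function(tab) {
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chisq <- sum((tab - expected)^2 / expected)
  k <- min(nrow(tab), ncol(tab)) - 1
  list(chisq = chisq, v = sqrt(chisq / (n * k)))
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance> n = ", x$n, ", Cramer's V = ",
      sprintf("%.3f", x$cramers_v), ", permutation p = ",
      format(x$p_value, digits = 3), " (", x$n_perm, " permutations)\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' @method glance concordance
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(n = x$n, chisq = x$chisq, cramers_v = x$cramers_v,
                 p_value = x$p_value, n_perm = x$n_perm)
}

#' Summarise mean ancestry by group
#'
#' Per group (e.g. basin or mitotype): the mean ancestry vector, the
#' fraction of individuals whose largest ancestry component is >= 0.9
#' (i.e. essentially unadmixed individuals), and the sample size.
#'
#' @param ensemble An `admixture_ensemble`.
#' @param K Which K's mean ancestries to use.
#' @param grouping Named character vector (names = specimen ids) or a
#'   data frame with `specimen` plus one label column.
#' @return A tibble with one row per group.
#' @export
ancestry_by_group <- function(ensemble, K, grouping) {
  b <- ensemble$by_k[[paste0("K", K)]]
  assert_that(!is.null(b), paste0("ensemble has no K = ", K))
  g <- as_label_vector(grouping)
  Q <- b$Q_mean
  missing <- setdiff(rownames(Q), names(g))
  assert_that(length(missing) == 0,
              paste0("unknown group label for: ",
                     paste(missing, collapse = ", ")))
  tibble::as_tibble(Q, rownames = "specimen") |>
    dplyr::mutate(group = unname(g[.data$specimen]),
                  max_ancestry = apply(Q, 1, max)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("K"), mean),
                     fraction_unadmixed = mean(.data$max_ancestry >= 0.9),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select(-dplyr::any_of("max_ancestry"))
}
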