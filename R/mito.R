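# Mitochondrial mitotyping: substitution counts, K2P distances,
# single-linkage lineage delimitation and haplotype networks.

# Encode residues as integers: A=1, C=2, G=3, T=4; N/gap/other -> NA.
# Sites with NA in either sequence of a pair are excluded (pairwise
# deletion), as in the usual distance-software default.
encode_alignment <- function(aln) {
  chars <- strsplit(aln$residues, "", fixed = TRUE)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  mat <- t(vapply(chars, function(x) unname(code[x]), integer(nchar(aln$residues[1]))))
  rownames(mat) <- aln$specimen
  mat
}

pair_site_stats <- function(mat) {
  n <- nrow(mat)
  ids <- rownames(mat)
  eff <- ts_ <- tv_ <- matrix(0, n, n, dimnames = list(ids, ids))
  purine <- matrix(mat %in% c(1L, 3L), nrow = n)
  for (i in seq_len(n - 1)) {
    xi <- mat[i, ]
    pi_ <- purine[i, ]
    for (j in (i + 1):n) {
      xj <- mat[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      ne <- sum(ok)
      df <- ok & (xi != xj)
      same_class <- pi_ == purine[j, ]
      nts <- sum(df & same_class)
      eff[i, j] <- eff[j, i] <- ne
      ts_[i, j] <- ts_[j, i] <- nts
      tv_[i, j] <- tv_[j, i] <- sum(df) - nts
    }
  }
  diag(eff) <- rowSums(!is.na(mat))
  list(ids = ids, eff = eff, transitions = ts_, transversions = tv_)
}

new_pairdist <- function(ids, d, eff, kind, P = NULL, Q = NULL,
                         undefined = NULL) {
  if (is.null(undefined)) undefined <- matrix(FALSE, length(ids), length(ids))
  dimnames(d) <- dimnames(undefined) <- list(ids, ids)
  structure(list(ids = ids, d = d, eff = eff, kind = kind, P = P, Q = Q,
                 undefined = undefined),
            class = "pairdist")
}

#' @export
print.pairdist <- function(x, ...) {
  cat("<pairdist> ", length(x$ids), " sequences, kind = ", x$kind, "; ",
      sum(x$undefined[upper.tri(x$undefined)]), " undefined pairs\n",
      sep = "")
  invisible(x)
}

#' Pairwise substitution counts between aligned sequences
#'
#' Counts, for every pair, the sites at which both residues are unambiguous
#' nucleotides and differ; sites with `N` or a gap in either sequence are
#' excluded (pairwise deletion) and the per-pair effective site count is
#' recorded. Pairs with zero effective sites are flagged undefined.
#'
#' @param aln An `aligned_sequences` tibble.
#' @return A `pairdist` object with `kind = "substitution_count"`.
#' @export
substitution_counts <- function(aln) {
  st <- pair_site_stats(encode_alignment(aln))
  d <- st$transitions + st$transversions
  undef <- st$eff == 0
  diag(undef) <- FALSE
  d[undef] <- NA_real_
  new_pairdist(st$ids, d, st$eff, "substitution_count", undefined = undef)
}

#' Pairwise Kimura-2-parameter distances
#'
#' For each pair, with transition proportion `P` and transversion
#' proportion `Q` over the effective (pairwise-deleted) sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Pairs where a logarithm
#' argument is non-positive (substitution saturation) or where no sites
#' are comparable are flagged undefined rather than dropped.
#'
#' @param aln An `aligned_sequences` tibble.
#' @return A `pairdist` object with `kind = "K2P"` carrying `P` and `Q`.
#' @export
k2p_matrix <- function(aln) {
  st <- pair_site_stats(encode_alignment(aln))
  P <- st$transitions / st$eff
  Q <- st$transversions / st$eff
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  undef <- (st$eff == 0) | a1 <= 0 | a2 <= 0
  diag(undef) <- FALSE
  a1[a1 <= 0] <- NA_real_
  a2[a2 <= 0] <- NA_real_
  d <- -0.5 * log(a1) - 0.25 * log(a2)
  d[undef] <- NA_real_
  diag(d) <- 0
  P[st$eff == 0] <- NA_real_
  Q[st$eff == 0] <- NA_real_
  if (any(undef)) {
    inform(paste0(sum(undef[upper.tri(undef)]),
                  " sequence pairs have undefined K2P distance"))
  }
  new_pairdist(st$ids, d, st$eff, "K2P", P = P, Q = Q, undefined = undef)
}

#' @method tidy pairdist
#' @export
tidy.pairdist <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  out <- tibble::tibble(
    specimen_a = x$ids[ut[, 1]],
    specimen_b = x$ids[ut[, 2]],
    distance = x$d[ut],
    effective_sites = x$eff[ut],
    undefined = x$undefined[ut]
  )
  if (x$kind == "K2P") {
    out$P <- x$P[ut]
    out$Q <- x$Q[ut]
  }
  out
}

#' Delimit mitotypes by single-linkage clustering of a distance matrix
#'
#' Cuts a single-linkage dendrogram at a distance threshold; the resulting
#' clusters are the mitochondrial lineage groups ("mitotypes"). Undefined
#' distances are treated as above-threshold (never linking) and logged.
#' Clusters are relabelled `MT1`, `MT2`, ... by descending size, ties
#' broken by the lexically smallest member id, matching the convention
#' that MT1 is the largest lineage.
#'
#' @param dist A `pairdist` (K2P by default, substitution counts also work).
#' @param threshold Linkage cut height. Default 0.05, motivated by observed
#'   within-mitotype K2P maxima around 0.04-0.05 against a minimum
#'   between-mitotype distance of 0.06 on the defining COI marker.
#' @return A tibble of class `mitotype_partition` with columns `specimen`,
#'   `mitotype`.
#' @export
delimit_mitotypes <- function(dist, threshold = 0.05) {
  d <- dist$d
  if (any(dist$undefined)) {
    inform(paste0(sum(dist$undefined[upper.tri(dist$undefined)]),
                  " undefined distances treated as above-threshold"))
    big <- max(d[!dist$undefined & is.finite(d)], threshold, na.rm = TRUE)
    d[dist$undefined] <- big + 2 * threshold + 1
  }
  n <- length(dist$ids)
  if (n == 1) {
    member <- setNames(1L, dist$ids)
  } else {
    hc <- hclust(as.dist(d), method = "single")
    member <- cutree(hc, h = threshold)
  }
  relabelled <- relabel_by_size(member, dist$ids, prefix = "MT")
  structure(
    tibble::tibble(specimen = dist$ids, mitotype = relabelled),
    class = c("mitotype_partition", class(tibble::tibble())),
    threshold = threshold, kind = dist$kind,
    sizes = table(relabelled)
  )
}

# Relabel integer cluster memberships as <prefix>1.. by descending size;
# ties broken by the lexically smallest member id.
relabel_by_size <- function(member, ids, prefix = "MT") {
  groups <- split(ids, member)
  size <- lengths(groups)
  first_id <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-size, first_id)
  map <- setNames(paste0(prefix, seq_along(ord)), names(groups)[ord])
  unname(map[as.character(member)])
}

#' Transfer mitotype labels to another marker's specimens
#'
#' Mitotypes are defined on the more divergent marker (COI) and inherited
#' by shared specimen ids on a second marker (16S). Specimens absent from
#' the source partition remain unlabelled (`NA`) and are reported.
#'
#' @param partition A `mitotype_partition` from the defining marker.
#' @param aln_dst An `aligned_sequences` tibble for the destination marker.
#' @return A `mitotype_partition` over the destination specimens.
#' @export
transfer_mitotypes <- function(partition, aln_dst) {
  shared <- intersect(partition$specimen, aln_dst$specimen)
  assert_that(length(shared) > 0,
              "no specimen ids shared between partition and alignment")
  map <- setNames(partition$mitotype, partition$specimen)
  lab <- unname(map[aln_dst$specimen])
  missing <- aln_dst$specimen[is.na(lab)]
  if (length(missing) > 0) {
    inform(paste0(length(missing), " specimens unlabelled (absent from the ",
                  "source partition): ", paste(missing, collapse = ", ")))
  }
  structure(
    tibble::tibble(specimen = aln_dst$specimen, mitotype = lab),
    class = c("mitotype_partition", class(tibble::tibble())),
    threshold = attr(partition, "threshold"),
    kind = "transferred",
    sizes = table(lab)
  )
}

#' Summarize K2P distances within and between mitotypes
#'
#' Produces the classic min-max table: one row per mitotype (within) and
#' one per mitotype pair (between), rendered to two decimals. A singleton
#' mitotype has within range 0.00-0.00.
#'
#' @param dist A `pairdist`.
#' @param partition A `mitotype_partition` covering the matrix ids.
#' @return A tibble with columns `mitotype_a`, `mitotype_b`, `type`,
#'   `min`, `max`, `label`.
#' @export
mitotype_distance_summary <- function(dist, partition) {
  lab <- setNames(partition$mitotype, partition$specimen)
  assert_that(all(dist$ids %in% partition$specimen),
              "partition does not cover all matrix ids")
  li <- lab[dist$ids]
  mts <- unique(partition$mitotype[order(
    as.integer(sub("^MT", "", partition$mitotype)))])
  rows <- list()
  for (a in seq_along(mts)) {
    for (b in seq_len(a)) {
      ia <- which(li == mts[a]); ib <- which(li == mts[b])
      if (a == b) {
        if (length(ia) == 1) {
          lo <- hi <- 0
        } else {
          vals <- dist$d[ia, ia][upper.tri(diag(length(ia)))]
          vals <- vals[!is.na(vals)]
          lo <- min(vals); hi <- max(vals)
        }
        type <- "within"
      } else {
        vals <- as.vector(dist$d[ia, ib])
        vals <- vals[!is.na(vals)]
        lo <- min(vals); hi <- max(vals)
        type <- "between"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        mitotype_a = mts[a], mitotype_b = mts[b], type = type,
        min = lo, max = hi,
        label = sprintf("%.2f-%.2f", lo, hi))
    }
  }
  dplyr::bind_rows(rows)
}

#' @method tidy mitotype_partition
#' @export
tidy.mitotype_partition <- function(x, ...) tibble::as_tibble(x)

#' @method glance mitotype_partition
#' @export
glance.mitotype_partition <- function(x, ...) {
  tibble::tibble(
    n_specimens = nrow(x),
    n_mitotypes = length(unique(na.omit(x$mitotype))),
    largest = max(table(x$mitotype)),
    threshold = attr(x, "threshold") %||% NA_real_
  )
}
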