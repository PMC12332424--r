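# Ancestry inference: least-squares nonnegative matrix factorization of the
# dosage matrix into admixture proportions Q and ancestral allele
# frequencies F, with model evaluation by cross-entropy on masked cells.

#' Fit a sparse-NMF admixture model for one K
#'
#' Decomposes a complete 0/1/2 dosage matrix `X` (individuals x loci) as
#' `X ~ Q (2F)` with `Q` (individuals x K) on the probability simplex per
#' row and `F` (K x loci) in \[0, 1\], by alternating ridge-penalised least
#' squares: the `F` step is a clipped least-squares solve, the `Q` step a
#' ridge solve followed by Euclidean projection of each row onto the
#' simplex. Iteration stops when the relative loss change falls below
#' `tol` or after `max_sweeps` sweeps.
#'
#' Before fitting, a random `mask_fraction` of cells is hidden (replaced
#' by the per-locus mean of the visible cells); the masked cross-entropy
#' `-mean(x/2 log p + (1 - x/2) log(1 - p))` with `p = clamp(QF, 1e-6,
#' 1 - 1e-6)` is scored on the hidden cells and is the model-choice
#' criterion across K.
#'
#' @param X Complete numeric dosage matrix (no `NA`), individuals x loci.
#' @param K Number of ancestral clusters (>= 1, <= individuals).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @param alpha Ridge penalty on `Q` (default 1). A mild ridge stabilises
#'   the alternating solves without biasing ancestry: because the penalty
#'   competes with the small differential eigenvalue of the locus-summed
#'   normal equations, heavy ridges (say 10) visibly shrink Q towards
#'   uniform ancestry at moderate locus counts.
#' @param mask_fraction Fraction of cells hidden for cross-entropy
#'   (default 0.05; 0 disables masking and the criterion is `NA`).
#' @param max_sweeps,tol Convergence controls.
#' @return An `admixture_run`: list with `Q`, `F`, `K`, `cross_entropy`,
#'   `loss`, `sweeps`, `converged`, `seed`.
#' @export
fit_admixture <- function(X, K, seed, alpha = 1, mask_fraction = 0.05,
                          max_sweeps = 500, tol = 1e-6) {
  assert_that(!anyNA(X), "X must be complete; run impute_missing() first")
  n <- nrow(X); L <- ncol(X)
  assert_that(K >= 1 && K <= n, "K must be between 1 and the number of individuals")
  set.seed(seed)

  masked <- matrix(FALSE, n, L)
  X_fit <- X
  if (mask_fraction > 0) {
    n_mask <- max(1L, round(mask_fraction * n * L))
    masked[sample.int(n * L, n_mask)] <- TRUE
    colmean <- colSums(X * !masked) / pmax(colSums(!masked), 1)
    X_fit[masked] <- matrix(colmean, n, L, byrow = TRUE)[masked]
  }
  Xh <- X_fit / 2

  Q <- matrix(runif(n * K), n, K)
  Q <- Q / rowSums(Q)
  Fm <- matrix(0.5, K, L)
  lambda <- alpha / 4            # ridge on the dosage/2 scale
  loss <- Inf; converged <- FALSE; sweep <- 0
  while (sweep < max_sweeps) {
    sweep <- sweep + 1
    A <- crossprod(Q) + diag(1e-8, K)
    Fm <- solve(A, crossprod(Q, Xh))
    Fm[Fm < 0] <- 0; Fm[Fm > 1] <- 1
    G <- tcrossprod(Fm) + diag(lambda, K)
    Q <- t(solve(G, Fm %*% t(Xh)))
    Qp <- apply(Q, 1, project_simplex)
    Q <- if (is.matrix(Qp)) t(Qp) else matrix(Qp, ncol = 1)
    new_loss <- sum((X_fit - 2 * (Q %*% Fm))^2) + alpha * sum(Q^2)
    if (is.finite(loss) &&
        abs(loss - new_loss) <= tol * max(loss, .Machine$double.eps)) {
      loss <- new_loss; converged <- TRUE; break
    }
    loss <- new_loss
  }

  ce <- NA_real_
  if (any(masked)) {
    P <- Q %*% Fm
    P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
    xh <- X[masked] / 2
    ce <- -mean(xh * log(P[masked]) + (1 - xh) * log(1 - P[masked]))
  }
  rownames(Q) <- rownames(X)
  colnames(Fm) <- colnames(X)
  structure(list(Q = Q, F = Fm, K = K, cross_entropy = ce, loss = loss,
                 sweeps = sweep, converged = converged, seed = seed,
                 n_masked = sum(masked)),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("<admixture_run> K = ", x$K, ", ", nrow(x$Q), " individuals; loss ",
      format(x$loss, digits = 6), ", cross-entropy ",
      format(x$cross_entropy, digits = 4), " (", x$sweeps, " sweeps",
      if (x$converged) ", converged" else "", ")\n", sep = "")
  invisible(x)
}

#' Replicate-run admixture ensemble with alignment and diagnostics
#'
#' Fits `reps` replicate NMF runs for each K, aligns cluster labels of
#' every run to the lowest-loss run of its K (assignment matching on
#' column correlations of Q, resolving label switching), and summarises:
#' per-individual mean ancestry with percentile 95% CIs across runs, mean
#' masked cross-entropy per K, and per-cluster Gelman-Rubin PSRF and
#' effective sample size with the replicate runs treated as chains of
#' per-individual ancestries.
#'
#' The cross-entropy curve across K is reported in full; the package
#' never auto-selects K silently — see [recommend_k()].
#'
#' @param X Complete dosage matrix.
#' @param K_range Integer vector of K values (default `1:10`).
#' @param reps Replicate runs per K (>= 2; default 10).
#' @param seed Master seed from which per-run seeds are derived.
#' @param ... Passed to [fit_admixture()].
#' @return An `admixture_ensemble`: per-K list with the aligned Q stack,
#'   `Q_mean`, `Q_lo`, `Q_hi`, `cross_entropies`, `psrf`, `ess`, `seeds`.
#' @export
admixture_ensemble <- function(X, K_range = 1:10, reps = 10, seed = 1, ...) {
  assert_that(reps >= 2, "reps must be >= 2 for CI computation")
  seeds <- matrix(derive_seeds(seed, length(K_range) * reps),
                  nrow = length(K_range))
  by_k <- purrr::map(seq_along(K_range), function(ki) {
    K <- K_range[ki]
    runs <- purrr::map(seq_len(reps), function(r) {
      fit_admixture(X, K, seed = seeds[ki, r], ...)
    })
    bad <- purrr::map_lgl(runs, ~ anyNA(.x$Q))
    if (any(bad)) {
      inform(paste0("K = ", K, ": excluded ", sum(bad),
                    " degenerate runs from the ensemble"))
      runs <- runs[!bad]
    }
    ref <- which.min(purrr::map_dbl(runs, "loss"))
    Qs <- purrr::map(runs, function(run) {
      perm <- match_columns(runs[[ref]]$Q, run$Q)
      run$Q[, perm, drop = FALSE]
    })
    stack <- array(unlist(Qs), dim = c(nrow(X), K, length(Qs)),
                   dimnames = list(rownames(X), paste0("K", seq_len(K)), NULL))
    Q_mean <- apply(stack, c(1, 2), mean)
    Q_lo <- apply(stack, c(1, 2), quantile, probs = 0.025, names = FALSE)
    Q_hi <- apply(stack, c(1, 2), quantile, probs = 0.975, names = FALSE)
    psrf <- vapply(seq_len(K), function(k) psrf(stack[, k, ]), numeric(1))
    ess <- vapply(seq_len(K), function(k) {
      sum(apply(stack[, k, , drop = FALSE], 3, ess_chain))
    }, numeric(1))
    list(K = K, stack = stack, Q_mean = Q_mean, Q_lo = Q_lo, Q_hi = Q_hi,
         cross_entropies = purrr::map_dbl(runs, "cross_entropy"),
         losses = purrr::map_dbl(runs, "loss"),
         psrf = psrf, ess = ess, seeds = seeds[ki, ], ref_run = ref)
  })
  names(by_k) <- paste0("K", K_range)
  structure(list(by_k = by_k, K_range = K_range, reps = reps, seed = seed),
            class = "admixture_ensemble")
}

#' @export
print.admixture_ensemble <- function(x, ...) {
  cat("<admixture_ensemble> K = ", paste(range(x$K_range), collapse = ".."),
      ", ", x$reps, " replicate runs each\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname admixture_ensemble
#' @param x An `admixture_ensemble`.
#' @method glance admixture_ensemble
#' @export
glance.admixture_ensemble <- function(x, ...) {
  purrr::map_dfr(x$by_k, function(b) tibble::tibble(
    K = b$K,
    reps = dim(b$stack)[3],
    mean_cross_entropy = mean(b$cross_entropies),
    sd_cross_entropy = sd(b$cross_entropies),
    max_psrf = max(b$psrf),
    min_ess = min(b$ess)
  ))
}

#' @rdname admixture_ensemble
#' @param K Which K to extract per-individual summaries for.
#' @method tidy admixture_ensemble
#' @export
tidy.admixture_ensemble <- function(x, K = NULL, ...) {
  ks <- if (is.null(K)) x$K_range else K
  purrr::map_dfr(ks, function(k) {
    b <- x$by_k[[paste0("K", k)]]
    long <- function(m, nm) {
      tibble::as_tibble(m, rownames = "specimen") |>
        tidyr::pivot_longer(-"specimen", names_to = "cluster",
                            values_to = nm)
    }
    dplyr::bind_cols(
      tibble::tibble(K = k),
      long(b$Q_mean, "mean"),
      long(b$Q_lo, "lo")["lo"],
      long(b$Q_hi, "hi")["hi"]
    )
  })
}

#' Recommend a K from the cross-entropy curve
#'
#' Returns the K with lowest mean masked cross-entropy, with a message
#' showing the full curve. A flat curve means the data carry little
#' structure signal; the choice of K remains the analyst's and should
#' weigh parsimony, not only this criterion.
#'
#' @param ensemble An `admixture_ensemble`.
#' @return The recommended K (integer), invisibly the whole curve as
#'   attribute `"curve"`.
#' @export
recommend_k <- function(ensemble) {
  g <- glance(ensemble)
  k <- g$K[which.min(g$mean_cross_entropy)]
  inform(paste0("cross-entropy by K: ",
                paste(sprintf("K%d=%.4f", g$K, g$mean_cross_entropy),
                      collapse = ", "),
                "; lowest at K = ", k,
                " (inspect the curve before committing)"))
  structure(k, curve = g)
}

# Assignment of run columns to reference columns maximising total Pearson
# correlation: exhaustive over permutations for K <= 8, greedy matching
# plus pairwise-swap refinement beyond.
match_columns <- function(Q_ref, Q) {
  K <- ncol(Q_ref)
  if (K == 1) return(1L)
  C <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    sa <- sd(Q_ref[, a]); sb <- sd(Q[, b])
    C[a, b] <- if (sa == 0 || sb == 0) 0 else cor(Q_ref[, a], Q[, b])
  }
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- apply(perms, 1, function(p) sum(C[cbind(seq_len(K), p)]))
    return(perms[which.max(scores), ])
  }
  perm <- integer(K)
  used <- logical(K)
  for (a in order(-apply(C, 1, max))) {
    b <- which.max(ifelse(used, -Inf, C[a, ]))
    perm[a] <- b; used[b] <- TRUE
  }
  repeat {
    improved <- FALSE
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      cur <- C[a, perm[a]] + C[b, perm[b]]
      swp <- C[a, perm[b]] + C[b, perm[a]]
      if (swp > cur + 1e-12) {
        tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  perm
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
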