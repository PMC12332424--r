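test_that("Nei distance matches hand computations at the individual level", {
  # two loci; ind1 = (AA, AA), ind2 = (AA, aa)
  d <- rbind(ind1 = c(2L, 2L), ind2 = c(2L, 0L))
  nd <- nei_distance(d, "individual")
  # Jxy = 1, Jx = Jy = 2 -> D = -ln(1/2)
  expect_equal(unname(nd$d[1, 2]), log(2), tolerance = 1e-12)

  # identical individuals (with a het locus) are at distance zero
  d2 <- rbind(a = c(1L, 2L, 0L), b = c(1L, 2L, 0L))
  expect_equal(unname(nei_distance(d2, "individual")$d["a", "b"]), 0,
               tolerance = 1e-12)
})

test_that("population-level Nei distance is zero for identical frequencies", {
  set.seed(81)
  block <- matrix(rbinom(60, 2, 0.4), 10, 6)
  d <- rbind(block, block)
  grp <- rep(c("P1", "P2"), each = 10)
  nd <- nei_distance(d, "population", groups = grp)
  expect_equal(unname(nd$d["P1", "P2"]), 0, tolerance = 1e-12)
})

test_that("one-individual populations reduce to individual distances", {
  set.seed(82)
  d <- matrix(rbinom(40, 2, 0.5), 4, 10,
              dimnames = list(paste0("i", 1:4), NULL))
  ind <- nei_distance(d, "individual")
  pop <- nei_distance(d, "population", groups = paste0("i", 1:4))
  expect_equal(pop$d[ind$ids, ind$ids], ind$d, tolerance = 1e-12)
})

test_that("Nei-Chesser F_ST equals the direct-formula oracle", {
  set.seed(83)
  for (rep in 1:5) {
    d <- matrix(rbinom(30 * 20, 2, runif(1, 0.2, 0.8)), 30, 20)
    d[sample(length(d), 20)] <- NA
    grp <- sample(c("A", "B", "C"), 30, replace = TRUE,
                  prob = c(0.4, 0.35, 0.25))
    est <- fst_nei_chesser(d, grp)
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      o <- fst_oracle(d[grp == pair[1], , drop = FALSE],
                      d[grp == pair[2], , drop = FALSE])
      expect_equal(unname(est[pair[1], pair[2]]), o, tolerance = 1e-12)
    }
  }
})

test_that("fixation and panmixia bracket the F_ST estimator", {
  # groups fixed for alternate alleles at every locus
  fixed <- rbind(matrix(0L, 5, 8), matrix(2L, 5, 8))
  grp <- rep(c("A", "B"), each = 5)
  expect_equal(unname(fst_nei_chesser(fixed, grp)["A", "B"]), 1)

  set.seed(84)
  pool <- matrix(rbinom(60 * 500, 2, rep(runif(500, 0.2, 0.8), each = 60)),
                 60, 500)
  est <- fst_nei_chesser(pool, rep(c("A", "B"), 30))["A", "B"]
  expect_lt(abs(est), 0.01)

  mono <- matrix(0L, 6, 4)
  expect_warning(z <- fst_nei_chesser(mono, rep(c("A", "B"), 3)),
                 "monomorphic")
  expect_equal(unname(z["A", "B"]), 0)
})

test_that("Ward clustering plus DAPC separates planted groups", {
  sim <- simulate_admixed_genotypes(n_individuals = 45, n_loci = 300,
                                    K = 3, fst = 0.5, admixed_fraction = 0,
                                    missing_rate = 0, seed = 85)
  X <- impute_missing(filter_genotypes(sim$genotypes))
  nd <- nei_distance(X, "individual")
  fit <- ward_dapc(nd, X, n_clusters = 3, n_pc = 10, n_df = 2)
  truth <- max.col(as.matrix(sim$truth[match(fit$clusters$specimen,
                                             sim$truth$specimen),
                                       c("Q1", "Q2", "Q3")]))
  expect_equal(adjusted_rand_index(fit$clusters$cluster, truth), 1)

  # DF1 separates groups: between-group share of variance is high
  sc <- tidy(fit)
  fitaov <- stats::aov(LD1 ~ cluster, data = sc)
  ss <- summary(fitaov)[[1]][["Sum Sq"]]
  expect_gt(ss[1] / sum(ss), 0.8)

  expect_error(ward_dapc(nd, X, n_clusters = 1), "at least two")
  expect_error(ward_dapc(nd, X, n_pc = 45), "n_pc")
})

test_that("connectivity tables weight basin pairs by inverse F_ST", {
  sim <- simulate_admixed_genotypes(n_individuals = 40, n_loci = 200,
                                    fst = 0.4, seed = 86)
  X <- impute_missing(filter_genotypes(sim$genotypes))
  ens <- admixture_ensemble(X, K_range = 2, reps = 2, seed = 3)
  fst <- matrix(c(0, 0.01, 0.01, 0), 2, 2,
                dimnames = list(c("BB", "WEB"), c("BB", "WEB")))
  class(fst) <- c("fst_matrix", "matrix", "array")
  meta <- sim$truth[match(rownames(X), sim$truth$specimen), ]
  cm <- connectivity_map_data(ens, 2, fst, meta)
  expect_equal(cm$pairs$weight, 100)
  expect_equal(sum(cm$basins$n), nrow(X))
  # mean ancestry rows stay on the simplex
  expect_equal(unname(rowSums(as.matrix(cm$basins[c("K1", "K2")]))),
               rep(1, nrow(cm$basins)), tolerance = 1e-8)

  zero <- fst; zero[1, 2] <- zero[2, 1] <- 0
  cm0 <- connectivity_map_data(ens, 2, zero, meta)
  expect_equal(cm0$pairs$weight, 10000)     # epsilon floor, no Inf
})
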