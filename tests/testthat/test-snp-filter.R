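make_genotypes <- function(dosage) {
  storage.mode(dosage) <- "integer"
  popconnect:::genotype_table(
    dosage,
    individuals = sprintf("i%02d", seq_len(nrow(dosage))),
    loci = sprintf("tag%03d:1", seq_len(ncol(dosage))))
}

test_that("filters remove planted individuals and loci, conserving counts", {
  set.seed(51)
  d <- matrix(rbinom(10 * 12, 2, 0.4), 10, 12)
  d[3:10, 2] <- NA                         # locus 2: high missingness
  d[, 3] <- 0L                             # monomorphic
  d[, 4] <- c(1L, 1L, rep(0L, 8))          # becomes singleton after i01 drop
  d[, 5] <- c(0L, 1L, 1L, 1L, rep(0L, 6))  # mac 3: retained
  d[1, 1:10] <- NA                         # individual 1: 83% missing
  g <- make_genotypes(d)
  fg <- filter_genotypes(g)

  expect_false("i01" %in% fg$individuals)
  expect_false("tag002:1" %in% fg$loci)
  expect_false("tag003:1" %in% fg$loci)
  expect_false("tag004:1" %in% fg$loci)
  expect_true("tag005:1" %in% fg$loci)

  log <- fg$log
  ind_row <- log[log$unit == "individual", ]
  expect_equal(ind_row$removed + ind_row$retained, 10)
  loc_rows <- log[log$unit == "locus", ]
  # successive locus rules chain: retained of one is input of the next
  expect_equal(loc_rows$removed[1] + loc_rows$retained[1], 12)
  expect_equal(loc_rows$removed[2] + loc_rows$retained[2],
               loc_rows$retained[1])
  expect_equal(loc_rows$removed[3] + loc_rows$retained[3],
               loc_rows$retained[2])
  expect_equal(loc_rows$retained[3], length(fg$loci))
})

test_that("completely filtered tables raise an explicit error", {
  d <- matrix(0L, 4, 3)
  expect_error(filter_genotypes(make_genotypes(d)), "all individuals or loci")
})

test_that("LD pruning removes duplicated loci and is idempotent", {
  set.seed(52)
  base <- matrix(rbinom(40 * 6, 2, 0.5), 40, 6)
  d <- cbind(base[, 1], base[, 1], base[, 2:6])   # exact duplicate
  g <- make_genotypes(d)
  fg <- prune_ld(filter_genotypes(g, loc_miss = 1))
  expect_false(fg$loci[2] %in% fg$pruned)
  expect_true(fg$loci[1] %in% fg$pruned)

  # independent loci survive
  indep <- which(fg$loci %in% fg$pruned)
  expect_gte(length(indep), 5)

  # pruning the pruned set removes nothing
  sub <- fg
  sub$dosage <- fg$dosage[, fg$pruned, drop = FALSE]
  sub$loci <- fg$pruned
  sub2 <- prune_ld(sub)
  expect_identical(sub2$pruned, fg$pruned)
})

test_that("pruning rejects degenerate windows", {
  g <- make_genotypes(matrix(rbinom(20, 2, 0.5), 5, 4))
  fg <- filter_genotypes(g, loc_miss = 1)
  expect_error(prune_ld(fg, window = 1), "window")
})

test_that("imputation fills with the per-locus mode, ties to lower dosage", {
  d <- rbind(c(0L, 0L, NA), c(1L, 1L, 2L), c(1L, 2L, 2L), c(NA, NA, 0L))
  g <- make_genotypes(d)
  fg <- filter_genotypes(g, ind_miss = 1, loc_miss = 1)
  X <- impute_missing(fg, use_pruned = FALSE)
  expect_equal(unname(X[4, 1]), 1)          # mode of {0,1,1}
  expect_equal(unname(X[4, 2]), 0)          # three-way tie {0,1,2} -> lowest
  expect_equal(unname(X[1, 3]), 2)          # mode of {2,2,0}
  expect_equal(attr(X, "n_imputed"), 3L)

  # explicit tie case: {0,0,1,1} -> lower dosage wins
  d2 <- rbind(c(0L), c(0L), c(1L), c(1L), c(NA))
  d2 <- cbind(d2, c(0L, 1L, 0L, 1L, 2L))    # second locus keeps it polymorphic
  g2 <- make_genotypes(d2)
  fg2 <- filter_genotypes(g2, ind_miss = 1, loc_miss = 1)
  X2 <- impute_missing(fg2, use_pruned = FALSE)
  expect_equal(unname(X2[5, 1]), 0)

  # no missing data: identity
  d3 <- matrix(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L), 4, 2)
  fg3 <- filter_genotypes(make_genotypes(d3), ind_miss = 1, loc_miss = 1)
  X3 <- impute_missing(fg3, use_pruned = FALSE)
  expect_equal(unname(X3), unname(matrix(as.double(d3), 4, 2)),
               ignore_attr = TRUE)
  expect_equal(attr(X3, "n_imputed"), 0L)
})
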