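test_that("substitution counts use pairwise deletion", {
  aln <- make_alignment(c(x = "ACGT", y = "ACGT"))
  d <- substitution_counts(aln)
  expect_equal(unname(d$d["x", "y"]), 0)

  aln <- make_alignment(c(x = "ACGT", y = "ACGA"))
  d <- substitution_counts(aln)
  expect_equal(unname(d$d["x", "y"]), 1)
  expect_equal(unname(d$eff["x", "y"]), 4)

  aln <- make_alignment(c(x = "ACNT", y = "ACGA"))
  d <- substitution_counts(aln)
  expect_equal(unname(d$d["x", "y"]), 1)     # N site excluded
  expect_equal(unname(d$eff["x", "y"]), 3)
})

test_that("K2P matches closed-form values for single substitutions", {
  # one transition (G->A) in 10 sites: P = 0.1, Q = 0
  aln <- make_alignment(c(x = "ACGTACGTAC", y = "ACATACGTAC"))
  d <- k2p_matrix(aln)
  expect_equal(unname(d$d["x", "y"]), -0.5 * log(0.8), tolerance = 1e-12)
  # one transversion (G->C): P = 0, Q = 0.1
  aln <- make_alignment(c(x = "ACGTACGTAC", y = "ACCTACGTAC"))
  d <- k2p_matrix(aln)
  expect_equal(unname(d$d["x", "y"]),
               -0.5 * log(0.9) - 0.25 * log(0.8), tolerance = 1e-12)
})

test_that("K2P equals the per-site counting oracle and bounds P+Q", {
  set.seed(21)
  for (i in 1:20) {
    s1 <- random_seq(120)
    s2chars <- strsplit(s1, "")[[1]]
    flip <- sample(120, 12)
    s2chars[flip] <- vapply(s2chars[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    s2 <- paste(s2chars, collapse = "")
    d <- k2p_matrix(make_alignment(c(a = s1, b = s2)))
    o <- k2p_oracle(s1, s2)
    expect_equal(unname(d$d["a", "b"]), o$d, tolerance = 1e-12)
    expect_equal(unname(d$P["a", "b"]), o$P, tolerance = 1e-12)
    expect_gte(unname(d$d["a", "b"]), o$P + o$Q)   # Jensen lower bound
  }
})

test_that("K2P flags saturated pairs as undefined instead of dropping", {
  # complementary strands: every site a transversion, Q = 1
  aln <- make_alignment(c(x = "ACGTACGT", y = "TGCATGCA"))
  expect_message(d <- k2p_matrix(aln), "undefined")
  expect_true(d$undefined["x", "y"])
  expect_true(is.na(d$d["x", "y"]))
})

test_that("mitotype delimitation cuts single linkage and orders by size", {
  base <- random_seq(615)
  mut <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(ch, collapse = "")
  }
  set.seed(31)
  far <- mut(base, 1:60)                    # ~60 substitutions away
  aln <- make_alignment(c(a1 = base, a2 = mut(base, 1),
                          b1 = far, b2 = mut(far, 600), b3 = mut(far, 610)))
  part <- delimit_mitotypes(k2p_matrix(aln), threshold = 0.05)
  expect_equal(sort(unique(part$mitotype)), c("MT1", "MT2"))
  # MT1 is the larger cluster (the b's)
  expect_equal(unname(part$mitotype[part$specimen == "b1"]), "MT1")
  expect_equal(unname(part$mitotype[part$specimen == "a1"]), "MT2")

  # everything below threshold collapses to one mitotype
  one <- delimit_mitotypes(k2p_matrix(make_alignment(
    c(a = base, b = mut(base, 1), c = mut(base, 2)))), threshold = 0.05)
  expect_equal(unique(one$mitotype), "MT1")
})

test_that("delimitation is invariant to input order", {
  sim <- simulate_heteroplasmic_sequences(n_specimens = 24, seed = 5)
  p1 <- delimit_mitotypes(k2p_matrix(sim$alignment))
  shuffled <- sim$alignment[sample(nrow(sim$alignment)), ]
  p2 <- delimit_mitotypes(k2p_matrix(shuffled))
  m1 <- setNames(p1$mitotype, p1$specimen)
  m2 <- setNames(p2$mitotype, p2$specimen)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("planted F/M lineages are recovered exactly", {
  sim <- simulate_heteroplasmic_sequences(n_specimens = 40, divergence = 0.25,
                                          within = 0.02, seed = 9)
  part <- delimit_mitotypes(k2p_matrix(sim$alignment))
  expect_equal(adjusted_rand_index(part$mitotype, sim$truth$lineage), 1)
})

test_that("mitotype labels transfer by specimen id", {
  sim <- simulate_heteroplasmic_sequences(n_specimens = 10, seq_length = 200,
                                          seed = 3, marker = "COI")
  part <- delimit_mitotypes(k2p_matrix(sim$alignment))
  dst <- sim$alignment[1:8, ]
  class(dst) <- class(sim$alignment)
  tr <- transfer_mitotypes(part, dst)
  expect_equal(nrow(tr), 8)
  expect_equal(tr$mitotype,
               part$mitotype[match(tr$specimen, part$specimen)])

  # destination specimen absent from the source stays unlabelled
  part_small <- part[part$specimen != "sp001", ]
  class(part_small) <- class(part)
  expect_message(tr2 <- transfer_mitotypes(part_small, dst), "unlabelled")
  expect_true(is.na(tr2$mitotype[tr2$specimen == "sp001"]))

  off <- sim$alignment
  off$specimen <- paste0("zz", off$specimen)
  expect_error(transfer_mitotypes(part, off), "shared")
})

test_that("distance summaries report min-max within and between", {
  # two clusters with known distances plus a singleton
  base <- random_seq(100)
  mut <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(ch, collapse = "")
  }
  aln <- make_alignment(c(a1 = base, a2 = mut(base, 1), a3 = mut(base, 1:2),
                          b1 = mut(base, 31:60), s1 = mut(base, 61:95)))
  d <- substitution_counts(aln)
  part <- delimit_mitotypes(d, threshold = 10)
  summ <- mitotype_distance_summary(d, part)
  singleton_rows <- summ[summ$type == "within" & summ$min == 0 & summ$max == 0, ]
  expect_gte(nrow(singleton_rows), 1)
  expect_true(all(summ$label == sprintf("%.2f-%.2f", summ$min, summ$max)))
  # within ranges never overlap the smallest between range here
  expect_lt(max(summ$max[summ$type == "within"]),
            min(summ$min[summ$type == "between"]))
})
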