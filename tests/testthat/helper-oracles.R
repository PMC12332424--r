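# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive per-site / per-locus loops so they share no code
# with the implementation they check.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

make_alignment <- function(seqs, marker = "COI") {
  read_fasta_alignment(write_tmp_fasta(seqs), marker = marker)
}

# Site-by-site K2P oracle: count transitions/transversions in a loop.
k2p_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ts <- tv <- eff <- 0
  purines <- c("A", "G")
  for (i in seq_along(a)) {
    if (!a[i] %in% c("A", "C", "G", "T")) next
    if (!b[i] %in% c("A", "C", "G", "T")) next
    eff <- eff + 1
    if (a[i] == b[i]) next
    same_class <- (a[i] %in% purines) == (b[i] %in% purines)
    if (same_class) ts <- ts + 1 else tv <- tv + 1
  }
  P <- ts / eff; Q <- tv / eff
  list(P = P, Q = Q, eff = eff,
       d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
}

# Direct-formula Nei & Chesser (1983) oracle for one pair of groups,
# written as an explicit per-locus loop over scalar quantities.
fst_oracle <- function(da, db) {
  hs_list <- ht_list <- c()
  for (l in seq_len(ncol(da))) {
    xa <- da[, l]; xa <- xa[!is.na(xa)]
    xb <- db[, l]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) next
    pa <- mean(xa) / 2; pb <- mean(xb) / 2
    hoa <- mean(xa == 1); hob <- mean(xb == 1)
    ho <- (hoa + hob) / 2
    nt <- 2 / (1 / length(xa) + 1 / length(xb))
    hs_raw <- 1 - ((pa^2 + (1 - pa)^2) + (pb^2 + (1 - pb)^2)) / 2
    hs <- nt / (nt - 1) * (hs_raw - ho / (2 * nt))
    pbar <- (pa + pb) / 2
    ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (2 * nt) - ho / (2 * nt * 2)
    hs_list <- c(hs_list, hs); ht_list <- c(ht_list, ht)
  }
  1 - mean(hs_list) / mean(ht_list)
}

# Plain-loop SNIP oracle.
snip_oracle <- function(y, iterations = 15) {
  n <- length(y)
  b <- y
  for (i in seq_len(iterations)) {
    w <- min(i, iterations)
    b_new <- b
    for (j in seq_len(n)) {
      lo <- max(j - w, 1); hi <- min(j + w, n)
      b_new[j] <- min(b[j], (b[lo] + b[hi]) / 2)
    }
    b <- b_new
  }
  b
}

# Align an estimated Q to a truth Q by the best column permutation
# (exhaustive; K is small in tests) under total correlation.
align_to_truth <- function(Q_est, Q_true) {
  K <- ncol(Q_true)
  perms <- if (K == 2) list(1:2, 2:1) else
    combinat_perms(K)
  best <- NULL; best_score <- -Inf
  for (p in perms) {
    sc <- sum(vapply(seq_len(K), function(k) {
      if (sd(Q_est[, p[k]]) == 0) 0 else cor(Q_est[, p[k]], Q_true[, k])
    }, numeric(1)))
    if (sc > best_score) { best_score <- sc; best <- p }
  }
  Q_est[, best, drop = FALSE]
}

combinat_perms <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (s in combinat_perms(K - 1)) {
      ss <- s + (s >= i)
      out[[length(out) + 1]] <- c(i, ss)
    }
  }
  out
}

# Minimal VCF text fixture in the writer's canonical form.
canonical_vcf_lines <- function(gt_matrix, individuals, chrom, pos,
                                ref = "A", alt = "T") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals), collapse = "\t"))
  body <- vapply(seq_len(nrow(gt_matrix)), function(r) {
    paste(c(chrom[r], pos[r], paste0(chrom[r], ":", pos[r]), ref, alt,
            ".", "PASS", ".", "GT", gt_matrix[r, ]), collapse = "\t")
  }, character(1))
  c(header, body)
}

simulate_two_group_matrix <- function(n = 30, p = 25, n_informative = 8,
                                      shift = 3, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(p, log(10), 0.5))
  base <- outer(rep(1, n), mu) * exp(matrix(rnorm(n * p, 0, 0.2), n, p))
  grp <- rep(c("A", "B"), length.out = n)
  base[grp == "B", seq_len(n_informative)] <-
    base[grp == "B", seq_len(n_informative)] * shift
  rownames(base) <- sprintf("sp%03d", seq_len(n))
  colnames(base) <- sprintf("%.4f", seq(3000, by = 97.3, length.out = p))
  list(im = popconnect:::new_intensity_matrix(
         base, bins = tibble::tibble(ref_mz = as.numeric(colnames(base)),
                                     n_members = n),
         tolerance = 0.002),
       groups = stats::setNames(grp, rownames(base)))
}
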