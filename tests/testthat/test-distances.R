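test_that("substitution counting classifies transitions, transversions and ambiguity", {
  r <- pairwise_counts("ACGT", "ACAT")
  expect_equal(r$n_sites, 4L)
  expect_equal(r$transitions, 1L)   # G/A
  expect_equal(r$transversions, 0L)
  expect_equal(r$p, 0.25)

  # pairwise deletion drops the N column entirely
  r <- pairwise_counts("ACGT", "ACNT")
  expect_equal(r$n_sites, 3L)
  expect_equal(r$n_diff, 0L)

  r <- pairwise_counts("AAAA", "AAAA")
  expect_equal(r$n_diff, 0L)
  expect_equal(r$d_k2p, 0)

  expect_error(pairwise_counts("ACGT", "ACG"), "unequal")
  expect_error(pairwise_counts("NNNN", "ACGT"), "no comparable sites")
})

test_that("range restriction compares only the requested segment", {
  r <- pairwise_counts("AAAATTTT", "AAAATTCT", range = c(1, 4))
  expect_equal(r$n_diff, 0L)
  r <- pairwise_counts("AAAATTTT", "AAAATTCT", range = c(5, 8))
  expect_equal(r$n_sites, 4L)
  expect_equal(r$transitions, 1L)
  expect_error(pairwise_counts("ACGT", "ACGT", range = c(0, 4)), "bounds")
})

test_that("K2P matches the closed form and errors at saturation", {
  expect_equal(k2p(0.25, 0), -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(k2p(0.25, 0), 0.34657359, tolerance = 1e-7)
  expect_equal(k2p(0, 0), 0)
  expect_error(k2p(0.5, 0), "saturated")
  expect_error(k2p(0.2, 0.6), "saturated")
})

test_that("K2P never shrinks the observed distance and agrees in the small-p limit", {
  set.seed(11)
  for (rep in 1:50) {
    L <- 400L
    a <- random_seq(L)
    n_mut <- sample(1:60, 1)
    pos <- sample(L, n_mut)
    b <- a
    for (p in pos) {
      from <- substr(a, p, p)
      b <- mutate_at(b, p, sample(setdiff(c("A", "C", "G", "T"), from), 1))
    }
    r <- pairwise_counts(a, b)
    expect_gte(r$d_k2p, r$p)
    if (r$p == 0) expect_equal(r$d_k2p, 0)
  }
  # small-distance limit: correction below 1e-4 near p = 0.01
  L <- 1000L
  a <- paste(rep("A", L), collapse = "")
  r <- pairwise_counts(a, mutate_at(a, 1:9, "G"))  # 9 transitions
  expect_equal(r$p, 0.009)
  expect_lt(abs(r$d_k2p - r$p), 1e-4)
  r <- pairwise_counts(a, mutate_at(mutate_at(a, 1:5, "G"), 6:10, "T"))
  expect_equal(r$p, 0.01)                          # mixed ts/tv at p = 1%
  expect_lt(abs(r$d_k2p - r$p), 1e-4)
})

test_that("distance matrices are symmetric with zero diagonal and match brute-force recounts", {
  set.seed(5)
  a <- random_seq(200)
  seqs <- seq_set(c(s1 = a,
                    s2 = mutate_at(a, 1:5, "A"),
                    s3 = mutate_at(a, 50:60, "T"),
                    s4 = mutate_at(a, c(3, 9, 120), "C")))
  m <- build_matrix(seqs, metric = "k2p")
  expect_true(isSymmetric(unname(m$d)))
  expect_equal(unname(diag(m$d)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    bc <- brute_counts(seqs$seqs[i], seqs$seqs[j])
    expect_equal(m$n_diff[i, j], bc$ts + bc$tv)
    expect_equal(m$d[i, j], k2p(bc$ts / bc$n, bc$tv / bc$n))
  }
})

test_that("K2P matrix agrees with an independent reference implementation", {
  bc <- herm_barcodes()
  m <- build_matrix(bc, metric = "k2p")
  dnab <- ape::as.DNAbin(do.call(rbind, strsplit(unname(bc$seqs), "")))
  rownames(dnab) <- bc$ids
  ref <- as.matrix(ape::dist.dna(dnab, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(m$d, ref[bc$ids, bc$ids], tolerance = 1e-10)
})

test_that("group divergence equals brute-force pair enumeration and respects singletons", {
  set.seed(21)
  a <- random_seq(300)
  seqs <- list()
  labels <- character()
  for (g in 1:3) {
    cons <- a
    for (p in sample(300, 8 * g)) cons <- mutate_at(cons, p, sample(c("A","C","G","T"), 1))
    n_g <- c(4, 3, 1)[g]
    for (i in seq_len(n_g)) {
      h <- cons
      for (p in sample(300, sample(0:2, 1)))
        h <- mutate_at(h, p, sample(c("A","C","G","T"), 1))
      id <- sprintf("g%d_%d", g, i)
      seqs[[id]] <- h
      labels[id] <- sprintf("G%d", g)
    }
  }
  s <- seq_set(unlist(seqs))
  m <- build_matrix(s)
  rep_ <- group_divergence(m, labels)

  # independent recomputation by explicit pair enumeration
  pct <- 100 * m$d
  for (g in unique(labels)) {
    idx <- which(labels[s$ids] == g)
    vals <- c()
    if (length(idx) >= 2) {
      for (i in idx) for (j in idx) if (i < j) vals <- c(vals, pct[i, j])
    }
    row <- rep_$within[rep_$within$group == g, ]
    if (length(vals)) {
      expect_equal(row$mean, mean(vals))
      expect_equal(row$sd, sd(vals))   # n-1 denominator
      expect_equal(row$max, max(vals))
    } else {
      expect_true(is.na(row$mean) && is.na(row$max))  # absent, not zero
    }
  }
  bt <- rep_$between[rep_$between$group1 == "G1" & rep_$between$group2 == "G2", ]
  vals <- c()
  for (i in which(labels[s$ids] == "G1")) for (j in which(labels[s$ids] == "G2"))
    vals <- c(vals, pct[i, j])
  expect_equal(bt$min, min(vals))
  expect_equal(bt$mean, mean(vals))
  expect_error(group_divergence(m, labels[-1]), "no group assignment")
})

test_that("identical sequences in one group give zero divergence", {
  s <- seq_set(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  rep_ <- group_divergence(build_matrix(s), rep("G", 3))
  expect_equal(rep_$within$mean, 0)
  expect_equal(rep_$within$sd, 0)
  expect_equal(rep_$within$max, 0)
})

test_that("barcode gap demands tight groups and a distant nearest neighbour", {
  fake_report <- function(wmax, bmin) {
    structure(list(
      within = data.frame(group = c("A", "B"), n = c(3, 3), n_pairs = c(3, 3),
                          mean = wmax / 2, sd = c(0.1, 0.1), max = wmax),
      between = data.frame(group1 = "A", group2 = "B", min = bmin,
                           mean = bmin + 1, max = bmin + 2),
      scale = "percent"), class = "group_divergence")
  }
  expect_true(barcode_gap(fake_report(c(0.9, 0.5), 2.0), 2)$gap_present)
  expect_false(barcode_gap(fake_report(c(2.5, 0.5), 2.0), 2)$gap_present)
  expect_false(barcode_gap(fake_report(c(0.9, 0.5), 1.9), 2)$gap_present)

  # degenerate single group: empty verdict set
  s <- seq_set(c(a = "ACGT", b = "ACGT"))
  rep1 <- group_divergence(build_matrix(s), c("G", "G"))
  expect_equal(nrow(barcode_gap(rep1, 2)), 0L)
})

test_that("single-linkage delimitation joins strictly below the threshold", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.005
  d["a", "c"] <- d["c", "a"] <- 0.030
  d["b", "c"] <- d["c", "b"] <- 0.032
  d["a", "d"] <- d["d", "a"] <- 0.020   # exactly at a 2% threshold
  d["b", "d"] <- d["d", "b"] <- 0.021
  d["c", "d"] <- d["d", "c"] <- 0.028
  m <- structure(list(labels = letters[1:4], d = d, metric = "k2p"),
                 class = "dist_matrix")
  cl <- delimit_clusters(m, 2.0)
  expect_equal(unname(cl), c(1, 1, 2, 3))  # 2.0% pair stays split (strict <)
  expect_equal(length(unique(delimit_clusters(m, 100))), 1L)
  expect_equal(length(unique(delimit_clusters(m, 0))), 4L)
})

test_that("percent rounding is half away from zero at one decimal", {
  expect_equal(percent_1dp(3.4378), 3.4)
  expect_equal(percent_1dp(0.15), 0.2)   # not banker's 0.1
  expect_equal(percent_1dp(-0.15), -0.2)
})
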