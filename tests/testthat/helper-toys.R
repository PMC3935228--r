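# Small generators shared across test files.

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_at <- function(s, pos, to) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- to
  paste(v, collapse = "")
}

# brute-force substitution recount, independent of pairwise_counts
brute_counts <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  keep <- x %in% acgt & y %in% acgt
  x <- x[keep]; y <- y[keep]
  ts <- 0L; tv <- 0L
  for (i in seq_along(x)) {
    if (x[i] == y[i]) next
    pair <- sort(c(x[i], y[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
      ts <- ts + 1L
    } else tv <- tv + 1L
  }
  list(n = length(x), ts = ts, tv = tv)
}

# a random unrooted binary tree with strictly positive branch lengths,
# used to manufacture additive distance matrices
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.05, 0.5))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}
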