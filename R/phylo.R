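# BioNJ tree construction, column-resampling bootstrap and newick output.
# Trees are represented as ape "phylo" objects throughout.

quote_newick_label <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.|-]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

fmt_len <- function(x) sprintf("%.12g", x)

#' BioNJ distance tree
#'
#' Neighbor joining with the variance-weighted matrix reduction of the
#' BioNJ algorithm: pairs are agglomerated by the standard NJ Q criterion,
#' branch lengths follow the usual split formulas, and the distance to a
#' new node is the variance-optimal convex combination of the distances
#' to its two children. The output is deterministic: when several pairs
#' tie on the Q criterion the pair whose contained leaf labels sort first
#' is chosen. Negative branch lengths are kept as computed (preserving
#' additivity) and flagged with a message.
#'
#' @param m a `dist_matrix` from [build_matrix()], a [stats::dist], or a
#'   symmetric numeric matrix with dimnames.
#' @return an unrooted `phylo` (class from \pkg{ape}) with branch lengths
#'   in the input's units.
#' @export
bionj_tree <- function(m) {
  D <- if (inherits(m, "dist_matrix")) m$d else as.matrix(m)
  if (is.null(rownames(D))) stop("distance matrix needs labels", call. = FALSE)
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric",
                                    call. = FALSE)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labs <- rownames(D)
  V <- D
  frag <- quote_newick_label(labs)   # newick fragment per active node
  rep_lab <- labs                    # smallest contained leaf label
  active <- seq_len(n)
  saw_negative <- FALSE

  while (length(active) > 3L) {
    r <- length(active)
    Da <- D[active, active, drop = FALSE]
    S <- rowSums(Da)
    Qc <- (r - 2) * Da - outer(S, S, "+")
    diag(Qc) <- Inf
    qmin <- min(Qc)
    cand <- which(Qc - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[active[ij[1]]], rep_lab[active[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    best <- cand[order(key)[1L], ]
    i <- active[best[1]]; j <- active[best[2]]
    dij <- D[i, j]
    bi <- 0.5 * dij + (S[best[1]] - S[best[2]]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0 || bj < 0) saw_negative <- TRUE

    others <- setdiff(active, c(i, j))
    lambda <- if (V[i, j] > 0 && length(others)) {
      0.5 + sum(V[j, others] - V[i, others]) / (2 * (r - 2) * V[i, j])
    } else 0.5
    lambda <- min(1, max(0, lambda))

    newD <- lambda * (D[i, others] - bi) + (1 - lambda) * (D[j, others] - bj)
    newV <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
      lambda * (1 - lambda) * V[i, j]
    # reuse slot i for the merged node
    D[i, others] <- D[others, i] <- newD
    V[i, others] <- V[others, i] <- newV
    D[i, i] <- V[i, i] <- 0
    frag[i] <- paste0("(", frag[i], ":", fmt_len(bi), ",",
                      frag[j], ":", fmt_len(bj), ")")
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  ba <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  bb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  bc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  if (min(ba, bb, bc) < 0) saw_negative <- TRUE
  if (saw_negative) message("bionj_tree: negative branch length(s) kept as computed")
  nwk <- paste0("(", frag[a], ":", fmt_len(ba), ",",
                frag[b], ":", fmt_len(bb), ",",
                frag[c3], ":", fmt_len(bc), ");")
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; a split is keyed by the
#' side that does not contain the alphabetically smallest leaf label, so
#' keys are invariant to leaf order and to any display rooting.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (sorted labels joined
#'   by `"|"`), one per internal edge.
#' @export
tree_splits <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- tips[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L)
      return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Column-resampling bootstrap supports on a BioNJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and BioNJ tree for each replicate, and counts how often each
#' internal edge (bipartition) of the full-data tree recurs. Supports are
#' percentages of the successful replicates and are stored in the node
#' labels of the returned tree. Replicates whose resampled distances are
#' saturated are skipped and counted in `attr(tree, "n_skipped")`.
#' Bipartition counts are streamed; replicate trees are not retained.
#'
#' @param seqs an aligned [seq_set()].
#' @param metric `"k2p"` or `"p"`.
#' @param n_reps number of replicates (>= 1; default 100).
#' @param seed integer seed; the run is reproducible.
#' @return the full-data `phylo` with node labels holding percent
#'   supports, and attributes `n_reps` and `n_skipped`.
#' @export
bootstrap_tree <- function(seqs, metric = c("k2p", "p"), n_reps = 100L,
                           seed) {
  metric <- match.arg(metric)
  assert_aligned(seqs, "bootstrap")
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required for the bootstrap",
                          call. = FALSE)
  full <- bionj_tree(build_matrix(seqs, metric = metric))
  L <- seqs$alignment_length
  mat <- do.call(rbind, strsplit(unname(seqs$seqs), ""))
  rownames(mat) <- seqs$ids

  counts <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))
  n_skipped <- 0L
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- seq_set(apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
                  ids = seqs$ids)
    tr <- tryCatch(
      suppressMessages(bionj_tree(build_matrix(rs, metric = metric))),
      error = function(e) NULL)
    if (is.null(tr)) { n_skipped <- n_skipped + 1L; next }
    for (key in tree_splits(tr)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  n_ok <- n_reps - n_skipped
  if (n_ok == 0L) stop("all bootstrap replicates were saturated",
                       call. = FALSE)

  tips <- full$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(full)
  node_lab <- vapply(seq_along(parts), function(k) {
    side <- tips[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) return("")
    key <- paste(sort(side), collapse = "|")
    cnt <- if (is.null(counts[[key]])) 0L else counts[[key]]
    as.character(percent_1dp(100 * cnt / n_ok))
  }, "")
  full$node.label <- node_lab
  attr(full, "n_reps") <- as.integer(n_reps)
  attr(full, "n_skipped") <- n_skipped
  full
}

write_newick_node <- function(tree, node, n_tip) {
  if (node <= n_tip) return(quote_newick_label(tree$tip.label[node]))
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sub <- vapply(kids, function(k) {
    e <- which(tree$edge[, 1] == node & tree$edge[, 2] == k)
    len <- if (!is.null(tree$edge.length))
      paste0(":", fmt_len(tree$edge.length[e])) else ""
    paste0(write_newick_node(tree, k, n_tip), len)
  }, "")
  lab <- if (!is.null(tree$node.label)) {
    l <- tree$node.label[node - n_tip]
    if (is.na(l) || !nzchar(l)) "" else quote_newick_label(l)
  } else ""
  paste0("(", paste(sub, collapse = ","), ")", lab)
}

#' Write a tree to a newick file
#'
#' Branch lengths are always written; node labels (bootstrap supports)
#' are written as internal labels; labels containing whitespace or newick
#' metacharacters are single-quoted. Trees are emitted as built
#' (unrooted); an outgroup may be named to root the displayed tree.
#'
#' @param tree a `phylo`.
#' @param path output file; `NULL` returns the newick string invisibly
#'   without writing.
#' @param outgroup optional tip label to root at for display.
#' @return invisibly, the newick string.
#' @export
write_newick <- function(tree, path = NULL, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a tip", call. = FALSE)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  nwk <- paste0(write_newick_node(tree, root, n_tip), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}
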