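# Pairwise substitution counting, Kimura 2-parameter correction, distance
# matrices, group divergence statistics and barcode-gap delimitation.

#' Round a percentage half away from zero to one decimal
#'
#' Matches the conventional reporting style for barcode distances
#' (e.g. 3.4%); base `round()` rounds half to even and is unsuitable.
#'
#' @param x numeric vector of percentages.
#' @return numeric vector rounded to one decimal.
#' @export
percent_1dp <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Count substitutions between two aligned sequences
#'
#' Columns where either residue is a gap or an IUPAC ambiguity code are
#' excluded (pairwise deletion). Transitions are A/G and C/T; every other
#' differing unambiguous pair is a transversion. An optional 1-based
#' closed range restricts the comparison to an alignment segment.
#'
#' @param s1,s2 sequence strings of equal length (or single-record
#'   subsets of a [seq_set()] given as named strings).
#' @param range optional `c(start, end)` 1-based closed interval.
#' @param ids length-2 identifiers used in error messages.
#' @return an object of class `dist_result`: a list with `n_sites`,
#'   `n_diff`, `transitions`, `transversions`, `p`, `P`, `Q` and `d_k2p`
#'   (substitutions/site; see [k2p()]).
#' @examples
#' pairwise_counts("ACGT", "ACAT")
#' @export
pairwise_counts <- function(s1, s2, range = NULL, ids = c("seq1", "seq2")) {
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (nchar(s1) != nchar(s2)) {
    stop("sequences '", ids[1], "' (", nchar(s1), " bp) and '", ids[2],
         "' (", nchar(s2), " bp) have unequal lengths", call. = FALSE)
  }
  x <- seq_chars(s1); y <- seq_chars(s2)
  if (!is.null(range)) {
    stopifnot(length(range) == 2L)
    if (range[1] < 1L || range[2] > length(x) || range[1] > range[2]) {
      stop("range [", range[1], ", ", range[2],
           "] outside alignment bounds 1..", length(x), call. = FALSE)
    }
    idx <- range[1]:range[2]
    x <- x[idx]; y <- y[idx]
  }
  keep <- is_unambiguous(x) & is_unambiguous(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) {
    stop("no comparable sites between '", ids[1], "' and '", ids[2],
         "' after pairwise deletion", call. = FALSE)
  }
  diff <- x != y
  purine_x <- x %in% c("A", "G")
  purine_y <- y %in% c("A", "G")
  ts <- sum(diff & (purine_x == purine_y))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  res <- structure(
    list(n_sites = n, n_diff = as.integer(sum(diff)),
         transitions = as.integer(ts), transversions = as.integer(tv),
         p = (ts + tv) / n, P = P, Q = Q, d_k2p = NA_real_),
    class = "dist_result"
  )
  # d_k2p is NA for saturated pairs; k2p() and any k2p-metric pipeline
  # raise the saturation error loudly, but p-metric uses stay usable
  res$d_k2p <- tryCatch(k2p(res), error = function(e) NA_real_)
  res
}

#' @export
print.dist_result <- function(x, ...) {
  cat(sprintf(
    "dist_result: %d sites, %d diffs (%d ts + %d tv); p = %.4f, K2P d = %.4f (%.1f%%)\n",
    x$n_sites, x$n_diff, x$transitions, x$transversions, x$p, x$d_k2p,
    percent_1dp(100 * x$d_k2p)))
  invisible(x)
}

#' Kimura 2-parameter distance
#'
#' Corrects observed transition and transversion proportions for multiple
#' hits under a model with distinct transition and transversion rates:
#' `d = -log((1 - 2P - Q) * sqrt(1 - 2Q)) / 2`, in substitutions per site.
#' The correction never shrinks the observed distance (`d >= p`).
#'
#' @param x a `dist_result` from [pairwise_counts()], or the transition
#'   proportion `P` as a plain number.
#' @param Q transversion proportion, required when `x` is numeric.
#' @return the K2P distance in substitutions/site. Saturated inputs
#'   (either logarithm argument non-positive) raise an error rather than
#'   returning infinity.
#' @examples
#' k2p(0.25, 0)  # -log(0.5)/2
#' @export
k2p <- function(x, Q = NULL) {
  if (inherits(x, "dist_result")) {
    P <- x$P; Q <- x$Q
  } else {
    P <- x
    if (is.null(Q)) stop("Q is required when P is given as a number",
                         call. = FALSE)
  }
  stopifnot(is.numeric(P), is.numeric(Q), P >= 0, Q >= 0)
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) {
    stop("saturated distance: K2P undefined for P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), call. = FALSE)
  }
  -0.5 * log(a * sqrt(b))
}

#' Build a pairwise distance matrix from an aligned sequence set
#'
#' @param seqs an aligned [seq_set()] with at least two records.
#' @param metric `"k2p"` (default) or `"p"` (uncorrected proportion).
#' @param range optional 1-based closed interval restricting all
#'   comparisons to an alignment segment.
#' @return an object of class `dist_matrix`: a list with `labels`,
#'   `d` (symmetric numeric matrix, substitutions/site, zero diagonal),
#'   `n_diff` and `n_sites` (integer matrices), and `metric`. Percent
#'   distances are `100 * x$d`.
#' @export
build_matrix <- function(seqs, metric = c("k2p", "p"), range = NULL) {
  metric <- match.arg(metric)
  assert_aligned(seqs, "distance matrix construction")
  n <- length(seqs$ids)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(seqs$ids, seqs$ids))
  nd <- matrix(0L, n, n, dimnames = dimnames(d))
  ns <- matrix(NA_integer_, n, n, dimnames = dimnames(d))
  diag(ns) <- if (is.null(range)) seqs$alignment_length else
    as.integer(range[2] - range[1] + 1)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pc <- tryCatch(
        pairwise_counts(seqs$seqs[i], seqs$seqs[j], range = range,
                        ids = seqs$ids[c(i, j)]),
        error = function(e) {
          stop("pair (", seqs$ids[i], ", ", seqs$ids[j], "): ",
               conditionMessage(e), call. = FALSE)
        })
      if (metric == "k2p" && is.na(pc$d_k2p)) {
        stop("pair (", seqs$ids[i], ", ", seqs$ids[j],
             "): saturated distance, K2P undefined", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- if (metric == "k2p") pc$d_k2p else pc$p
      nd[i, j] <- nd[j, i] <- pc$n_diff
      ns[i, j] <- ns[j, i] <- pc$n_sites
    }
  }
  structure(list(labels = seqs$ids, d = d, n_diff = nd, n_sites = ns,
                 metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$metric, "), ", length(x$labels),
      " taxa; percent distances:\n", sep = "")
  print(round(100 * x$d, 2))
  invisible(x)
}

#' Coerce a dist_matrix to a plain numeric matrix or stats::dist
#' @param x a `dist_matrix`.
#' @param percent return percentages instead of substitutions/site.
#' @return symmetric numeric matrix.
#' @export
as_matrix <- function(x, percent = FALSE) {
  stopifnot(inherits(x, "dist_matrix"))
  if (percent) 100 * x$d else x$d
}

#' Within- and between-group divergence statistics
#'
#' Within-group statistics (mean, sample standard deviation with `n - 1`
#' denominator, maximum) are computed over unordered within-group pairs
#' and reported as `NA` — absent, not zero — for singleton groups.
#' Between-group statistics (minimum, mean, maximum) are over all
#' cross-group pairs.
#'
#' @param m a `dist_matrix` from [build_matrix()].
#' @param labels group assignment: a character vector named by matrix
#'   label, or an unnamed vector in matrix-label order.
#' @param percent report statistics in percent (default) or raw
#'   substitutions/site.
#' @return an object of class `group_divergence`: a list with data frames
#'   `within` (`group`, `n`, `n_pairs`, `mean`, `sd`, `max`) and
#'   `between` (`group1`, `group2`, `min`, `mean`, `max`), plus `scale`.
#' @export
group_divergence <- function(m, labels, percent = TRUE) {
  stopifnot(inherits(m, "dist_matrix"))
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(m$labels))
    labels <- stats::setNames(as.character(labels), m$labels)
  }
  unknown <- setdiff(m$labels, names(labels))
  if (length(unknown)) {
    stop("no group assignment for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grp <- unname(labels[m$labels])
  d <- if (percent) 100 * m$d else m$d
  groups <- sort(unique(grp))
  within <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(grp == g)
    vals <- if (length(idx) >= 2L) d[idx, idx][upper.tri(d[idx, idx])] else
      numeric()
    data.frame(group = g, n = length(idx), n_pairs = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) >= 2L) stats::sd(vals) else
                 if (length(vals) == 1L) NA_real_ else NA_real_,
               max = if (length(vals)) max(vals) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  between <- if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- which(grp == pairs[1, k]); j <- which(grp == pairs[2, k])
      vals <- as.vector(d[i, j, drop = FALSE])
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 min = min(vals), mean = mean(vals), max = max(vals),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group1 = character(), group2 = character(),
               min = numeric(), mean = numeric(), max = numeric())
  }
  structure(list(within = within, between = between,
                 scale = if (percent) "percent" else "subst/site"),
            class = "group_divergence")
}

#' @export
print.group_divergence <- function(x, ...) {
  cat("group divergence (", x$scale, ")\nwithin groups:\n", sep = "")
  print(x$within, row.names = FALSE)
  cat("between groups:\n")
  print(x$between, row.names = FALSE)
  invisible(x)
}

#' Barcode-gap verdict for each group pair
#'
#' A pair of groups shows a barcode gap at a threshold when the larger of
#' the two within-group maxima lies below the threshold and the smallest
#' between-group distance is at least the threshold. The realized hiatus
#' interval `(max_within, min_between)` is reported alongside. Within
#' maxima that are absent (singleton groups) do not constrain the gap.
#'
#' @param report a `group_divergence` from [group_divergence()].
#' @param threshold gap threshold on the report's scale (default 2,
#'   i.e. 2% for percent-scale reports).
#' @return data frame with one row per group pair: `group1`, `group2`,
#'   `max_within`, `min_between`, `gap_present`, `threshold`.
#' @export
barcode_gap <- function(report, threshold = 2) {
  stopifnot(inherits(report, "group_divergence"))
  bt <- report$between
  if (nrow(bt) == 0L) {
    return(data.frame(group1 = character(), group2 = character(),
                      max_within = numeric(), min_between = numeric(),
                      gap_present = logical(), threshold = numeric()))
  }
  wmax <- stats::setNames(report$within$max, report$within$group)
  out <- do.call(rbind, lapply(seq_len(nrow(bt)), function(k) {
    w <- wmax[c(bt$group1[k], bt$group2[k])]
    mw <- if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
    data.frame(group1 = bt$group1[k], group2 = bt$group2[k],
               max_within = mw, min_between = bt$min[k],
               gap_present = (is.na(mw) || mw < threshold) &&
                 bt$min[k] >= threshold,
               threshold = threshold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Single-linkage cluster delimitation at a distance threshold
#'
#' Joins every pair of records whose distance is strictly below the
#' threshold and takes connected components, operationalizing
#' threshold-based species delimitation. Clusters are numbered by the
#' alphabetically smallest label they contain, so the assignment is
#' deterministic.
#'
#' @param m a `dist_matrix`.
#' @param threshold joining threshold in percent.
#' @return named integer vector of cluster ids, one per matrix label.
#' @export
delimit_clusters <- function(m, threshold) {
  stopifnot(inherits(m, "dist_matrix"), is.numeric(threshold))
  labs <- m$labels
  n <- length(labs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pct <- 100 * m$d
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pct[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comp_min_label <- vapply(unique(roots), function(r) {
    min(labs[roots == r])
  }, "")
  order_ids <- stats::setNames(rank(comp_min_label), unique(roots))
  stats::setNames(as.integer(order_ids[as.character(roots)]), labs)
}
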