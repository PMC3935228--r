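# Genitalic ratio discriminant and exact two-group linear separability.

#' Morphometric discriminant scores from six genitalic lengths
#'
#' Maps the six measured lengths of the male genitalia — uncus width at
#' the apex (`a`) and at the narrowest point near the base (`b`),
#' distances from the uncus apex to the widest (`c`) and narrowest (`d`)
#' cross-sections, and the valval dorsal "window" length (`l`) and valva
#' height at its end (`h`) — onto two dimensionless coordinates:
#' `u = a/b + weight * c/d` (uncus shape; the second ratio is
#' down-weighted, default 0.5) and `v = h/l` (valva base shape). Being
#' ratios, the scores are invariant to uniform scaling, so measurement
#' units need only be consistent within a specimen.
#'
#' @param m data frame with columns `a`, `b`, `c`, `d`, `l`, `h` (all
#'   strictly positive), plus any identifier/label columns, which are
#'   carried through.
#' @param weight weight of the `c/d` ratio (default 0.5).
#' @return the input data frame with columns `u` and `v` appended.
#' @examples
#' morpho_score(data.frame(a = 2, b = 1, c = 1, d = 2, l = 2, h = 3))
#' @export
morpho_score <- function(m, weight = 0.5) {
  needed <- c("a", "b", "c", "d", "l", "h")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols)) {
    stop("missing measurement column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(m[needed])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all six measurements must be strictly positive", call. = FALSE)
  }
  m$u <- m$a / m$b + weight * m$c / m$d
  m$v <- m$h / m$l
  m
}

# candidate directions for an exact 2-D linear classifier search:
# normals to lines through every point pair, all cross-class difference
# vectors, and the axes. For strict separation the optimal direction is
# realized at a vertex-vertex or vertex-edge closest-pair of the convex
# hulls, both of which are covered. Each pair normal is also included
# rotated by +/- a tiny angle: an error-minimizing boundary through two
# points may need those two points on opposite sides, which only a
# perturbed direction can express through a threshold.
candidate_directions <- function(X, y) {
  dirs <- list(c(1, 0), c(0, 1))
  eps <- 1e-7
  rot <- function(w, t) c(w[1] - t * w[2], w[2] + t * w[1])
  n <- nrow(X)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- X[j, ] - X[i, ]
      if (sum(v^2) < 1e-24) next
      w <- c(-v[2], v[1])                            # normal to the pair line
      dirs <- c(dirs, list(w, rot(w, eps), rot(w, -eps)))
      if (y[i] != y[j]) dirs[[length(dirs) + 1L]] <- v
    }
  }
  dirs <- do.call(rbind, dirs)
  dirs / sqrt(rowSums(dirs^2))
}

#' Exact two-group linear separability in the (u, v) plane
#'
#' Decides whether a straight line classifies all points correctly
#' (strict separation, equivalent to disjoint convex hulls) by testing
#' the finite set of candidate directions at which a strictly separating
#' projection must exist. If separable, one witness boundary
#' `w1*u + w2*v = b` with maximal margin among the candidates is
#' returned; otherwise the minimum misclassification count achievable by
#' any line, found by optimal 1-D thresholding along each candidate
#' direction.
#'
#' @param points data frame with columns `u`, `v` and a label column, or
#'   a two-column matrix plus `labels`.
#' @param labels binary class labels (ignored when `points` has a
#'   `species`/`label` column).
#' @return an object of class `separability`: list with `separable`
#'   (logical), `boundary` (named vector `w1`, `w2`, `b`, or `NULL`) and
#'   `min_misclassified` (0 when separable).
#' @examples
#' separability(data.frame(u = c(1, 3), v = c(1, 3),
#'                         species = c("A", "B")))
#' @export
separability <- function(points, labels = NULL) {
  if (is.data.frame(points)) {
    lab_col <- intersect(c("species", "label", "group"), names(points))
    if (is.null(labels) && length(lab_col)) labels <- points[[lab_col[1]]]
    X <- cbind(points$u, points$v)
  } else {
    X <- as.matrix(points)
  }
  if (is.null(labels)) stop("class labels are required", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("exactly two classes are required; got ",
         length(classes), " (", paste(classes, collapse = ", "), ")",
         call. = FALSE)
  }
  if (min(table(labels)) < 1L) stop("one class is empty", call. = FALSE)
  y <- labels == classes[1]
  dirs <- candidate_directions(X, y)

  best_margin <- -Inf
  best_boundary <- NULL
  min_err <- Inf
  for (k in seq_len(nrow(dirs))) {
    w <- dirs[k, ]
    pr <- X %*% w
    pa <- pr[y]; pb <- pr[!y]
    # strict separation in this direction?
    gap1 <- min(pa) - max(pb)   # class A above
    gap2 <- min(pb) - max(pa)   # class B above
    if (max(gap1, gap2) > 0 && max(gap1, gap2) > best_margin) {
      best_margin <- max(gap1, gap2)
      thr <- if (gap1 > gap2) (min(pa) + max(pb)) / 2 else
        (min(pb) + max(pa)) / 2
      best_boundary <- c(w1 = w[1], w2 = w[2], b = thr)
    }
    # optimal 1-D threshold error along w (thresholds at midpoints
    # between consecutive distinct projections, plus both extremes)
    vals <- sort(unique(pr))
    thr_cand <- c(vals[1] - 1, (utils::head(vals, -1) + vals[-1]) / 2,
                  vals[length(vals)] + 1)
    for (t in thr_cand) {
      above_a <- sum(pa > t); above_b <- sum(pb > t)
      err <- min((length(pa) - above_a) + above_b,      # A above, B below
                 (length(pb) - above_b) + above_a)      # B above, A below
      if (err < min_err) min_err <- err
    }
  }
  structure(
    list(separable = is.finite(best_margin) && best_margin > 0,
         boundary = best_boundary,
         min_misclassified = if (!is.null(best_boundary)) 0L
         else as.integer(min_err),
         classes = classes),
    class = "separability"
  )
}

#' @export
print.separability <- function(x, ...) {
  if (x$separable) {
    cat(sprintf(
      "separable: boundary %.4g*u + %.4g*v = %.4g splits %s from %s\n",
      x$boundary["w1"], x$boundary["w2"], x$boundary["b"],
      x$classes[1], x$classes[2]))
  } else {
    cat("not separable: minimum misclassification count =",
        x$min_misclassified, "\n")
  }
  invisible(x)
}
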