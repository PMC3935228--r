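# Diagnostic-site discovery, ID-tag window selection, degenerate-primer
# virtual PCR, and fragment-based species calling. Coordinates are 1-based
# closed intervals on the plus strand throughout.

seq_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs$seqs), ""))
  rownames(m) <- seqs$ids
  m
}

resolve_groups <- function(seqs, labels) {
  if (is.null(labels)) labels <- stats::setNames(seqs$species, seqs$ids)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(seqs$ids))
    labels <- stats::setNames(as.character(labels), seqs$ids)
  }
  grp <- unname(labels[seqs$ids])
  if (anyNA(grp)) {
    stop("no group label for: ",
         paste(seqs$ids[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  grp
}

#' Find fixed diagnostic positions between labeled groups
#'
#' A column is diagnostic when every chosen group is invariant and
#' unambiguous (A/C/G/T only) at that column and the group states are not
#' all equal. With more than two groups a column qualifies as soon as any
#' pair of groups differs there; all group states are recorded.
#'
#' @param seqs an aligned [seq_set()].
#' @param labels group assignment (named by record id, or in record
#'   order); defaults to the set's species labels.
#' @param groups subset of at least two group labels to compare; default
#'   all labels present.
#' @return an object of class `diagnostic_sites`: a data frame with
#'   `position` (ascending, 1-based) and one state column per group; the
#'   alignment length is kept in `attr(, "alignment_length")`.
#' @export
find_diagnostic_sites <- function(seqs, labels = NULL, groups = NULL) {
  assert_aligned(seqs, "diagnostic-site discovery")
  grp <- resolve_groups(seqs, labels)
  if (is.null(groups)) groups <- sort(unique(grp))
  unknown <- setdiff(groups, grp)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  m <- seq_matrix(seqs)
  # per-group consensus state, NA where a group is variable or ambiguous
  states <- sapply(groups, function(g) {
    sub <- m[grp == g, , drop = FALSE]
    apply(sub, 2L, function(col) {
      u <- unique(col)
      if (length(u) == 1L && is_unambiguous(u)) u else NA_character_
    })
  })
  ok <- rowSums(is.na(states)) == 0L &
    apply(states, 1L, function(s) length(unique(s)) > 1L)
  out <- data.frame(position = which(ok), states[ok, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "alignment_length") <- seqs$alignment_length
  attr(out, "groups") <- groups
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

site_groups <- function(sites) {
  g <- attr(sites, "groups")
  if (is.null(g)) setdiff(names(sites), "position") else g
}

#' Rank candidate ID-tag windows by diagnostic content
#'
#' Slides a fixed-length window over the alignment and scores each start
#' by `(pair_min, site_count)` compared lexicographically, where
#' `pair_min` is the minimum over group pairs of the number of in-window
#' sites separating that pair: the weakest pairwise discrimination is
#' maximized first. Ties prefer the smaller start; windows containing an
#' identical set of sites are collapsed to the leftmost.
#'
#' @param sites a `diagnostic_sites` object.
#' @param window_len window length in columns (>= 1).
#' @param alignment_length total alignment columns (default: recorded on
#'   `sites`).
#' @param top_k number of windows to return (default 5).
#' @return data frame with `start`, `end`, `length`, `site_count`,
#'   `pair_min`, ranked best-first.
#' @export
select_tag_windows <- function(sites, window_len,
                               alignment_length = attr(sites, "alignment_length"),
                               top_k = 5L) {
  if (window_len < 1L) stop("window_len must be >= 1", call. = FALSE)
  if (is.null(alignment_length)) stop("alignment_length unknown", call. = FALSE)
  if (window_len > alignment_length) {
    stop("window_len exceeds alignment length", call. = FALSE)
  }
  groups <- site_groups(sites)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      site_count = integer(), pair_min = integer())
  if (nrow(sites) == 0L) return(empty)
  pairs <- utils::combn(groups, 2L)
  # indicator per position: does this site separate pair k?
  sep <- sapply(seq_len(ncol(pairs)), function(k) {
    sites[[pairs[1, k]]] != sites[[pairs[2, k]]]
  })
  sep <- matrix(sep, nrow = nrow(sites))
  starts <- seq_len(alignment_length - window_len + 1L)
  res <- do.call(rbind, lapply(starts, function(s) {
    inw <- sites$position >= s & sites$position <= s + window_len - 1L
    data.frame(start = s, end = s + window_len - 1L,
               length = as.integer(window_len),
               site_count = sum(inw),
               pair_min = if (any(inw))
                 as.integer(min(colSums(sep[inw, , drop = FALSE]))) else 0L,
               key = paste(sites$position[inw], collapse = ","))
  }))
  res <- res[res$site_count > 0L, , drop = FALSE]
  if (nrow(res) == 0L) return(empty)
  res <- res[!duplicated(res$key), , drop = FALSE]   # leftmost per site set
  res <- res[order(-res$pair_min, -res$site_count, res$start), , drop = FALSE]
  res$key <- NULL
  rownames(res) <- NULL
  utils::head(res, top_k)
}

#' Locate primer binding sites on a template
#'
#' Forward primers are matched as written against the plus strand;
#' reverse primers are matched through their reverse complement. A primer
#' residue matches a template residue when their IUPAC sets intersect
#' (degenerate bases match any expansion); no mismatches are tolerated.
#'
#' @param template a sequence string or single-record [seq_set()].
#' @param primer primer sequence string (IUPAC).
#' @param orientation `"forward"` or `"reverse"`.
#' @return data frame of 1-based closed binding intervals (`start`,
#'   `end`) on the plus strand; zero rows when the primer does not bind.
#' @examples
#' match_primer("CCTTGAGCAGGAATAATTGGAACATCC", "TTGAGCAGGAATAATTGGWACAT")
#' @export
match_primer <- function(template, primer,
                         orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (inherits(template, "seq_set")) {
    stopifnot(length(template$ids) == 1L)
    template <- template$seqs[[1]]
  }
  template <- toupper(template)
  primer <- toupper(primer)
  validate_residues(template, "<template>")
  validate_residues(primer, "<primer>")
  if (orientation == "reverse") primer <- revcomp(primer)
  tm <- iupac_mask(seq_chars(template))
  pm <- iupac_mask(seq_chars(primer))
  L <- length(tm); k <- length(pm)
  if (k > L) return(data.frame(start = integer(), end = integer()))
  ok <- rep(TRUE, L - k + 1L)
  for (off in seq_len(k)) {
    ok <- ok & bitwAnd(tm[off:(L - k + off)], pm[off]) > 0L
  }
  starts <- which(ok)
  data.frame(start = starts, end = starts + k - 1L)
}

#' Virtual PCR with one degenerate primer pair
#'
#' Requires each primer to bind exactly once, with the forward site
#' strictly upstream of the reverse site; anything else — no binding,
#' multiple bindings (non-specific amplification), or reversed order —
#' aborts with an error. The insert is the template segment strictly
#' between the two binding intervals.
#'
#' @param template a sequence string or single-record [seq_set()].
#' @param fwd,rev primer sequences (IUPAC strings); `rev` is given 5'-3'
#'   on the minus strand, as primers are ordered.
#' @param template_id identifier for reporting.
#' @return an object of class `amplicon`: list with `template_id`,
#'   `fwd_interval`, `rev_interval` (1-based closed, plus strand),
#'   `insert`, `insert_len` and `product_len`
#'   (`insert_len + nchar(fwd) + nchar(rev)`).
#' @export
virtual_pcr <- function(template, fwd, rev, template_id = "template") {
  if (inherits(template, "seq_set")) {
    stopifnot(length(template$ids) == 1L)
    template_id <- template$ids[1]
    template <- template$seqs[[1]]
  }
  template <- toupper(template)
  fhit <- match_primer(template, fwd, "forward")
  rhit <- match_primer(template, rev, "reverse")
  if (nrow(fhit) != 1L) {
    stop("forward primer binds ", nrow(fhit), " time(s) on ", template_id,
         " (need exactly 1)", call. = FALSE)
  }
  if (nrow(rhit) != 1L) {
    stop("reverse primer binds ", nrow(rhit), " time(s) on ", template_id,
         " (need exactly 1)", call. = FALSE)
  }
  if (rhit$start <= fhit$end) {
    stop("primer orientation/order violation on ", template_id,
         ": reverse-binding site [", rhit$start, ", ", rhit$end,
         "] does not lie downstream of forward-binding site [",
         fhit$start, ", ", fhit$end, "]", call. = FALSE)
  }
  insert <- substr(template, fhit$end + 1L, rhit$start - 1L)
  structure(
    list(template_id = template_id,
         fwd_interval = c(fhit$start, fhit$end),
         rev_interval = c(rhit$start, rhit$end),
         insert = insert,
         insert_len = nchar(insert),
         product_len = nchar(insert) + nchar(fwd) + nchar(rev)),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf(
    "amplicon on %s: fwd [%d, %d], rev [%d, %d]; insert %d bp, product %d bp\n",
    x$template_id, x$fwd_interval[1], x$fwd_interval[2],
    x$rev_interval[1], x$rev_interval[2], x$insert_len, x$product_len))
  invisible(x)
}

#' Call the species of a (possibly degraded) fragment
#'
#' Scores the fragment at every diagnostic site it covers. The verdict is
#' a group label only when every scorable site matches exactly that
#' group; `"ambiguous"` when several groups remain compatible;
#' `"contaminated"` when sites support different groups or ambiguity
#' codes appear at diagnostic sites (the signature of mixed templates);
#' `"no-match"` when no site is scorable or a single site matches no
#' group.
#'
#' @param fragment fragment sequence string (or single-record
#'   [seq_set()]).
#' @param sites a `diagnostic_sites` profile (optionally restricted to a
#'   tag window).
#' @param offset 1-based alignment position of the fragment's first
#'   residue.
#' @return an object of class `species_call`: list with `verdict` and
#'   `evidence` (data frame: `position`, `observed`, `matching_groups`).
#' @export
call_species <- function(fragment, sites, offset) {
  if (inherits(fragment, "seq_set")) {
    stopifnot(length(fragment$ids) == 1L)
    fragment <- fragment$seqs[[1]]
  }
  fragment <- toupper(fragment)
  validate_residues(fragment, "<fragment>")
  aln_len <- attr(sites, "alignment_length")
  if (offset < 1L || (!is.null(aln_len) &&
                      offset + nchar(fragment) - 1L > aln_len)) {
    stop("fragment at offset ", offset, " does not map onto the ",
         aln_len, "-column alignment", call. = FALSE)
  }
  groups <- site_groups(sites)
  inw <- sites$position >= offset &
    sites$position <= offset + nchar(fragment) - 1L
  sub <- sites[inw, , drop = FALSE]
  fr <- seq_chars(fragment)
  evidence <- do.call(rbind, lapply(seq_len(nrow(sub)), function(k) {
    obs <- fr[sub$position[k] - offset + 1L]
    matches <- groups[vapply(groups, function(g) {
      is_unambiguous(obs) && sub[[g]][k] == obs
    }, TRUE)]
    data.frame(position = sub$position[k], observed = obs,
               matching_groups = paste(matches, collapse = ","),
               ambiguous = !is_unambiguous(obs),
               stringsAsFactors = FALSE)
  }))
  if (is.null(evidence) || nrow(evidence) == 0L) {
    return(structure(list(verdict = "no-match",
                          evidence = data.frame(position = integer(),
                                                observed = character(),
                                                matching_groups = character(),
                                                ambiguous = logical())),
                     class = "species_call"))
  }
  match_sets <- strsplit(evidence$matching_groups, ",", fixed = TRUE)
  verdict <- if (any(evidence$ambiguous)) {
    "contaminated"
  } else {
    consistent <- Reduce(intersect, match_sets, groups)
    if (length(consistent) == 1L) {
      consistent
    } else if (length(consistent) > 1L) {
      "ambiguous"
    } else {
      # sites disagree: >= 2 sites backing different groups is the
      # contamination signature; a lone mismatching site is a no-match
      supported <- unique(unlist(match_sets))
      supported <- supported[nzchar(supported)]
      n_support <- sum(lengths(match_sets) > 0L)
      if (length(supported) >= 2L && n_support >= 2L) "contaminated"
      else "no-match"
    }
  }
  structure(list(verdict = verdict, evidence = evidence),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat("species call:", x$verdict, "(", nrow(x$evidence), "site(s) scored )\n")
  if (nrow(x$evidence)) print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Pairwise difference counts inside a tag window
#'
#' For each unordered pair of records, counts alignment columns within
#' the window at which both residues are unambiguous and differ.
#'
#' @param seqs an aligned [seq_set()].
#' @param window either a `c(start, end)` interval or one row of
#'   [select_tag_windows()] output.
#' @return data frame with `id1`, `id2`, `n_diff`.
#' @export
tag_difference_counts <- function(seqs, window) {
  assert_aligned(seqs, "tag difference counting")
  if (is.data.frame(window) || is.list(window)) {
    window <- c(window$start[1], window$end[1])
  }
  stopifnot(length(window) == 2L)
  if (window[1] < 1L || window[2] > seqs$alignment_length ||
      window[1] > window[2]) {
    stop("window [", window[1], ", ", window[2],
         "] outside alignment bounds", call. = FALSE)
  }
  m <- seq_matrix(seqs)[, window[1]:window[2], drop = FALSE]
  pairs <- utils::combn(seqs$ids, 2L)
  data.frame(
    id1 = pairs[1, ], id2 = pairs[2, ],
    n_diff = apply(pairs, 2L, function(p) {
      a <- m[p[1], ]; b <- m[p[2], ]
      sum(is_unambiguous(a) & is_unambiguous(b) & a != b)
    }),
    stringsAsFactors = FALSE
  )
}
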