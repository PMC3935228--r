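# Transition-biased barcode simulator, degraded-fragment generator and
# two-group morphometric sampler. Every generator is reproducible from an
# integer seed and returns a truth table alongside the data.

#' Configuration for the species-cluster barcode simulator
#'
#' Defaults emulate the study design the pipeline targets: a handful of
#' species whose consensus barcodes sit 2--4.5% (K2P) apart, individual
#' haplotypes within 1--3 substitutions of their species consensus (so
#' within-species divergence stays below 1%), transition-biased
#' substitution typical of insect mitochondrial DNA, and an AT-rich COI
#' base composition over 658 columns.
#'
#' @param n_species number of species clusters (default 3).
#' @param target_divergence symmetric matrix of desired pairwise K2P
#'   distances between species consensuses (substitutions/site, zero
#'   diagonal); default `c(0.02, 0.034, 0.045)` for three species.
#' @param kappa transition/transversion rate ratio (> 0, default 4).
#' @param base_composition frequencies of A, C, G, T summing to 1;
#'   default AT-rich `c(0.31, 0.15, 0.15, 0.39)`.
#' @param seq_length alignment columns (default 658).
#' @param n_per_species haplotypes sampled per species (default 20;
#'   recycled to `n_species`).
#' @param intra_max_diffs maximum substitutions separating a haplotype
#'   from its species consensus (default 3).
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 3L,
                              target_divergence = NULL,
                              kappa = 4,
                              base_composition = c(A = 0.31, C = 0.15,
                                                   G = 0.15, T = 0.39),
                              seq_length = 658L,
                              n_per_species = 20L,
                              intra_max_diffs = 3L,
                              seed = 1L) {
  if (is.null(target_divergence)) {
    if (n_species == 3L) {
      target_divergence <- matrix(0, 3, 3)
      target_divergence[lower.tri(target_divergence)] <- c(0.02, 0.034, 0.045)
      target_divergence <- target_divergence + t(target_divergence)
    } else {
      stop("target_divergence must be given for n_species != 3",
           call. = FALSE)
    }
  }
  target_divergence <- as.matrix(target_divergence)
  stopifnot(nrow(target_divergence) == n_species,
            isSymmetric(unname(target_divergence)),
            all(diag(target_divergence) == 0),
            all(target_divergence >= 0))
  # triangle inequality on the targets
  for (i in seq_len(n_species)) for (j in seq_len(n_species))
    for (k in seq_len(n_species)) {
      if (target_divergence[i, j] >
          target_divergence[i, k] + target_divergence[k, j] + 1e-12) {
        stop("target divergence grid violates the triangle inequality (",
             i, ",", j, ") > (", i, ",", k, ") + (", k, ",", j, ")",
             call. = FALSE)
      }
    }
  stopifnot(kappa > 0, seq_length >= 1, all(n_per_species >= 1),
            intra_max_diffs >= 0)
  if (abs(sum(base_composition) - 1) > 1e-9) {
    stop("base composition must sum to 1", call. = FALSE)
  }
  structure(list(
    n_species = as.integer(n_species),
    target_divergence = target_divergence,
    kappa = kappa,
    base_composition = base_composition,
    seq_length = as.integer(seq_length),
    n_per_species = rep_len(as.integer(n_per_species), n_species),
    intra_max_diffs = as.integer(intra_max_diffs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# draw a substituted base, transition with probability kappa/(kappa+1)
mutate_base <- function(base, kappa) {
  if (stats::runif(1) < kappa / (kappa + 1)) TRANSITION_OF[[base]]
  else sample(TRANSVERSIONS_OF[[base]], 1L)
}

# expected K2P distance when n of L sites differ and a fraction
# kappa/(kappa+1) of the differences are transitions
expected_k2p_for_count <- function(n, L, kappa) {
  tsf <- kappa / (kappa + 1)
  k2p(n * tsf / L, n * (1 - tsf) / L)
}

# smallest (real-valued) substitution count whose expected K2P hits d
count_for_divergence <- function(d, L, kappa) {
  if (d == 0) return(0)
  tsf <- kappa / (kappa + 1)
  # K2P saturates as 2P + Q -> 1, i.e. n -> L / (1 + tsf)
  upper <- 0.999 * L / (1 + tsf)
  if (expected_k2p_for_count(upper, L, kappa) < d) {
    stop("target divergence ", d, " unattainable at length ", L,
         call. = FALSE)
  }
  stats::uniroot(function(n) expected_k2p_for_count(n, L, kappa) - d,
                 c(1e-9, upper), tol = 1e-9)$root
}

#' Simulate a multi-species barcode alignment with known truth
#'
#' Draws one ancestral sequence from the configured base composition,
#' derives one consensus per species by placing transition-biased
#' substitutions at globally distinct positions (infinite-sites style, so
#' fixed inter-species differences exist by construction), with per-species
#' substitution counts solved from the target K2P grid, then derives each
#' individual haplotype by at most `intra_max_diffs` further substitutions
#' at unconstrained positions. Realized consensus-to-consensus K2P
#' distances are recomputed from the emitted sequences and must fall
#' within 10% relative error of each non-zero target, otherwise the
#' configuration is rejected as unattainable.
#'
#' @param cfg a [simulation_config()].
#' @return list with `seqs` (an aligned [seq_set()] labeled
#'   `sp1 ... spk`), and `truth`: `per_seq` (id, species, haplotype id,
#'   mutated positions), `consensus_pairs` (realized difference counts
#'   and K2P per species pair), and `consensuses` (named character).
#' @export
simulate_species_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  k <- cfg$n_species
  sp <- sprintf("sp%d", seq_len(k))
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, L, replace = TRUE, prob = cfg$base_composition)

  # solve per-species substitution counts m_i from pairwise targets
  # (least squares on m_i + m_j = n_ij, the star decomposition)
  m_counts <- rep(0, k)
  if (any(cfg$target_divergence > 0)) {
    pairs <- utils::combn(k, 2L)
    n_ij <- apply(pairs, 2L, function(p) {
      count_for_divergence(cfg$target_divergence[p[1], p[2]], L, cfg$kappa)
    })
    A <- matrix(0, ncol(pairs), k)
    for (c2 in seq_len(ncol(pairs))) A[c2, pairs[, c2]] <- 1
    m_counts <- as.vector(stats::lm.fit(A, n_ij)$coefficients)
    m_counts[is.na(m_counts)] <- 0
    if (any(m_counts < -0.5)) {
      stop("contradictory divergence grid: no non-negative star ",
           "decomposition", call. = FALSE)
    }
    m_counts <- pmax(0L, as.integer(round(m_counts)))
  }
  if (sum(m_counts) > L) {
    stop("divergence targets require more substitutions than sites",
         call. = FALSE)
  }

  all_pos <- sample.int(L, sum(m_counts))
  consensuses <- list()
  mut_pos <- split(all_pos, rep(seq_len(k), m_counts))
  for (i in seq_len(k)) {
    cons <- ancestor
    for (p in mut_pos[[as.character(i)]] %||% integer()) {
      cons[p] <- mutate_base(cons[p], cfg$kappa)
    }
    consensuses[[sp[i]]] <- cons
  }

  # individual haplotypes
  ids <- character(); species <- character(); seqs <- character()
  per_seq <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(cfg$n_per_species[i])) {
      hap <- consensuses[[sp[i]]]
      n_mut <- if (cfg$intra_max_diffs > 0)
        sample.int(cfg$intra_max_diffs + 1L, 1L) - 1L else 0L
      pos <- if (n_mut > 0) sample.int(L, n_mut) else integer()
      for (p in pos) hap[p] <- mutate_base(hap[p], cfg$kappa)
      id <- sprintf("%s_%02d", sp[i], j)
      ids <- c(ids, id); species <- c(species, sp[i])
      seqs <- c(seqs, paste(hap, collapse = ""))
      per_seq[[id]] <- data.frame(
        id = id, species = sp[i], n_mut = n_mut,
        positions = paste(sort(pos), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out_seqs <- seq_set(seqs, ids = ids, species = species)

  # haplotype ids within species (1 = first distinct sequence seen)
  per_seq <- do.call(rbind, per_seq)
  rownames(per_seq) <- NULL
  per_seq$haplotype <- stats::ave(out_seqs$seqs, per_seq$species,
                                  FUN = function(s) match(s, unique(s)))
  per_seq$haplotype <- as.integer(per_seq$haplotype)

  cons_str <- vapply(consensuses, paste, "", collapse = "")
  pairs <- utils::combn(k, 2L)
  consensus_pairs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    pc <- pairwise_counts(cons_str[i], cons_str[j], ids = sp[c(i, j)])
    data.frame(species1 = sp[i], species2 = sp[j],
               target_k2p = cfg$target_divergence[i, j],
               realized_n_diff = pc$n_diff, realized_k2p = pc$d_k2p,
               stringsAsFactors = FALSE)
  }))
  bad <- consensus_pairs$target_k2p > 0 &
    abs(consensus_pairs$realized_k2p - consensus_pairs$target_k2p) >
      0.1 * consensus_pairs$target_k2p
  if (any(bad)) {
    stop("realized consensus divergence misses its target by more than ",
         "10% for pair(s): ",
         paste(consensus_pairs$species1[bad], consensus_pairs$species2[bad],
               sep = "-", collapse = ", "), call. = FALSE)
  }
  list(seqs = out_seqs,
       truth = list(per_seq = per_seq, consensus_pairs = consensus_pairs,
                    consensuses = cons_str))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fragment templates the way old-specimen DNA fragments
#'
#' Cuts each template into contiguous, non-overlapping fragments whose
#' lengths are drawn around the requested mean (Poisson, floored at
#' `min_len`; a short terminal remnant is merged into the preceding
#' fragment). Fragments carry their true 1-based offset, so reassembly by
#' offset reproduces the template exactly. A mean at or above the
#' template length returns the template as a single fragment.
#'
#' @param seqs a [seq_set()] of templates.
#' @param mean_fragment_len requested mean fragment length.
#' @param min_len minimum fragment length (>= 1).
#' @param seed integer seed.
#' @return data frame with `fragment_id`, `template_id`, `species`,
#'   `offset`, `length`, `seq`.
#' @export
degrade_fragments <- function(seqs, mean_fragment_len, min_len = 1L, seed) {
  stopifnot(inherits(seqs, "seq_set"))
  if (!(mean_fragment_len >= min_len && min_len >= 1L)) {
    stop("need mean_fragment_len >= min_len >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_along(seqs$ids)) {
    s <- seqs$seqs[[i]]
    L <- nchar(s)
    cuts <- integer()
    if (mean_fragment_len < L) {
      pos <- 1L
      while (pos < L) {
        len <- max(min_len, stats::rpois(1L, mean_fragment_len))
        nxt <- pos + len
        if (nxt > L || L - nxt + 1L < min_len) break
        cuts <- c(cuts, nxt)
        pos <- nxt
      }
    }
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, L)
    for (f in seq_along(starts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = sprintf("%s_f%d", seqs$ids[i], f),
        template_id = seqs$ids[i],
        species = seqs$species[i],
        offset = starts[f],
        length = ends[f] - starts[f] + 1L,
        seq = substr(s, starts[f], ends[f]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate two-group genitalic measurements
#'
#' Independent Gaussian noise around each group's mean measurement
#' vector, truncated at a small positive floor so ratios stay defined.
#'
#' @param n_per_group integer count per group (recycled to 2).
#' @param group_means 2 x 6 matrix (or list of two length-6 vectors) of
#'   mean `a, b, c, d, l, h` per group; all strictly positive.
#' @param dispersion per-measurement standard deviation (scalar or
#'   length 6); non-negative.
#' @param seed integer seed.
#' @param floor positive truncation floor (default 1e-3).
#' @return data frame with `id`, `species` (`g1`/`g2`) and the six
#'   measurement columns, ready for [morpho_score()].
#' @export
simulate_morphometrics <- function(n_per_group, group_means, dispersion,
                                   seed, floor = 1e-3) {
  if (is.list(group_means)) group_means <- do.call(rbind, group_means)
  group_means <- as.matrix(group_means)
  stopifnot(nrow(group_means) == 2L, ncol(group_means) == 6L,
            all(group_means > 0), all(dispersion >= 0), floor > 0)
  n_per_group <- rep_len(as.integer(n_per_group), 2L)
  stopifnot(all(n_per_group >= 1L))
  dispersion <- rep_len(dispersion, 6L)
  set.seed(as.integer(seed))
  cols <- c("a", "b", "c", "d", "l", "h")
  out <- do.call(rbind, lapply(1:2, function(g) {
    vals <- sapply(1:6, function(j) {
      pmax(floor, stats::rnorm(n_per_group[g], group_means[g, j],
                               dispersion[j]))
    })
    vals <- matrix(vals, nrow = n_per_group[g],
                   dimnames = list(NULL, cols))
    data.frame(id = sprintf("g%d_%02d", g, seq_len(n_per_group[g])),
               species = sprintf("g%d", g), vals,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
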