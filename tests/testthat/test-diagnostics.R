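test_that("the published diagnostic positions are rediscovered from the reference barcodes", {
  bc <- herm_barcodes()
  two <- seq_set(bc$seqs[c("KJ025569", "KJ025561")],
                 species = c("hermybius", "sosybius"))
  sites <- find_diagnostic_sites(two)
  ref <- hermybius_diagnostic_positions()
  expect_equal(nrow(ref), 11L)
  # every printed entry appears with the stated states
  for (k in seq_len(nrow(ref))) {
    row <- sites[sites$position == ref$position[k], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$hermybius, ref$hermybius[k])
    expect_equal(row$sosybius, ref$sosybius[k])
  }
})

test_that("identical groups yield no diagnostic sites", {
  s <- seq_set(c(a = "ACGTACGT", b = "ACGTACGT"), species = c("X", "Y"))
  expect_equal(nrow(find_diagnostic_sites(s)), 0L)
})

test_that("site discovery equals a brute-force per-column scan", {
  set.seed(61)
  for (rep in 1:5) {
    L <- 50L
    n_per <- c(3, 2, 4)
    groups <- rep(c("g1", "g2", "g3"), n_per)
    cons <- lapply(1:3, function(i) strsplit(random_seq(L), "")[[1]])
    rows <- lapply(seq_along(groups), function(i) {
      v <- cons[[match(groups[i], c("g1", "g2", "g3"))]]
      idx <- sample(L, sample(0:3, 1))
      v[idx] <- sample(c("A", "C", "G", "T", "N"), length(idx), replace = TRUE)
      v
    })
    s <- seq_set(vapply(rows, paste, "", collapse = ""),
                 ids = sprintf("r%d", seq_along(rows)), species = groups)
    sites <- find_diagnostic_sites(s)

    # oracle: literal per-column check
    expected <- integer()
    for (col in seq_len(L)) {
      st <- vapply(c("g1", "g2", "g3"), function(g) {
        obs <- unique(vapply(rows[groups == g], `[`, "", col))
        if (length(obs) == 1L && obs %in% c("A", "C", "G", "T")) obs
        else NA_character_
      }, "")
      if (!anyNA(st) && length(unique(st)) > 1L) expected <- c(expected, col)
    }
    expect_equal(sites$position, expected)
  }
})

test_that("a single ambiguous residue disqualifies a column", {
  s <- seq_set(c(a1 = "AANA", a2 = "AAGA", b1 = "TAGA", b2 = "TAGA"),
               species = c("A", "A", "B", "B"))
  sites <- find_diagnostic_sites(s)
  expect_equal(sites$position, 1L)  # column 3 lost to the N in a1
})

test_that("window ranking maximizes the weakest pair first and matches enumeration", {
  set.seed(62)
  # synthetic site list with a dense region around positions 40..60
  pos <- c(5, 12, 41, 44, 52, 58, 90)
  st <- data.frame(
    position = pos,
    g1 = c("A", "A", "A", "A", "A", "A", "A"),
    g2 = c("C", "A", "C", "C", "C", "A", "C"),
    g3 = c("A", "T", "T", "C", "T", "T", "A"),
    stringsAsFactors = FALSE)
  attr(st, "alignment_length") <- 100L
  attr(st, "groups") <- c("g1", "g2", "g3")
  class(st) <- c("diagnostic_sites", "data.frame")

  top <- select_tag_windows(st, window_len = 20, top_k = 1)

  # oracle: enumerate every window, recompute both scores directly
  best <- NULL
  for (s0 in 1:81) {
    inw <- pos >= s0 & pos <= s0 + 19
    if (!any(inw)) next
    pm <- min(
      sum(st$g1[inw] != st$g2[inw]),
      sum(st$g1[inw] != st$g3[inw]),
      sum(st$g2[inw] != st$g3[inw]))
    sc <- c(pm, sum(inw), -s0)
    if (is.null(best) || sc[1] > best[1] ||
        (sc[1] == best[1] && sc[2] > best[2]) ||
        (sc[1] == best[1] && sc[2] == best[2] && sc[3] > best[3])) best <- sc
  }
  expect_equal(top$pair_min, best[1])
  expect_equal(top$site_count, best[2])
  expect_equal(top$start, -best[3])
  expect_equal(top$length, 20L)
  expect_gte(top$site_count, top$pair_min)
})

test_that("window ranking is stable under permutation of the site list and handles empties", {
  st <- find_diagnostic_sites(herm_barcodes())
  perm <- st[sample(nrow(st)), ]
  perm <- perm[order(perm$position), ]  # positions must stay ascending
  attr(perm, "alignment_length") <- attr(st, "alignment_length")
  attr(perm, "groups") <- attr(st, "groups")
  class(perm) <- class(st)
  expect_equal(select_tag_windows(st, 75), select_tag_windows(perm, 75))

  empty <- st[0, ]
  attr(empty, "alignment_length") <- 658L
  expect_equal(nrow(select_tag_windows(empty, 75)), 0L)
  expect_error(select_tag_windows(st, 0), "window_len")
})

test_that("primer matching uses IUPAC set intersection on the correct strand", {
  bc <- herm_barcodes()
  neo <- bc$seqs[["KJ025561"]]
  pr <- idtag_primers()
  hit <- match_primer(neo, pr$sequence[pr$name == "styr-ID1F"], "forward")
  expect_equal(nrow(hit), 1L)  # W matches the template A at that offset
  expect_equal(nrow(match_primer("CCCC", "AAAA")), 0L)
  expect_equal(nrow(match_primer("AAGAA", "AARAA")), 1L)  # R vs G intersects
  # a gap in the template never matches
  expect_equal(nrow(match_primer("AA-AA", "AANAA")), 0L)
  # reverse orientation: matches via reverse complement on the plus strand
  expect_equal(match_primer("TTTTT", "AAAAA", "reverse")$start[1], 1L)
})

test_that("virtual PCR reproduces the published tag lengths on the neotype barcode", {
  bc <- herm_barcodes()
  neo <- bc$seqs[["KJ025561"]]
  pr <- idtag_primers()
  p <- function(n) pr$sequence[pr$name == n]

  amp1 <- virtual_pcr(neo, p("styr-ID1F"), p("styr-ID1R"), "KJ025561")
  expect_equal(amp1$insert_len, 75L)
  expect_equal(amp1$product_len, 118L)

  amp2 <- virtual_pcr(neo, p("styr-ID2F"), p("styr-ID2R"), "KJ025561")
  expect_equal(amp2$insert_len, 56L)
  expect_equal(amp2$product_len, 103L)

  # product = insert + both primers, for each pair
  expect_equal(amp1$product_len - amp1$insert_len,
               nchar(p("styr-ID1F")) + nchar(p("styr-ID1R")))
  expect_equal(amp2$product_len - amp2$insert_len,
               nchar(p("styr-ID2F")) + nchar(p("styr-ID2R")))

  # swapped primers: the "forward" primer no longer binds the plus strand
  expect_error(virtual_pcr(neo, p("styr-ID1R"), p("styr-ID1F")), "binds 0")
  # multiple binding sites abort
  tandem <- paste0(neo, neo)
  expect_error(virtual_pcr(tandem, p("styr-ID2F"), p("styr-ID2R")),
               "binds 2")
})

test_that("fragment species calls recover the source species from tag inserts", {
  bc <- herm_barcodes()
  labels <- c(KJ025561 = "sosybius", KJ025595 = "intricata",
              KJ025569 = "hermybius")
  sites <- find_diagnostic_sites(bc, labels)
  pr <- idtag_primers()
  p <- function(n) pr$sequence[pr$name == n]

  amp_neo <- virtual_pcr(bc$seqs[["KJ025561"]], p("styr-ID2F"), p("styr-ID2R"))
  off <- amp_neo$fwd_interval[2] + 1L
  expect_equal(call_species(amp_neo$insert, sites, off)$verdict, "sosybius")

  amp_int <- virtual_pcr(bc$seqs[["KJ025595"]], p("styr-ID2F"), p("styr-ID2R"))
  expect_equal(call_species(amp_int$insert, sites,
                            amp_int$fwd_interval[2] + 1L)$verdict, "intricata")

  # chimera spliced from the two inserts triggers the contamination rule
  # (scored against the two-species profile it purports to come from)
  two <- seq_set(bc$seqs[c("KJ025561", "KJ025595")],
                 species = c("sosybius", "intricata"))
  sites2 <- find_diagnostic_sites(two)
  half <- nchar(amp_neo$insert) %/% 2
  chimera <- paste0(substr(amp_neo$insert, 1, half),
                    substr(amp_int$insert, half + 1, nchar(amp_int$insert)))
  expect_equal(call_species(chimera, sites2, off)$verdict, "contaminated")

  # ambiguity codes at diagnostic sites also count as contamination
  v <- strsplit(amp_neo$insert, "")[[1]]
  in_window <- sites$position[sites$position >= off &
                              sites$position < off + length(v)]
  v[in_window - off + 1] <- "N"
  expect_equal(call_species(paste(v, collapse = ""), sites, off)$verdict,
               "contaminated")

  # a fragment covering no diagnostic site cannot be called
  expect_equal(call_species("ACGT", sites, 2)$verdict, "no-match")
  expect_error(call_species(amp_neo$insert, sites, 0), "offset")
  expect_error(call_species(amp_neo$insert, sites, 650), "map onto")
})

test_that("every unmodified training member is called back to its own group", {
  cfg <- simulation_config(n_per_species = 5, seed = 31)
  sim <- simulate_species_set(cfg)
  sites <- find_diagnostic_sites(sim$seqs)
  for (i in seq_along(sim$seqs$ids)) {
    call <- call_species(sim$seqs$seqs[[i]], sites, 1L)
    expect_equal(call$verdict, sim$seqs$species[i])
  }
})

test_that("tag-window difference counts reproduce the published figures", {
  bc <- herm_barcodes()
  pr <- idtag_primers()
  p <- function(n) pr$sequence[pr$name == n]
  amp <- virtual_pcr(bc$seqs[["KJ025561"]], p("styr-ID2F"), p("styr-ID2R"))
  window <- c(amp$fwd_interval[2] + 1L, amp$rev_interval[1] - 1L)
  tc <- tag_difference_counts(bc, window)

  sos_int <- tc$n_diff[(tc$id1 == "KJ025561" & tc$id2 == "KJ025595") |
                       (tc$id1 == "KJ025595" & tc$id2 == "KJ025561")]
  expect_equal(sos_int, 4L)      # sosybius vs intricata inside tag 2
  expect_gte(min(tc$n_diff), 2L) # every species pair separated by >= 2

  self <- tag_difference_counts(
    seq_set(c(x = bc$seqs[["KJ025561"]], y = bc$seqs[["KJ025561"]])), window)
  expect_equal(self$n_diff, 0L)
  expect_error(tag_difference_counts(bc, c(600, 700)), "bounds")
})
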