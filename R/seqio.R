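# Sequence and specimen-metadata input/output.

#' Construct a set of barcode sequence records
#'
#' A `seq_set` holds named, uppercased IUPAC nucleotide sequences together
#' with optional species labels. Sets whose sequences all share one length
#' are flagged as aligned; ragged sets are accepted (templates for virtual
#' PCR need not be aligned) but rejected by alignment-requiring operations.
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of unique record identifiers
#'   (default `names(seqs)`).
#' @param species optional character vector of group labels, one per record
#'   (`NA` allowed).
#' @return an object of class `seq_set` with fields `ids`, `species`,
#'   `seqs` (named by id), `aligned`, and `alignment_length` (`NA` for
#'   ragged sets).
#' @examples
#' s <- seq_set(c(x = "ACGT", y = "ACAT"))
#' s$alignment_length
#' @export
seq_set <- function(seqs, ids = names(seqs), species = NULL) {
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  if (is.null(ids)) stop("sequence records need identifiers", call. = FALSE)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("[ \t]", "", as.character(seqs)))
  for (i in seq_along(seqs)) validate_residues(seqs[i], ids[i])
  if (is.null(species)) species <- rep(NA_character_, length(seqs))
  stopifnot(length(species) == length(seqs))
  names(seqs) <- ids
  len <- nchar(seqs)
  aligned <- length(unique(len)) == 1L
  structure(
    list(ids = ids, species = as.character(species), seqs = seqs,
         aligned = aligned,
         alignment_length = if (aligned) unname(len[1]) else NA_integer_),
    class = "seq_set"
  )
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set:", length(x$ids), "record(s); ",
      if (x$aligned) paste0("aligned, ", x$alignment_length, " columns")
      else "unaligned (ragged lengths)", "\n")
  n <- min(6L, length(x$ids))
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s  [%d bp]%s\n", x$ids[i],
                substr(x$seqs[i], 1, 40), nchar(x$seqs[i]),
                if (!is.na(x$species[i])) paste0("  ", x$species[i]) else ""))
  }
  if (length(x$ids) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$ids)

#' Number of residues in each record of a sequence set
#'
#' @param x a `seq_set` or a single sequence string.
#' @return named integer vector of sequence lengths.
#' @export
sequence_length <- function(x) {
  if (inherits(x, "seq_set")) return(nchar(x$seqs))
  validate_residues(toupper(x))
  nchar(x)
}

#' Require an aligned sequence set
#' @keywords internal
assert_aligned <- function(x, what = "this operation") {
  if (!inherits(x, "seq_set")) stop("expected a seq_set", call. = FALSE)
  if (!x$aligned) {
    stop(what, " requires an aligned set (all sequences the same length); ",
         "this set is ragged", call. = FALSE)
  }
  invisible(x)
}

#' Read aligned or unaligned sequences from a FASTA file
#'
#' Residues are uppercased and validated against the IUPAC alphabet;
#' validation errors name the record and column. A species label may be
#' embedded in the header after a `|` separator (`>id|species`), which
#' takes precedence over labels supplied later from a metadata table.
#'
#' @param path path to a FASTA file.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- vapply(recs, function(r) attr(r, "Annot"), "")
  headers <- sub("^>", "", headers)
  headers <- sub("\\s+$", "", headers)
  ids <- sub("\\|.*$", "", headers)
  species <- ifelse(grepl("|", headers, fixed = TRUE),
                    sub("^[^|]*\\|", "", headers), NA_character_)
  seq_set(vapply(recs, as.character, ""), ids = ids, species = species)
}

#' Write a sequence set to FASTA
#'
#' Lines are wrapped at a fixed column width; species labels, when present,
#' are written after a `|` in the header so that [read_fasta()] round-trips
#' them.
#'
#' @param x a [seq_set()].
#' @param path output file path.
#' @param wrap line width (default 60 columns).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, wrap = 60L) {
  stopifnot(inherits(x, "seq_set"), wrap >= 1L)
  headers <- ifelse(is.na(x$species), x$ids, paste0(x$ids, "|", x$species))
  seqinr::write.fasta(as.list(unname(x$seqs)), names = headers,
                      file.out = path, nbchar = wrap, as.string = TRUE)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated with a header; columns `species` and `voucher` are
#' required, `accession`, `locality`, `date` and `collector` are optional
#' and filled with `NA` when absent. Dates and other annotations are kept
#' as free text.
#'
#' @param path path to a TSV file.
#' @return a data frame with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("species", "voucher")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("accession", "locality", "date", "collector")) {
    if (!col %in% names(meta)) meta[[col]] <- rep(NA_character_, nrow(meta))
  }
  if (nrow(meta) == 0L) {
    warning("metadata file ", path, " has a header but no rows")
    return(meta)
  }
  if (any(is.na(meta$voucher) | !nzchar(meta$voucher))) {
    stop("metadata row(s) without a voucher: ",
         paste(which(is.na(meta$voucher) | !nzchar(meta$voucher)),
               collapse = ", "), call. = FALSE)
  }
  has_acc <- !is.na(meta$accession) & nzchar(meta$accession)
  bad_acc <- has_acc & !grepl("^[A-Za-z]+[0-9]+$", meta$accession)
  if (any(bad_acc)) {
    stop("malformed accession(s): ",
         paste(meta$accession[bad_acc], collapse = ", "), call. = FALSE)
  }
  meta
}

#' Summarize a specimen collection by species
#'
#' Reports per-species counts, each species' share of the total as a
#' percentage, and for every species pair the larger-to-smaller count
#' ratio. Useful for collection-survey arithmetic such as relative
#' abundance of a rarely collected species.
#'
#' @param x a metadata data frame with a `species` column, or a named
#'   integer vector of per-species counts.
#' @return a list with `counts` (named integer), `share_pct` (named
#'   numeric, percent of total) and `pair_ratios` (data frame with columns
#'   `species1`, `species2`, `ratio` where `ratio` = max/min count).
#' @examples
#' summarize_collection(c(sosybius = 169, intricata = 8))
#' @export
summarize_collection <- function(x) {
  if (is.data.frame(x)) {
    if (!"species" %in% names(x)) stop("no species column", call. = FALSE)
    counts <- table(x$species)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    counts <- stats::setNames(as.integer(x), names(x))
  }
  if (length(counts) == 0L || sum(counts) == 0L) {
    stop("at least one specimen required", call. = FALSE)
  }
  share <- 100 * counts / sum(counts)
  sp <- names(counts)
  pairs <- if (length(sp) >= 2L) utils::combn(sp, 2L) else
    matrix(character(), nrow = 2L)
  ratios <- data.frame(
    species1 = pairs[1, ], species2 = pairs[2, ],
    ratio = if (ncol(pairs)) apply(pairs, 2L, function(p) {
      a <- counts[[p[1]]]; b <- counts[[p[2]]]
      max(a, b) / min(a, b)
    }) else numeric(),
    stringsAsFactors = FALSE
  )
  list(counts = counts, share_pct = share, pair_ratios = ratios)
}

#' Inclusive size of a GenBank-style accession range
#'
#' @param first,last accession strings with the same alphabetic prefix,
#'   e.g. `"KJ025523"` and `"KJ025607"`.
#' @return the inclusive count of accessions in the range.
#' @examples
#' accession_range_count("KJ025523", "KJ025607")
#' @export
accession_range_count <- function(first, last) {
  parse_acc <- function(a) {
    m <- regmatches(a, regexec("^([A-Za-z]+)([0-9]+)$", a))[[1]]
    if (length(m) != 3L) stop("malformed accession: ", a, call. = FALSE)
    list(prefix = m[2], num = as.numeric(m[3]))
  }
  f <- parse_acc(first); l <- parse_acc(last)
  if (f$prefix != l$prefix) {
    stop("accession prefixes differ: ", f$prefix, " vs ", l$prefix,
         call. = FALSE)
  }
  if (l$num < f$num) stop("last accession precedes first", call. = FALSE)
  as.integer(l$num - f$num + 1)
}
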