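# Bundled reference data: three published full-length COI barcodes and the
# four ID-tag primers designed for degraded museum specimens.

#' Reference COI barcodes for the three USA Hermeuptychia species
#'
#' The three full-length (658 bp) barcodes published for the group:
#' the *Hermeuptychia sosybius* neotype (GenBank KJ025561), the
#' *H. intricata* holotype (KJ025595) and the most common *H. hermybius*
#' haplotype (KJ025569, voucher NVG-1603). Species labels ride along in
#' the set, so the records can feed diagnostics directly.
#'
#' @return an aligned [seq_set()] of three 658-column records.
#' @examples
#' herm_barcodes()
#' @export
herm_barcodes <- function() {
  read_fasta(system.file("extdata", "hermeuptychia_barcodes.fasta",
                         package = "barcodegap", mustWork = TRUE))
}

#' ID-tag mini-barcode primers for Hermeuptychia
#'
#' The two published degenerate primer pairs (styr-ID1F/R and
#' styr-ID2F/R) that amplify ~100 bp "ID tag" fragments from degraded
#' old-specimen DNA. Coordinates on the 658 bp barcode are recovered by
#' [match_primer()] / [virtual_pcr()].
#'
#' @return a data frame with columns `name`, `sequence`, `orientation`.
#' @examples
#' idtag_primers()
#' @export
idtag_primers <- function() {
  utils::read.delim(system.file("extdata", "idtag_primers.tsv",
                                package = "barcodegap", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published diagnostic positions separating H. hermybius from H. sosybius
#'
#' The eleven barcode positions reported as invariant within each
#' species' sample but different between the two species, with the
#' nucleotide carried by each species (1-based coordinates on the 658 bp
#' reference barcode). [find_diagnostic_sites()] on the bundled reference
#' barcodes rediscovers every entry.
#'
#' @return a data frame with columns `position`, `hermybius`, `sosybius`.
#' @examples
#' hermybius_diagnostic_positions()
#' @export
hermybius_diagnostic_positions <- function() {
  utils::read.delim(system.file("extdata", "hermybius_diagnostic_positions.tsv",
                                package = "barcodegap", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
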