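## Genetic-code access. The package default is NCBI translation table 4
## (mold / protozoan / coelenterate mitochondrial code): TGA encodes Trp,
## stops are TAA and TAG only. Scleractinian mitogenomes additionally use
## ATA and GTG as initiation codons, so the canonical start set is
## {ATG, ATA, GTG}.

CANONICAL_STARTS <- c("ATG", "ATA", "GTG")

#' Fetch a genetic code table
#'
#' Thin wrapper around [Biostrings::getGeneticCode()] returning the codon to
#' amino-acid map as a named character vector (stops are `"*"`), with the
#' table id and the canonical mitochondrial start-codon set attached.
#'
#' @param table_id Integer or character NCBI genetic-code identifier.
#'   Defaults to 4, the coelenterate mitochondrial code, under which TGA
#'   translates to tryptophan.
#' @return Named character vector of length 64, class `codon_table`, with
#'   attributes `table_id` and `start_codons`.
#' @export
#' @examples
#' ct <- codon_table()
#' ct[["TGA"]]   # "W" under the coelenterate mitochondrial code
codon_table <- function(table_id = 4) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  out <- setNames(as.character(code), names(code))
  attr(out, "table_id") <- as.integer(table_id)
  attr(out, "start_codons") <- CANONICAL_STARTS
  class(out) <- "codon_table"
  out
}

stop_codons <- function(table) names(table)[unclass(table) == "*"]

is_stop <- function(codon, table) unclass(table)[codon] == "*"

#' Translate a coding sequence
#'
#' Translates an in-frame coding sequence under the given genetic code.
#' A terminal stop codon is excluded from the protein, so a CDS of
#' `3(k + 1)` bases ending in a stop yields `k` amino acids. Internal stop
#' codons are an error (they indicate a frame or annotation problem).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param table A [codon_table()].
#' @param require_stop If `TRUE`, error when the terminal codon is not a
#'   stop. Default `FALSE`: the 5' exon of an intron-split gene legitimately
#'   ends without one.
#' @return Single amino-acid string (one-letter code), stop excluded.
#' @export
#' @examples
#' translate("ATGTGATAA")  # "MW": TGA is Trp, terminal TAA dropped
translate <- function(cds, table = codon_table(), require_stop = FALSE) {
  cod <- codons_of(cds)
  aa <- unclass(table)[cod]
  if (anyNA(aa))
    stop("unrecognized codon(s): ", paste(unique(cod[is.na(aa)]), collapse = ", "))
  n <- length(aa)
  terminal_stop <- aa[n] == "*"
  if (require_stop && !terminal_stop)
    stop("terminal codon ", cod[n], " is not a stop codon")
  internal <- which(aa[-n] == "*")
  if (length(internal) > 0)
    stop("internal stop codon ", cod[internal[1]], " at codon index ", internal[1])
  if (terminal_stop) aa <- aa[-n]
  paste(aa, collapse = "")
}

#' Identify start and stop codons of a coding sequence
#'
#' Returns the literal first and last codons together with flags: a start is
#' `canonical` when in the mitochondrial set ATG/ATA/GTG (flagged
#' `alternative` for ATA/GTG), and the stop is `NA` when the terminal codon
#' is not a stop under the table (as for the 5' exon of an intron-split
#' gene, which ends mid-frame). Flags, not failures: no error is raised.
#'
#' @inheritParams translate
#' @return List with `start`, `stop` (codon or `NA`), `start_canonical`,
#'   `start_alternative` logicals.
#' @export
detect_start_stop <- function(cds, table = codon_table()) {
  if (nchar(cds) < 6 || nchar(cds) %% 3L != 0L)
    stop("need an in-frame CDS of at least two codons")
  cod <- codons_of(cds)
  start <- cod[1]
  last <- cod[length(cod)]
  list(
    start = start,
    stop = if (is_stop(last, table)) last else NA_character_,
    start_canonical = start %in% attr(table, "start_codons"),
    start_alternative = start %in% setdiff(attr(table, "start_codons"), "ATG")
  )
}
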