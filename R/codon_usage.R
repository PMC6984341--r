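## Codon tallies and relative synonymous codon usage (RSCU).
##
## RSCU(c) = count(c) * k / sum(counts over the k synonymous codons of
## c's amino acid family). Under no usage bias every codon of a family has
## RSCU 1; a family's RSCU values always average to 1 and sum to the family
## size. Stop codons are excluded. Six-fold families (Leu, Ser, Arg under
## the mitochondrial code) are treated as single families of size 6.

#' Count codons of one coding sequence
#'
#' @param cds In-frame nucleotide string.
#' @param drop_terminal_stop Exclude the terminal codon when it is a stop
#'   (default `TRUE`), so tallies cover translated codons only.
#' @param table A [codon_table()].
#' @return A `codon_counts`: list with `counts` (named integer vector over
#'   the 64 codons) and `n_codons`.
#' @export
count_codons <- function(cds, table = codon_table(),
                         drop_terminal_stop = TRUE) {
  cod <- codons_of(cds)
  if (drop_terminal_stop && length(cod) > 0 &&
      is_stop(cod[length(cod)], table))
    cod <- cod[-length(cod)]
  all64 <- names(unclass(table))
  counts <- setNames(integer(64), all64)
  tab <- table(factor(cod, levels = all64))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, n_codons = length(cod)),
            class = "codon_counts")
}

#' Pool codon counts over protein-coding genes
#'
#' Tallies codons over a set of coding sequences with terminal stop codons
#' excluded, as when codon usage is reported over all 13 mitochondrial
#' PCGs of a genome.
#'
#' @param cds_list List/vector of in-frame coding sequences.
#' @inheritParams count_codons
#' @return A `codon_counts`.
#' @export
pooled_codon_counts <- function(cds_list, table = codon_table()) {
  cds_list <- as.list(cds_list)
  if (length(cds_list) == 0) stop("cds_list must be non-empty")
  per_gene <- lapply(cds_list, count_codons, table = table)
  counts <- Reduce(`+`, lapply(per_gene, `[[`, "counts"))
  structure(list(counts = counts, n_codons = sum(counts)),
            class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' @param counts A `codon_counts` from [count_codons()] or
#'   [pooled_codon_counts()].
#' @param table A [codon_table()].
#' @return A data.frame with columns `codon`, `aa`, `count`, `rscu`,
#'   ordered by amino acid then codon. Codons of families with zero total
#'   usage get `NA` (unused, as opposed to biased against); stop codons are
#'   omitted.
#' @export
#' @examples
#' cc <- count_codons("TTTTTTTTTTTC", drop_terminal_stop = FALSE)
#' rscu(cc)  # Phe family {TTT:3, TTC:1} -> RSCU 1.5 and 0.5
rscu <- function(counts, table = codon_table()) {
  if (counts$n_codons <= 0) stop("no codons to analyze")
  aa_of <- unclass(table)
  keep <- aa_of != "*"
  codons <- names(aa_of)[keep]
  aa <- aa_of[keep]
  cnt <- counts$counts[codons]
  fam_total <- tapply(cnt, aa, sum)[aa]
  fam_size <- table(aa)[aa]
  vals <- ifelse(fam_total > 0, cnt * as.numeric(fam_size) / fam_total,
                 NA_real_)
  out <- data.frame(codon = codons, aa = unname(aa), count = unname(cnt),
                    rscu = unname(vals), stringsAsFactors = FALSE)
  out[order(out$aa, out$codon), , drop = FALSE]
}

#' Extract the 13 protein-coding gene sequences of a genome
#'
#' Returns the coding sequence of each PCG with the intron-split ND5
#' joined from its 5' and 3' exon segments (the stored feature table keeps
#' the exons as separate features; translation needs the joined CDS).
#'
#' @param genome A [mito_genome()].
#' @param table A [feature_table()].
#' @param join_nd5 Join ND5-5prime and ND5-3prime into a single `ND5`
#'   entry (default `TRUE`).
#' @return Named character vector of coding sequences.
#' @export
pcg_sequences <- function(genome, table, join_nd5 = TRUE) {
  pcgs <- Filter(function(f) f$ftype == "PCG", table$features)
  out <- setNames(
    vapply(pcgs, function(f) extract_feature(genome, f), ""),
    vapply(pcgs, `[[`, "", "name"))
  if (join_nd5 && all(c("ND5-5prime", "ND5-3prime") %in% names(out))) {
    joined <- paste0(out[["ND5-5prime"]], out[["ND5-3prime"]])
    out <- out[!names(out) %in% c("ND5-5prime", "ND5-3prime")]
    out <- c(out, ND5 = joined)
  }
  out
}
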