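## Base composition and strand-asymmetry (skew) statistics.
##
## AT-skew = (A - T) / (A + T); GC-skew = (G - C) / (G + C), computed on
## counts of unambiguous bases. N bases are excluded from both numerator
## and denominator. Scleractinian mitogenomes are T-rich with A second,
## giving negative AT-skew and positive GC-skew on the coding strand.

#' Base composition and skews of a sequence
#'
#' @param seq Nucleotide string over A, C, G, T, N.
#' @return A `composition_profile`: list with `counts` (named A/C/G/T),
#'   `n_effective` (non-N bases), `pct` (percentages of non-N bases),
#'   `at_skew`, `gc_skew` (`NA` when the respective denominator is zero).
#' @export
#' @examples
#' base_composition("AATT")$at_skew  # 0
base_composition <- function(seq) {
  if (!is_nucleotide_string(seq))
    stop("sequence must be non-empty and contain only A, C, G, T, N")
  chars <- seq_chars(seq)
  counts <- vapply(BASES, function(b) sum(chars == b), 0L)
  n_eff <- sum(counts)
  if (n_eff == 0)
    stop("undefined composition profile: sequence contains no unambiguous bases")
  structure(
    list(counts = counts, n_effective = n_eff,
         pct = 100 * counts / n_eff,
         at_skew = skew(counts[["A"]], counts[["T"]]),
         gc_skew = skew(counts[["G"]], counts[["C"]])),
    class = "composition_profile"
  )
}

skew <- function(x, y) {
  if (x + y == 0) return(NA_real_)
  (x - y) / (x + y)
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile> n=%d  A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%  AT-skew %s  GC-skew %s\n",
    x$n_effective, x$pct[["A"]], x$pct[["C"]], x$pct[["G"]], x$pct[["T"]],
    format_skew(x$at_skew), format_skew(x$gc_skew)))
  invisible(x)
}

format_skew <- function(s) {
  if (is.na(s)) "NA" else sprintf("%.3f", round_half_up(s, 3))
}

#' Skews from published composition percentages
#'
#' Computes AT- and GC-skew directly from four base percentages, e.g. to
#' validate a published composition table without the underlying sequence.
#' Because both skews are ratios, any common scaling of the inputs cancels;
#' the result equals the count-based skew whenever the percentages are
#' exact.
#'
#' @param a_pct,t_pct,g_pct,c_pct Non-negative percentages.
#' @return List with `at_skew` and `gc_skew` (`NA` on a zero denominator).
#' @export
#' @examples
#' skew_from_percentages(25.3, 41.1, 20.2, 13.3)  # -0.238, 0.206 at 3 dp
skew_from_percentages <- function(a_pct, t_pct, g_pct, c_pct) {
  vals <- c(a_pct, t_pct, g_pct, c_pct)
  if (any(vals < 0)) stop("percentages must be non-negative")
  list(at_skew = skew(a_pct, t_pct), gc_skew = skew(g_pct, c_pct))
}

REGION_CLASSES <- c("whole", "PCG", "tRNA", "rRNA", "intergenic")

#' Composition of a genome region class
#'
#' Pools all features of a class (deduplicating genomic positions shared by
#' overlapping features, so overlapped bases count once per class) and
#' profiles the pooled bases. `"intergenic"` is the whole genome minus
#' every annotated span; `"whole"` is the full sequence.
#'
#' @param genome A [mito_genome()].
#' @param table A [feature_table()].
#' @param region One of `"whole"`, `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"intergenic"`.
#' @return A `composition_profile`.
#' @export
region_composition <- function(genome, table, region = REGION_CLASSES) {
  region <- match.arg(region)
  if (region == "whole") return(base_composition(genome$sequence))
  covered <- function(features) {
    pos <- unlist(lapply(features, function(f)
      unlist(apply(f$segments, 1, function(s)
        circular_positions(s[1], s[2], genome$length_bp),
        simplify = FALSE))))
    sort(unique(pos))
  }
  if (region == "intergenic") {
    pos <- setdiff(seq_len(genome$length_bp), covered(table$features))
    if (length(pos) == 0)
      stop("region class 'intergenic' is empty: features cover the genome")
  } else {
    members <- Filter(function(f) f$ftype == region, table$features)
    if (length(members) == 0)
      stop("region class '", region, "' is empty: no such features annotated")
    pos <- covered(members)
  }
  base_composition(paste(seq_chars(genome$sequence)[pos], collapse = ""))
}

#' Composition by codon position
#'
#' Pools the first, second and third codon positions over a set of in-frame
#' coding sequences and profiles each position separately. Third positions
#' are the least constrained and carry most of the compositional bias in
#' mitochondrial protein-coding genes.
#'
#' @param cds_list Named or unnamed list/vector of in-frame coding
#'   sequences (each length divisible by 3).
#' @return List of three `composition_profile` objects, named `pos1`,
#'   `pos2`, `pos3`.
#' @export
codon_position_composition <- function(cds_list) {
  cds_list <- as.list(cds_list)
  if (length(cds_list) == 0) stop("cds_list must be non-empty")
  nms <- names(cds_list)
  if (is.null(nms)) nms <- paste0("cds", seq_along(cds_list))
  bad <- which(vapply(cds_list, nchar, 1L) %% 3L != 0L)
  if (length(bad) > 0)
    stop("CDS length not a multiple of 3: ", paste(nms[bad], collapse = ", "))
  pooled <- lapply(1:3, function(p) {
    paste(vapply(cds_list, function(cds) {
      chars <- seq_chars(cds)
      paste(chars[seq(p, length(chars), 3L)], collapse = "")
    }, ""), collapse = "")
  })
  setNames(lapply(pooled, base_composition), c("pos1", "pos2", "pos3"))
}

#' Composition table in the style of published mitogenome summaries
#'
#' One row per genome with entire-genome percentages and skews plus
#' protein-coding-gene AT%, skews, and concatenated product length (in
#' amino acids, counting each coding segment as length/3 - 1). Percentages
#' are rounded to 1 decimal and skews to 3 decimals, half away from zero.
#'
#' @param genomes List of `list(genome =, features =)` pairs as returned by
#'   [read_genbank()] or [generate_genome()].
#' @return A data.frame with columns `species`, `accession`, `length_bp`,
#'   `A_pct`, `T_pct`, `C_pct`, `G_pct`, `AT_skew`, `GC_skew`, `pcg_aa`,
#'   `pcg_AT_pct`, `pcg_AT_skew`, `pcg_GC_skew`.
#' @export
composition_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    whole <- base_composition(g$genome$sequence)
    pcg <- region_composition(g$genome, g$features, "PCG")
    aa_total <- sum(vapply(
      Filter(function(f) f$ftype == "PCG", g$features$features),
      function(f) feature_span(f) %/% 3L - 1L, 1L))
    data.frame(
      species = g$genome$organism, accession = g$genome$accession,
      length_bp = g$genome$length_bp,
      A_pct = round_half_up(whole$pct[["A"]], 1),
      T_pct = round_half_up(whole$pct[["T"]], 1),
      C_pct = round_half_up(whole$pct[["C"]], 1),
      G_pct = round_half_up(whole$pct[["G"]], 1),
      AT_skew = round_half_up(whole$at_skew, 3),
      GC_skew = round_half_up(whole$gc_skew, 3),
      pcg_aa = aa_total,
      pcg_AT_pct = round_half_up(pcg$pct[["A"]] + pcg$pct[["T"]], 3),
      pcg_AT_skew = round_half_up(pcg$at_skew, 3),
      pcg_GC_skew = round_half_up(pcg$gc_skew, 3),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
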