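## Per-gene architecture summary: the annotation-level table of sizes,
## GC%, product lengths, start/stop codons, and signed intergenic spacers
## (positive = spacer to the next gene on the circle, negative = overlap).

#' Summarize gene architecture of an annotated genome
#'
#' One row per feature in circle order. `intergenic_bp` is the signed gap
#' to the next feature on the circle (`next_start - this_end - 1`); the
#' last feature's gap wraps to the first. `aa` counts each coding segment
#' as `size/3 - 1` (dropping the terminal codon: the stop for complete
#' genes, the intron-boundary codon for a 5' exon), matching the
#' convention of published per-gene tables. Start/stop codons are reported
#' when they belong to the canonical sets (ATG/ATA/GTG; TAA/TAG), blank
#' otherwise — an exon that begins or ends mid-frame shows a blank.
#'
#' @param genome A [mito_genome()].
#' @param table A [feature_table()].
#' @param code A [codon_table()].
#' @return data.frame with columns `gene`, `ftype`, `strand`, `size_bp`,
#'   `gc_pct`, `aa`, `start_codon`, `stop_codon`, `intergenic_bp`.
#' @export
summarize_genes <- function(genome, table, code = codon_table()) {
  feats <- table$features
  if (length(feats) == 0) stop("feature table is empty")
  L <- genome$length_bp
  starts <- vapply(feats, function(f) f$segments[1, "start"], 1L)
  ends <- vapply(feats, function(f) f$segments[nrow(f$segments), "end"], 1L)
  ord <- order(starts)
  feats <- feats[ord]; starts <- starts[ord]; ends <- ends[ord]
  n <- length(feats)
  key <- paste(vapply(feats, `[[`, "", "name"), starts)
  if (anyDuplicated(key))
    stop("overlapping identically-named features")

  rows <- lapply(seq_len(n), function(i) {
    f <- feats[[i]]
    seq <- extract_feature(genome, f)
    comp <- base_composition(seq)
    gc <- comp$pct[["G"]] + comp$pct[["C"]]
    is_pcg <- f$ftype == "PCG"
    aa <- if (is_pcg) nchar(seq) %/% 3L - 1L else NA_integer_
    start_cod <- stop_cod <- NA_character_
    if (is_pcg && nchar(seq) >= 6) {
      ss <- detect_start_stop(seq, code)
      if (ss$start_canonical) start_cod <- ss$start
      stop_cod <- ss$stop
    }
    nxt <- if (i < n) i + 1 else 1
    gap <- starts[nxt] - ends[i] - 1L
    if (i == n) gap <- gap + L  # wrap gap attributed to the last feature
    data.frame(gene = f$name, ftype = f$ftype, strand = f$strand,
               size_bp = feature_span(f),
               gc_pct = round_half_up(gc, 2),
               aa = aa, start_codon = start_cod, stop_codon = stop_cod,
               intergenic_bp = gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Canonical gene-order string of a circular genome
#'
#' Rotates the circle-order gene list to start at tRNA-Met (falling back
#' to the alphabetically first name when absent), so the same circular
#' arrangement yields the same string regardless of where the genome's
#' origin was placed. Comparable across genomes as a rearrangement check.
#'
#' @param table A [feature_table()].
#' @param anchor Gene name at which to start the canonical order.
#' @return Character vector of gene names in canonical circular order.
#' @export
gene_order_string <- function(table, anchor = "tRNA-Met") {
  feats <- table$features
  if (length(feats) == 0) return(character(0))
  starts <- vapply(feats, function(f) f$segments[1, "start"], 1L)
  nms <- vapply(feats, `[[`, "", "name")[order(starts)]
  at <- match(anchor, nms)
  if (is.na(at)) at <- which.min(nms)
  if (at > 1) nms <- c(nms[at:length(nms)], nms[1:(at - 1)])
  nms
}
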