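## Concatenated 13-PCG supermatrix construction and a lightweight
## neighbor-joining tree for pipeline sanity checks.
##
## Concatenation convention: coding segments are taken in circle order
## with the final codon of every segment dropped — the terminal stop for
## complete genes, the intron-boundary codon for the ND5 exons — so the
## amino-acid matrix length equals the sum of the per-gene product
## lengths (size/3 - 1 per segment). ND5's two trimmed exons form a
## single ND5 partition.

SUPERMATRIX_GENE_ORDER <- c("ND5", "ND1", "Cyt b", "ND2", "ND6", "ATP6",
                            "ND4", "COIII", "COII", "ND4L", "ND3", "ATP8",
                            "COI")

#' Build a concatenated protein-coding-gene supermatrix
#'
#' Equal-length orthologs are concatenated directly; a per-gene length
#' mismatch across taxa is an error instructing external alignment (no
#' silent padding or internal aligner). At the amino-acid level each
#' trimmed segment is translated under the configured code.
#'
#' @param genomes Named list of `list(genome =, features =)` pairs; names
#'   (or accessions) become taxon labels.
#' @param level `"nt"` or `"aa"`.
#' @param table A [codon_table()].
#' @return A `supermatrix`: list with `taxa`, `level`, `matrix` (named
#'   character vector, one concatenated sequence per taxon) and
#'   `partitions` (data.frame `gene`, `start_col`, `end_col` tiling the
#'   columns exactly).
#' @export
build_supermatrix <- function(genomes, level = c("nt", "aa"),
                              table = codon_table()) {
  level <- match.arg(level)
  if (length(genomes) == 0) stop("no genomes supplied")
  taxa <- names(genomes)
  if (is.null(taxa))
    taxa <- vapply(genomes, function(g) g$genome$accession, "")
  names(genomes) <- taxa

  per_taxon <- lapply(genomes, function(g) {
    segs <- coding_segments_trimmed(g)
    if (level == "aa")
      segs <- vapply(segs, translate, "", table = table)
    ## join the two ND5 exon segments into one partition
    joined <- setNames(vector("list", length(SUPERMATRIX_GENE_ORDER)),
                       SUPERMATRIX_GENE_ORDER)
    for (nm in names(segs)) {
      key <- if (nm %in% c("ND5-5prime", "ND5-3prime")) "ND5" else nm
      joined[[key]] <- paste0(joined[[key]] %||% "", segs[[nm]])
    }
    joined
  })

  for (gene in SUPERMATRIX_GENE_ORDER) {
    missing <- taxa[vapply(per_taxon, function(x) is.null(x[[gene]]), TRUE)]
    if (length(missing) > 0)
      stop("gene ", gene, " missing in taxon ",
           paste(missing, collapse = ", "))
    lens <- vapply(per_taxon, function(x) nchar(x[[gene]]), 1L)
    if (length(unique(lens)) > 1)
      stop("per-gene length mismatch for ", gene, " (",
           paste(paste0(taxa, "=", lens), collapse = ", "),
           "); align externally before concatenation")
  }

  gene_len <- vapply(SUPERMATRIX_GENE_ORDER,
                     function(gn) nchar(per_taxon[[1]][[gn]]), 1L)
  ends <- cumsum(gene_len)
  partitions <- data.frame(gene = SUPERMATRIX_GENE_ORDER,
                           start_col = c(1L, head(ends, -1) + 1L),
                           end_col = ends, stringsAsFactors = FALSE,
                           row.names = NULL)
  mat <- vapply(per_taxon, function(x)
    paste(unlist(x[SUPERMATRIX_GENE_ORDER]), collapse = ""), "")
  structure(list(taxa = taxa, level = level, matrix = mat,
                 partitions = partitions),
            class = "supermatrix")
}

## Coding segments of one genome in circle order, each with its final
## codon dropped. ND5 exons are kept separate here (joined at partition
## level); the 3' exon of a split gene is trimmed of its stop, the 5'
## exon of its intron-boundary codon.
coding_segments_trimmed <- function(g) {
  feats <- Filter(function(f) f$ftype == "PCG", g$features$features)
  if (length(feats) == 0) stop("no protein-coding genes annotated")
  starts <- vapply(feats, function(f) f$segments[1, "start"], 1L)
  feats <- feats[order(starts)]
  out <- setNames(
    lapply(feats, function(f) {
      s <- extract_feature(g$genome, f)
      substr(s, 1, nchar(s) - 3L)
    }),
    vapply(feats, `[[`, "", "name"))
  out
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa, %d %s columns, %d partitions\n",
              length(x$taxa), nchar(x$matrix[[1]]), x$level,
              nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix to FASTA, relaxed PHYLIP, or NEXUS
#'
#' The NEXUS output includes a `sets` block with one `charset` per gene
#' partition. All writers emit ASCII with Unix newlines.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return Invisibly, `path`.
#' @export
write_supermatrix <- function(sm, path,
                              format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  ncols <- nchar(sm$matrix[[1]])
  lines <- switch(
    format,
    fasta = unlist(lapply(sm$taxa, function(t)
      c(paste0(">", t), sm$matrix[[t]]))),
    phylip = c(paste(length(sm$taxa), ncols),
               vapply(sm$taxa, function(t)
                 sprintf("%s  %s", t, sm$matrix[[t]]), "")),
    nexus = {
      dtype <- if (sm$level == "nt") "DNA" else "PROTEIN"
      c("#NEXUS", "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa), ncols),
        sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-;", dtype),
        "  MATRIX",
        vapply(sm$taxa, function(t)
          sprintf("    %s  %s", gsub("[^A-Za-z0-9_.]", "_", t),
                  sm$matrix[[t]]), ""),
        "  ;", "END;", "BEGIN SETS;",
        vapply(seq_len(nrow(sm$partitions)), function(i)
          sprintf("  CHARSET %s = %d-%d;",
                  gsub("[^A-Za-z0-9_.]", "_", sm$partitions$gene[i]),
                  sm$partitions$start_col[i], sm$partitions$end_col[i]),
          ""),
        "END;")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise distances between supermatrix rows
#'
#' p-distance (proportion of differing columns) or its Jukes-Cantor
#' correction; the correction uses the alphabet size of the level (4-state
#' for nucleotides, 20-state for amino acids).
#'
#' @param sm A `supermatrix`.
#' @param distance `"p"` or `"jc"`.
#' @return A `dist` object over the taxa, ordered by taxon label.
#' @export
supermatrix_dist <- function(sm, distance = c("p", "jc")) {
  distance <- match.arg(distance)
  taxa <- sort(sm$taxa)  # deterministic tie-breaking by label order
  rows <- lapply(sm$matrix[taxa], seq_chars)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    p <- mean(rows[[i]] != rows[[j]])
    if (distance == "jc") {
      r <- if (sm$level == "nt") 4 else 20
      f <- (r - 1) / r
      if (p >= f) stop("saturated distance between ", taxa[i], " and ",
                       taxa[j], " (p = ", signif(p, 3), ")")
      p <- -f * log(1 - p / f)
    }
    d[i, j] <- d[j, i] <- p
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from a supermatrix
#'
#' Builds pairwise distances (ties broken deterministically by sorting
#' taxa by label) and runs neighbor joining. Duplicate taxa are allowed
#' and yield zero-length branches.
#'
#' @param sm A `supermatrix` of at least 3 taxa.
#' @param distance `"p"` or `"jc"`.
#' @return Newick string with branch lengths.
#' @export
nj_tree <- function(sm, distance = c("p", "jc")) {
  if (length(sm$taxa) < 3) stop("need at least 3 taxa")
  tree <- ape::nj(supermatrix_dist(sm, distance))
  ape::write.tree(tree)
}
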