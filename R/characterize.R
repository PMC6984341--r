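## One-call characterization of one or more annotated mitogenomes,
## regenerating the standard report tables: per-genome gene architecture,
## pooled composition summary, RSCU, and pairwise per-gene Ka/Ks.

#' Run configuration for report generation
#'
#' @param code_table Genetic-code id (default 4).
#' @param pct_decimals,skew_decimals Rounding for reported percentages
#'   (default 1) and skews (default 3), matching the print precision of
#'   published composition tables.
#' @return A `run_config` list.
#' @export
run_config <- function(code_table = 4, pct_decimals = 1,
                       skew_decimals = 3) {
  stopifnot(pct_decimals >= 0, skew_decimals >= 0)
  structure(list(code_table = code_table, pct_decimals = pct_decimals,
                 skew_decimals = skew_decimals),
            class = "run_config")
}

#' Characterize annotated mitogenomes into a report bundle
#'
#' For each input genome writes a gene-architecture TSV and an RSCU TSV;
#' across genomes writes a pooled composition-summary TSV, pairwise
#' per-gene Ka/Ks TSVs when two or more genomes are given, and a JSON
#' manifest recording inputs, configuration and package version. All
#' tables are ASCII TSV with Unix newlines (any Unicode minus is
#' normalized to the ASCII hyphen).
#'
#' @param inputs Either a character vector of GenBank file paths or a
#'   list of `list(genome =, features =)` pairs.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list.
#' @export
characterize <- function(inputs, out_dir, config = run_config()) {
  if (is.character(inputs)) {
    genomes <- lapply(inputs, read_genbank)
  } else {
    genomes <- inputs
  }
  if (length(genomes) == 0) stop("no input genomes")
  names(genomes) <- vapply(genomes, function(g) g$genome$accession, "")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- codon_table(config$code_table)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_ascii(df, path)
    written <<- c(written, name)
  }

  for (acc in names(genomes)) {
    g <- genomes[[acc]]
    emit(summarize_genes(g$genome, g$features, code),
         sprintf("architecture_%s.tsv", acc))
    counts <- pooled_codon_counts(pcg_sequences(g$genome, g$features), code)
    emit(rscu(counts, code), sprintf("rscu_%s.tsv", acc))
  }
  emit(composition_table(genomes), "composition_summary.tsv")
  if (length(genomes) >= 2) {
    pairs <- utils::combn(names(genomes), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      emit(kaks_table(genomes[[a]], genomes[[b]], code),
           sprintf("kaks_%s_vs_%s.tsv", a, b))
    }
  }
  manifest <- list(
    package = "mitochar",
    version = as.character(utils::packageVersion("mitochar")),
    inputs = names(genomes),
    config = unclass(config),
    outputs = written
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## TSV writer: ASCII only, Unix newlines, U+2212 minus normalized to '-'.
write_tsv_ascii <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.character(df[[j]]))
      df[[j]] <- gsub("\u2212", "-", df[[j]])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n")
  invisible(path)
}
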