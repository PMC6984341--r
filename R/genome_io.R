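## Genome and feature containers, circular coordinate handling, and I/O.
##
## Coordinates are 1-based inclusive (GenBank convention). Circularity is
## encoded by allowing a segment end to run past the sequence length: a
## segment (L-3, L+4) on a genome of length L wraps through the origin.
## The GenBank writer emits such segments as join(start..L,1..rest); the
## reader folds that form back into the wrapped representation, so writer
## and reader round-trip exactly.

CANONICAL_GENES <- c(
  "tRNA-Met", "16S rRNA", "ND5-5prime", "ND1", "Cyt b", "ND2", "ND6",
  "ATP6", "ND4", "12S rRNA", "COIII", "COII", "ND4L", "ND3",
  "ND5-3prime", "tRNA-Trp", "ATP8", "COI"
)

GENE_ALIASES <- c(
  "nd1" = "ND1", "nad1" = "ND1", "nd2" = "ND2", "nad2" = "ND2",
  "nd3" = "ND3", "nad3" = "ND3", "nd4" = "ND4", "nad4" = "ND4",
  "nd4l" = "ND4L", "nad4l" = "ND4L", "nd5" = "ND5", "nad5" = "ND5",
  "nd6" = "ND6", "nad6" = "ND6",
  "coi" = "COI", "cox1" = "COI", "co1" = "COI",
  "coii" = "COII", "cox2" = "COII", "co2" = "COII",
  "coiii" = "COIII", "cox3" = "COIII", "co3" = "COIII",
  "atp6" = "ATP6", "atpase6" = "ATP6", "atp8" = "ATP8", "atpase8" = "ATP8",
  "cytb" = "Cyt b", "cyt b" = "Cyt b", "cob" = "Cyt b",
  "trnm" = "tRNA-Met", "trna-met" = "tRNA-Met", "trnamet" = "tRNA-Met",
  "trnw" = "tRNA-Trp", "trna-trp" = "tRNA-Trp", "trnatrp" = "tRNA-Trp",
  "rrns" = "12S rRNA", "12s" = "12S rRNA", "12s rrna" = "12S rRNA",
  "s-rrna" = "12S rRNA",
  "rrnl" = "16S rRNA", "16s" = "16S rRNA", "16s rrna" = "16S rRNA",
  "l-rrna" = "16S rRNA",
  "nd5-5prime" = "ND5-5prime", "nd5_5" = "ND5-5prime",
  "nd5 5'" = "ND5-5prime", "nad5_exon1" = "ND5-5prime",
  "nd5-3prime" = "ND5-3prime", "nd5_3" = "ND5-3prime",
  "nd5 3'" = "ND5-3prime", "nad5_exon2" = "ND5-3prime"
)

#' Standardize a mitochondrial gene name
#'
#' Maps common annotation spellings (nad5, cox1, cob, rrnL, trnM, ...) onto
#' the package's canonical labels. Returns `NA` for unrecognized names.
#'
#' @param name Character vector of raw gene labels.
#' @return Character vector of canonical labels or `NA`.
#' @export
standardize_gene_name <- function(name) {
  key <- tolower(trimws(name))
  out <- unname(GENE_ALIASES[key])
  direct <- name %in% c(CANONICAL_GENES, "ND5")
  out[direct] <- name[direct]
  out
}

#' Construct a mitochondrial genome object
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param accession Text identifier.
#' @param organism Organism name.
#' @param is_circular Logical; every genome this pipeline produces is
#'   circular.
#' @return A `mito_genome`: list with `sequence`, `length_bp`, `accession`,
#'   `organism`, `is_circular`.
#' @export
mito_genome <- function(sequence, accession = "UNKNOWN",
                        organism = "unknown organism", is_circular = TRUE) {
  sequence <- toupper(sequence)
  if (!is_nucleotide_string(sequence))
    stop("sequence must be non-empty and contain only A, C, G, T, N")
  structure(
    list(sequence = sequence, length_bp = nchar(sequence),
         accession = accession, organism = organism,
         is_circular = isTRUE(is_circular)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %d bp, %s\n", x$accession, x$organism,
              x$length_bp, if (x$is_circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a gene feature
#'
#' @param name Canonical gene label (see [standardize_gene_name()]).
#' @param ftype One of `"PCG"`, `"tRNA"`, `"rRNA"`.
#' @param segments Matrix or list of 1-based inclusive `(start, end)` pairs;
#'   `end` may exceed the genome length to wrap through the origin.
#'   Multi-segment features are joined in list order.
#' @param strand `"H"` (all scleractinian mitochondrial genes) or `"L"`.
#' @return A `gene_feature` list.
#' @export
gene_feature <- function(name, ftype = c("PCG", "tRNA", "rRNA"),
                         segments, strand = "H") {
  ftype <- match.arg(ftype)
  if (is.list(segments)) segments <- do.call(rbind, segments)
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0) stop("feature ", name, ": segments must be non-empty")
  if (any(segments[, "start"] < 1))
    stop("feature ", name, ": segment start below 1")
  if (any(segments[, "end"] < segments[, "start"]))
    stop("feature ", name, ": segment end before start")
  if (!strand %in% c("H", "L")) stop("strand must be 'H' or 'L'")
  structure(list(name = name, ftype = ftype, strand = strand,
                 segments = segments),
            class = "gene_feature")
}

feature_span <- function(feature) {
  sum(feature$segments[, "end"] - feature$segments[, "start"] + 1L)
}

#' Construct a feature table
#'
#' @param features List of [gene_feature()] objects; sorted by first-segment
#'   start. Duplicate names are an error.
#' @param genome_ref Accession of the genome the coordinates refer to.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, genome_ref = "UNKNOWN") {
  nms <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate feature name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (length(features) > 0) {
    starts <- vapply(features, function(f) f$segments[1, "start"], 1L)
    features <- features[order(starts)]
  }
  structure(list(genome_ref = genome_ref, features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d features\n", x$genome_ref,
              length(x$features)))
  for (f in x$features) {
    seg <- paste(apply(f$segments, 1, function(s)
      paste0(s[1], "..", s[2])), collapse = ",")
    cat(sprintf("  %-12s %-4s %s %s\n", f$name, f$ftype, f$strand, seg))
  }
  invisible(x)
}

#' @export
length.feature_table <- function(x) length(x$features)

feature_by_name <- function(table, name) {
  for (f in table$features) if (f$name == name) return(f)
  NULL
}

## Map circular coordinates (possibly > length) onto genome positions.
circular_positions <- function(start, end, length_bp) {
  ((seq.int(start, end) - 1L) %% length_bp) + 1L
}

#' Extract the sequence of a feature from a circular genome
#'
#' Segments are extracted 1-based inclusive and concatenated in list order,
#' so the joined sequence of an intron-split gene skips the intron. A
#' segment whose end exceeds the genome length wraps through the origin.
#' Features on the L strand are reverse-complemented.
#'
#' @param genome A [mito_genome()].
#' @param feature A [gene_feature()].
#' @return Nucleotide string.
#' @export
#' @examples
#' g <- mito_genome("ACGTACGT")
#' extract_feature(g, gene_feature("ND1", "PCG", cbind(7, 10)))  # "GTAC"
extract_feature <- function(genome, feature) {
  chars <- seq_chars(genome$sequence)
  pieces <- apply(feature$segments, 1, function(s) {
    if (!genome$is_circular && s[2] > genome$length_bp)
      stop("feature ", feature$name, " runs past the end of a linear genome")
    paste(chars[circular_positions(s[1], s[2], genome$length_bp)],
          collapse = "")
  })
  out <- paste(pieces, collapse = "")
  if (feature$strand == "L")
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  out
}

## ---- feature TSV dialect ---------------------------------------------------
## Columns: name, ftype, strand, segments; segments encoded
## "start..end[,start..end]" with end possibly past the genome length
## (wrap-around). Lines starting with '#' are comments.

#' Read a feature table from TSV
#'
#' @param genome The [mito_genome()] the coordinates refer to.
#' @param path Path to a tab-separated file with columns `name`, `ftype`,
#'   `strand`, `segments` (`start..end`, comma-separated for multi-segment
#'   features; an end past the genome length wraps through the origin).
#' @return A [feature_table()].
#' @export
read_feature_tsv <- function(genome, path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) > 0 &&
      grepl("^name\t", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  feats <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 4)
      stop("line ", i, ": expected 4 tab-separated fields, got ",
           length(fields))
    segs <- parse_segments(fields[4], line = i)
    if (any(segs > 2L * genome$length_bp))
      stop("line ", i, ": coordinate beyond twice the genome length (",
           genome$length_bp, " bp)")
    feats[[i]] <- gene_feature(fields[1], fields[2], segs,
                               strand = fields[3])
  }
  feature_table(feats, genome_ref = genome$accession)
}

parse_segments <- function(text, line = NA) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  where <- if (is.na(line)) "" else paste0("line ", line, ": ")
  if (length(parts) == 0) stop(where, "empty segment string")
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", trimws(p)))[[1]]
    if (length(m) != 3)
      stop(where, "malformed segment '", p, "' (expected start..end)")
    as.integer(m[2:3])
  })
  do.call(rbind, segs)
}

#' Write a feature table to TSV
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_tsv <- function(table, path) {
  lines <- c("name\tftype\tstrand\tsegments",
             vapply(table$features, function(f) {
               seg <- paste(apply(f$segments, 1, function(s)
                 paste0(s[1], "..", s[2])), collapse = ",")
               paste(f$name, f$ftype, f$strand, seg, sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

## ---- GenBank flat file -----------------------------------------------------

GB_FEATURE_KEYS <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")

#' Read a single-record GenBank flat file
#'
#' Minimal parser for annotated mitogenomes: LOCUS (length, circularity),
#' ACCESSION, SOURCE/organism, CDS/tRNA/rRNA features (including `join()`
#' and `complement()` locations) and the ORIGIN sequence. Feature names are
#' taken from the `/gene` (or `/product`) qualifier and standardized; a CDS
#' without a recognizable name is skipped with a warning. A trailing
#' `join(x..L,1..y)` across the origin is folded into the wrapped
#' single-segment form `(x, L + y)`.
#'
#' @param path Path to a GenBank flat file with one record.
#' @return List with elements `genome` ([mito_genome()]) and `features`
#'   ([feature_table()]).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0)
    stop("GenBank parse error: no ORIGIN sequence in ", path)
  origin_at <- origin_at[1]

  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0 && grepl("circular", locus[1])
  accession <- "UNKNOWN"
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]]
    if (length(acc) > 0 && nzchar(acc[1])) accession <- acc[1]
  }
  organism <- "unknown organism"
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(org_line) > 0) {
    organism <- trimws(sub("^\\s+ORGANISM", "", org_line[1]))
  } else {
    src_line <- grep("^SOURCE", lines, value = TRUE)
    if (length(src_line) > 0) {
      src <- trimws(sub("^SOURCE", "", src_line[1]))
      src <- sub("\\s+mitochondrion.*$", "", src)
      if (nzchar(src)) organism <- src
    }
  }

  ## sequence block: strip numbers and spaces
  seq_lines <- lines[(origin_at + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop("GenBank parse error: empty ORIGIN sequence in ", path)
  genome <- mito_genome(sequence, accession = accession,
                        organism = organism, is_circular = circular)

  feat_at <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_at) > 0) {
    block <- lines[(feat_at[1] + 1):(origin_at - 1)]
    feats <- parse_gb_features(block, genome$length_bp)
  } else {
    warning("no FEATURES block in ", path)
  }
  list(genome = genome,
       features = feature_table(feats, genome_ref = accession))
}

parse_gb_features <- function(block, length_bp) {
  ## a feature line starts at column 6 with a key; continuation/qualifier
  ## lines start at column 22
  key_idx <- grep("^\\s{5}\\S", block)
  feats <- list()
  for (j in seq_along(key_idx)) {
    from <- key_idx[j]
    to <- if (j < length(key_idx)) key_idx[j + 1] - 1 else length(block)
    chunk <- block[from:to]
    key <- sub("^\\s+(\\S+).*$", "\\1", chunk[1])
    ftype <- names(GB_FEATURE_KEYS)[GB_FEATURE_KEYS == key]
    if (length(ftype) == 0) next  # source etc.

    ## location may continue over lines until the first qualifier
    qual_start <- grep("^\\s+/", chunk)
    loc_end <- if (length(qual_start) > 0) qual_start[1] - 1 else length(chunk)
    loc <- paste(trimws(sub("^\\s+\\S+\\s*", "", chunk[1])),
                 paste(trimws(chunk[seq_len(loc_end)[-1]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)

    quals <- chunk[grepl("^\\s+/", chunk)]
    name_raw <- gb_qualifier(quals, "gene")
    if (is.na(name_raw)) name_raw <- gb_qualifier(quals, "product")
    name <- if (is.na(name_raw)) NA_character_ else standardize_gene_name(name_raw)
    if (is.na(name)) {
      warning("skipping ", key, " feature at ", loc,
              ": no recognizable gene name",
              if (!is.na(name_raw)) paste0(" ('", name_raw, "')") else "")
      next
    }
    parsed <- parse_gb_location(loc, length_bp)
    feats[[length(feats) + 1]] <-
      gene_feature(name, ftype, parsed$segments, strand = parsed$strand)
  }
  feats
}

gb_qualifier <- function(quals, what) {
  hit <- grep(paste0("^\\s*/", what, "="), quals, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  gsub('^[^=]*="?|"$', "", trimws(hit[1]))
}

parse_gb_location <- function(loc, length_bp) {
  strand <- "H"
  if (startsWith(loc, "complement(")) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  segs <- parse_segments(loc)
  ## fold join(x..L, 1..y) back into the wrapped representation (x, L+y)
  n <- nrow(segs)
  if (n >= 2 && segs[n - 1, 2] == length_bp && segs[n, 1] == 1L) {
    segs[n - 1, 2] <- length_bp + segs[n, 2]
    segs <- segs[-n, , drop = FALSE]
  }
  list(segments = segs, strand = strand)
}

#' Write a genome and its features as a GenBank flat file
#'
#' Emits a minimally valid single-record flat file (LOCUS, ACCESSION,
#' SOURCE, FEATURES, ORIGIN; ASCII, Unix newlines) that [read_genbank()]
#' round-trips exactly at the sequence and feature level. Segments wrapping
#' the origin are written as `join(start..L,1..rest)`.
#'
#' @param genome A [mito_genome()].
#' @param table A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(genome, table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %s INV",
            genome$accession, genome$length_bp,
            if (genome$is_circular) "circular" else "linear"))
  w(sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$organism))
  w(sprintf("ACCESSION   %s", genome$accession))
  w(sprintf("SOURCE      %s mitochondrion", genome$organism))
  w(sprintf("  ORGANISM  %s", genome$organism))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", genome$length_bp))
  w(sprintf('                     /organism="%s"', genome$organism))
  for (f in table$features) {
    loc <- gb_location_string(f, genome$length_bp)
    w(sprintf("     %-15s %s", GB_FEATURE_KEYS[[f$ftype]], loc))
    w(sprintf('                     /gene="%s"', f$name))
  }
  w("ORIGIN")
  chars <- seq_chars(tolower(genome$sequence))
  for (i in seq(1, length(chars), 60)) {
    chunk <- chars[i:min(i + 59, length(chars))]
    groups <- split(chunk, (seq_along(chunk) - 1) %/% 10)
    w(sprintf("%9d %s", i,
              paste(vapply(groups, paste, "", collapse = ""), collapse = " ")))
  }
  w("//")
  invisible(path)
}

gb_location_string <- function(feature, length_bp) {
  segs <- feature$segments
  parts <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    if (e > length_bp) {
      parts <- c(parts, paste0(s, "..", length_bp),
                 paste0(1, "..", e - length_bp))
    } else {
      parts <- c(parts, paste0(s, "..", e))
    }
  }
  loc <- if (length(parts) > 1)
    paste0("join(", paste(unlist(parts), collapse = ","), ")")
  else unlist(parts)
  if (feature$strand == "L") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a genome as FASTA
#'
#' @param genome A [mito_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  chars <- seq_chars(genome$sequence)
  starts <- seq(1, length(chars), 70)
  lines <- vapply(starts, function(i)
    paste(chars[i:min(i + 69, length(chars))], collapse = ""), "")
  writeLines(c(sprintf(">%s %s", genome$accession, genome$organism), lines),
             path)
  invisible(path)
}
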