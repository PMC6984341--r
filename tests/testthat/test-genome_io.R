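test_that("circular feature extraction wraps, joins, and reverse-complements", {
  g <- mito_genome("ACGTACGT")
  expect_equal(extract_feature(g, gene_feature("ND1", "PCG", cbind(7, 10))),
               "GTAC")
  expect_equal(extract_feature(g, gene_feature("ND1", "PCG", cbind(1, 8))),
               "ACGTACGT")
  expect_equal(
    extract_feature(g, gene_feature("ND1", "PCG",
                                    rbind(c(1, 3), c(6, 8)))),
    "ACGCGT")
  ## L strand: reverse complement of the extracted span
  expect_equal(extract_feature(g, gene_feature("ND1", "PCG", cbind(1, 4),
                                               strand = "L")),
               "ACGT")  # revcomp of ACGT is ACGT
  expect_equal(extract_feature(g, gene_feature("ND1", "PCG", cbind(2, 4),
                                               strand = "L")),
               "ACG")   # revcomp of CGT
})

test_that("extraction length equals the summed segment spans, wrap included", {
  g <- default_genome()
  set.seed(11)
  for (k in 1:25) {
    n_seg <- sample(1:3, 1)
    segs <- t(vapply(seq_len(n_seg), function(i) {
      s <- sample.int(g$genome$length_bp, 1)
      c(s, s + sample.int(500, 1))
    }, c(0L, 0L)))
    f <- gene_feature("ND1", "PCG", segs)
    expect_equal(nchar(extract_feature(g$genome, f)),
                 sum(segs[, 2] - segs[, 1] + 1))
  }
})

test_that("feature TSV dialect parses coordinates, joins, and empty input", {
  g <- mito_genome(strrep("ACGT", 4500))  # 18,000 bp
  tf <- tempfile(fileext = ".tsv")

  writeLines("COI\tPCG\tH\t100..1692", tf)
  tab <- read_feature_tsv(g, tf)
  expect_length(tab, 1L)
  expect_equal(nchar(extract_feature(g, tab$features[[1]])), 1593L)

  writeLines("ND5-5prime\tPCG\tH\t700..1410,10300..11403", tf)
  tab <- read_feature_tsv(g, tf)
  expect_equal(nrow(tab$features[[1]]$segments), 2L)
  expect_equal(nchar(extract_feature(g, tab$features[[1]])), 711L + 1104L)

  writeLines(character(0), tf)
  expect_length(read_feature_tsv(g, tf), 0L)

  writeLines("COI\tPCG\tH\t100-1692", tf)
  expect_error(read_feature_tsv(g, tf), "line 1.*malformed segment")

  writeLines(c("COI\tPCG\tH\t100..1692", "ND3\tPCG\tH\t1..99999"), tf)
  expect_error(read_feature_tsv(g, tf), "line 2.*beyond twice")

  ## header line tolerated; round trip through the writer
  writeLines(c("name\tftype\tstrand\tsegments", "COI\tPCG\tH\t100..1692"), tf)
  tab <- read_feature_tsv(g, tf)
  write_feature_tsv(tab, tf)
  expect_equal(read_feature_tsv(g, tf), tab)
})

test_that("GenBank write/read round-trips genomes and features exactly", {
  g <- default_genome()
  tf <- tempfile(fileext = ".gb")
  write_genbank(g$genome, g$features, tf)
  rt <- read_genbank(tf)
  expect_identical(rt$genome, g$genome)
  expect_identical(rt$features, g$features)

  ## a feature wrapping the origin survives the join() encoding
  gw <- mito_genome(strrep("ACGTTGCA", 100), accession = "WRAP01")
  tabw <- feature_table(list(
    gene_feature("COI", "PCG", cbind(701L, 820L)),   # wraps: 820 > 800
    gene_feature("tRNA-Met", "tRNA", cbind(10L, 81L))), "WRAP01")
  write_genbank(gw, tabw, tf)
  rtw <- read_genbank(tf)
  expect_identical(rtw$features, tabw)
  expect_identical(rtw$genome$sequence, gw$sequence)
})

test_that("GenBank parser handles degenerate and foreign records", {
  tf <- tempfile(fileext = ".gb")
  ## no features at all
  writeLines(c(
    "LOCUS       X1 12 bp DNA circular INV",
    "ACCESSION   X1",
    "ORIGIN",
    "        1 acgtacgtacgt",
    "//"), tf)
  expect_warning(rec <- read_genbank(tf), "no FEATURES block")
  expect_equal(rec$genome$length_bp, 12L)
  expect_length(rec$features, 0L)

  ## missing ORIGIN is a parse error
  writeLines(c("LOCUS       X1 12 bp DNA circular INV", "//"), tf)
  expect_error(read_genbank(tf), "ORIGIN")

  ## unrecognizable gene name: warning, feature skipped
  writeLines(c(
    "LOCUS       X2 24 bp DNA circular INV",
    "ACCESSION   X2",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..12",
    '                     /gene="mystery7"',
    "     tRNA            13..24",
    '                     /gene="trnM"',
    "ORIGIN",
    "        1 atgaaatttga atttaaatta aatt",
    "//"), tf)
  expect_warning(rec <- read_genbank(tf), "mystery7")
  expect_length(rec$features, 1L)
  expect_equal(rec$features$features[[1]]$name, "tRNA-Met")
})

test_that("annotation name standardization covers common spellings", {
  expect_equal(standardize_gene_name(c("nad5", "COX1", "cob", "rrnL",
                                       "trnW", "ND4L")),
               c("ND5", "COI", "Cyt b", "16S rRNA", "tRNA-Trp", "ND4L"))
  expect_true(is.na(standardize_gene_name("ORF-lost")))
})

test_that("preset features extract at their canonical published sizes", {
  g <- default_genome()
  arch <- merulinid_architecture()
  for (i in seq_len(nrow(arch))) {
    f <- Filter(function(x) x$name == arch$gene[i], g$features$features)[[1]]
    expect_equal(nchar(extract_feature(g$genome, f)), arch$size_bp[i],
                 info = arch$gene[i])
  }
})
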