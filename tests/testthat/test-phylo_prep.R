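test_that("supermatrix dimensions follow the trimmed-segment accounting", {
  g <- default_genome()
  taxa <- list(tax_a = g, tax_b = g, tax_c = g)
  sm_aa <- build_supermatrix(taxa, "aa")
  sm_nt <- build_supermatrix(taxa, "nt")

  ## 13 concatenated products of the canonical architecture: 3915 aa
  expect_equal(nchar(sm_aa$matrix[[1]]), 3915L)
  arch <- merulinid_architecture()
  coding <- arch$size_bp[arch$ftype == "PCG"]
  expect_equal(nchar(sm_nt$matrix[[1]]), sum(coding - 3L))
  expect_equal(nchar(sm_nt$matrix[[1]]), 3L * nchar(sm_aa$matrix[[1]]))

  ## partitions tile the columns exactly, 13 genes, ND5 joined
  for (sm in list(sm_aa, sm_nt)) {
    p <- sm$partitions
    expect_equal(nrow(p), 13L)
    expect_equal(p$start_col[1], 1L)
    expect_equal(p$end_col[nrow(p)], nchar(sm$matrix[[1]]))
    expect_true(all(p$start_col[-1] == head(p$end_col, -1) + 1))
  }

  ## no stop characters in the amino-acid matrix
  expect_false(grepl("\\*", sm_aa$matrix[[1]]))

  ## single taxon: the matrix is its own concatenation
  one <- build_supermatrix(list(solo = g), "nt")
  expect_equal(one$matrix[["solo"]], sm_nt$matrix[["tax_a"]])
})

test_that("missing genes and length-discordant orthologs are hard errors", {
  g <- default_genome()
  no_coi <- list(genome = g$genome,
                 features = feature_table(
                   Filter(function(f) f$name != "COI", g$features$features),
                   g$genome$accession))
  expect_error(build_supermatrix(list(a = g, b = no_coi), "nt"),
               "COI.*missing in taxon b")

  short_coi <- generate_genome(genome_spec(seed = 77,
                                           gene_sizes = c(COI = 1587L)))
  expect_error(build_supermatrix(list(a = g, b = short_coi), "nt"),
               "length mismatch for COI.*align externally")
})

test_that("supermatrix writers emit parseable FASTA, PHYLIP, and NEXUS", {
  g <- default_genome()
  sm <- build_supermatrix(list(tax_a = g, tax_b = g, tax_c = g), "aa")
  tf <- tempfile()

  write_supermatrix(sm, tf, "fasta")
  fa <- readLines(tf)
  expect_equal(sum(startsWith(fa, ">")), 3L)

  write_supermatrix(sm, tf, "phylip")
  ph <- readLines(tf)
  expect_equal(strsplit(ph[1], " ")[[1]], c("3", "3915"))

  write_supermatrix(sm, tf, "nexus")
  nx <- readLines(tf)
  expect_equal(nx[1], "#NEXUS")
  expect_equal(sum(grepl("^  CHARSET", nx)), 13L)
  expect_true(any(grepl("NCHAR=3915", nx)))
})

test_that("neighbor joining recovers known topologies deterministically", {
  g <- generate_genome(genome_spec(seed = 55))
  newick <- "((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06,(E:0.08,F:0.08):0.06);"
  tips <- evolve_on_tree(g, newick, rate = 1, seed = 13)
  sm <- build_supermatrix(tips, "nt")

  est <- ape::read.tree(text = nj_tree(sm, "jc"))
  truth <- ape::read.tree(text = newick)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(est),
                                         ape::unroot(truth))), 0)

  ## taxon input order does not change the topology or the Newick string
  perm <- sm
  perm$matrix <- perm$matrix[rev(names(perm$matrix))]
  perm$taxa <- rev(perm$taxa)
  expect_equal(nj_tree(perm, "jc"), nj_tree(sm, "jc"))

  ## three taxa: the single unrooted topology, with additive branch lengths
  sm3 <- build_supermatrix(tips[c("A", "C", "E")], "nt")
  tr3 <- ape::read.tree(text = nj_tree(sm3, "p"))
  expect_equal(length(tr3$tip.label), 3L)
  expect_equal(tr3$Nnode, 1L)

  ## identical sequences: all distances and branch lengths zero
  smz <- build_supermatrix(list(A = g, B = g, C = g), "nt")
  trz <- ape::read.tree(text = nj_tree(smz, "p"))
  expect_true(all(abs(trz$edge.length) < 1e-12))
  expect_error(nj_tree(build_supermatrix(list(A = g, B = g), "nt")),
               "at least 3")
})

test_that("supermatrix distances apply the alphabet-correct JC correction", {
  g <- default_genome()
  tips <- evolve_on_tree(g, "((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);",
                         rate = 1, seed = 3)
  sm <- build_supermatrix(tips, "nt")
  dp <- as.matrix(supermatrix_dist(sm, "p"))
  dj <- as.matrix(supermatrix_dist(sm, "jc"))
  off <- upper.tri(dp)
  ## JC correction always inflates a nonzero p-distance
  expect_true(all(dj[off] >= dp[off]))
  expect_equal(dj[off], -0.75 * log(1 - dp[off] / 0.75))
})
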