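test_that("generation is deterministic in the seed, down to FASTA bytes", {
  a <- generate_genome(genome_spec(seed = 5))
  b <- generate_genome(genome_spec(seed = 5))
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)

  fa <- tempfile(); fb <- tempfile()
  write_fasta(a$genome, fa)
  write_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))

  c <- generate_genome(genome_spec(seed = 6))
  expect_false(identical(a$genome$sequence, c$genome$sequence))

  ## the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_genome(genome_spec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("generated genomes have the canonical layout and size arithmetic", {
  g <- default_genome()
  arch <- merulinid_architecture()
  expect_length(g$features, 18L)
  expect_equal(g$genome$length_bp,
               sum(arch$size_bp) + sum(arch$intergenic))
  expect_equal(gene_order_string(g$features), arch$gene)
  expect_true(all(vapply(g$features$features,
                         function(f) f$strand == "H", TRUE)))

  ## the ND5 intron span hosts ten PCGs and one rRNA
  ord <- gene_order_string(g$features)
  inside <- ord[(which(ord == "ND5-5prime") + 1):
                  (which(ord == "ND5-3prime") - 1)]
  types <- arch$ftype[match(inside, arch$gene)]
  expect_equal(sum(types == "PCG"), 10L)
  expect_equal(sum(types == "rRNA"), 1L)

  ## size overrides propagate
  g2 <- generate_genome(genome_spec(seed = 5, gene_sizes = c(COI = 1500L),
                                    intergenic = c(`tRNA-Met` = 700L)))
  s <- summarize_genes(g2$genome, g2$features)
  expect_equal(s$size_bp[s$gene == "COI"], 1500L)
  expect_equal(s$intergenic_bp[s$gene == "tRNA-Met"], 700L)

  expect_error(generate_genome(genome_spec(seed = 5,
                                           gene_sizes = c(COI = 1501L))),
               "divisible by 3")
  expect_error(generate_genome(genome_spec(seed = 5,
                                           intergenic = c(COI = -5L))),
               "negative intergenic")
})

test_that("composition targeting stays within a point of the targets", {
  targets <- c(A = 25.2, T = 41.6, G = 20.3, C = 12.9)
  devs <- vapply(1:20, function(seed) {
    g <- generate_genome(genome_spec(seed = seed))
    p <- base_composition(g$genome$sequence)
    expect_lt(p$at_skew, 0)   # T-rich
    expect_gt(p$gc_skew, 0)   # G over C
    mean(abs(p$pct[names(targets)] - targets))
  }, 0)
  expect_lt(mean(devs), 1)
  expect_true(all(devs < 1))

  ## a PCG-region AT target is hit within half a point
  g <- generate_genome(genome_spec(
    seed = 4, target_pct = c(A = 25.0, T = 41.5, G = 20.4, C = 13.1)))
  pcg <- region_composition(g$genome, g$features, "PCG")
  expect_lt(abs(pcg$pct[["A"]] + pcg$pct[["T"]] - 66.5), 0.5)
})

test_that("generated genomes satisfy every downstream validator", {
  g <- default_genome()
  arch <- merulinid_architecture()

  ## GenBank round trip
  tf <- tempfile(fileext = ".gb")
  write_genbank(g$genome, g$features, tf)
  expect_identical(read_genbank(tf), g)

  ## every PCG translates cleanly with the published start/stop codons
  s <- summarize_genes(g$genome, g$features)
  for (i in which(arch$ftype == "PCG")) {
    row <- s[s$gene == arch$gene[i], ]
    expect_equal(row$start_codon, arch$start_codon[i], info = arch$gene[i])
    expect_equal(row$stop_codon, arch$stop_codon[i], info = arch$gene[i])
  }
  cds <- pcg_sequences(g$genome, g$features)
  for (nm in names(cds)) expect_no_error(translate(cds[[nm]]))
  expect_equal(detect_start_stop(cds[["COIII"]])$start, "GTG")
  expect_equal(detect_start_stop(cds[["ND2"]])$start, "ATA")
})

test_that("exact mutation sets are applied, inverted, and bounded", {
  g <- default_genome()
  cds <- pcg_sequences(g$genome, g$features)[["Cyt b"]]

  expect_identical(as.character(mutate_cds(cds, 0, 0, seed = 1)), cds)

  mut <- mutate_cds(cds, k_syn = 8, k_nonsyn = 3, seed = 2)
  rec <- attr(mut, "mutations")
  expect_equal(nrow(rec), 11L)
  expect_equal(sum(rec$synonymous), 8L)
  ## disjoint sites: one substitution per codon
  expect_false(anyDuplicated((rec$site - 1) %/% 3) > 0)
  ## the mutant still translates (no stops created)
  expect_no_error(translate(mut))

  ## invertibility by the complementary substitution set
  chars <- strsplit(as.character(mut), "")[[1]]
  chars[rec$site] <- rec$from
  expect_identical(paste(chars, collapse = ""), cds)

  ## more substitutions than codons cannot fit disjointly
  expect_error(mutate_cds("ATGAAATAA", 5, 5, seed = 1),
               "insufficient eligible sites")
})

test_that("tree evolution is seeded, rate-sensitive, and JC-consistent", {
  g <- default_genome()
  tree <- "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);"

  same <- evolve_on_tree(g, tree, rate = 0, seed = 1)
  for (t in names(same))
    expect_identical(same[[t]]$genome$sequence, g$genome$sequence)

  r1 <- evolve_on_tree(g, tree, rate = 1, seed = 8)
  r2 <- evolve_on_tree(g, tree, rate = 1, seed = 8)
  expect_identical(r1, r2)
  expect_error(evolve_on_tree(g, "((A:0.1,B", rate = 1, seed = 1),
               "malformed Newick")

  ## observed p-distance tracks the JC expectation and grows with length
  p_obs <- vapply(c(0.05, 0.15, 0.4), function(b) {
    tips <- evolve_on_tree(g, sprintf("(X:%f,Y:%f,Z:0.01);", b, b),
                           rate = 1, seed = 3)
    chars_x <- strsplit(tips$X$genome$sequence, "")[[1]]
    chars_y <- strsplit(tips$Y$genome$sequence, "")[[1]]
    mean(chars_x != chars_y)
  }, 0)
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 2 * c(0.05, 0.15, 0.4)))
  expect_true(all(diff(p_obs) > 0))
  ## within a few percent: start/stop codons are held invariant and
  ## stop-avoiding redraws slightly depress the observed distance
  expect_true(all(abs(p_obs - p_exp) / p_exp < 0.08))
})
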