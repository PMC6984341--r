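test_that("base composition handles symmetric, extreme, and degenerate input", {
  p <- base_composition("AATT")
  expect_equal(p$pct[["A"]], 50)
  expect_equal(p$pct[["T"]], 50)
  expect_equal(p$at_skew, 0)
  expect_true(is.na(p$gc_skew))

  expect_equal(base_composition("GGGG")$gc_skew, 1)
  expect_error(base_composition("NNNN"), "undefined")
  expect_error(base_composition(""), "non-empty")

  ## N excluded from numerator and denominator
  pn <- base_composition("AANNTT")
  expect_equal(pn$n_effective, 4L)
  expect_equal(pn$pct[["A"]], 50)
})

test_that("skews recomputed from published percentages match printed values", {
  ## rounding-consistent rows of the published scleractinian table
  s <- skew_from_percentages(25.3, 41.1, 20.2, 13.3)  # Favites pentagona
  expect_equal(round(s$at_skew, 3), -0.238)
  expect_equal(round(s$gc_skew, 3), 0.206)

  s <- skew_from_percentages(25.0, 41.2, 20.5, 13.3)  # Favites abdita
  expect_equal(round(s$at_skew, 3), -0.245)
  expect_equal(round(s$gc_skew, 3), 0.213)

  s <- skew_from_percentages(25.2, 41.6, 20.3, 12.9)  # Dipsastraea rotumana
  expect_equal(round(s$at_skew, 3), -0.246)

  ## balanced percentages give zero skews for any magnitudes
  for (x in c(1, 10, 33.3)) for (y in c(2, 25))
    expect_equal(unlist(skew_from_percentages(x, x, y, y)),
                 c(at_skew = 0, gc_skew = 0))
  expect_error(skew_from_percentages(-1, 1, 1, 1), "non-negative")
})

test_that("the published-table audit flags only third-decimal inconsistencies", {
  aud <- audit_skew_consistency()
  ## every disagreement between printed and recomputed skews is within the
  ## worst case induced by rounding both percentages to 1 decimal
  ## (|d skew| <= 2 * 0.05 * (x + y) / (x + y)^2 + rounding of the skew
  ## itself, under 0.004 for these magnitudes), i.e. attributable to the
  ## authors using unrounded counts
  expect_true(all(abs(aud$AT_skew_recomputed - aud$AT_skew) < 0.004))
  expect_true(all(abs(aud$GC_skew_recomputed - aud$GC_skew) < 0.004))
  ## and a majority of AT cells are exactly consistent
  expect_gt(sum(aud$AT_consistent), nrow(aud) / 2)
})

test_that("skew invariants hold on random sequences", {
  set.seed(21)
  for (k in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    p <- base_composition(seq)
    cnt <- oracle_counts(seq)
    expect_equal(unname(p$counts), as.vector(cnt))
    expect_true(p$at_skew >= -1 && p$at_skew <= 1)
    expect_true(p$gc_skew >= -1 && p$gc_skew <= 1)
    expect_equal(p$at_skew == 0, cnt[["A"]] == cnt[["T"]])

    ## reversal leaves composition invariant
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(base_composition(rev_seq)$counts, p$counts)

    ## complement swaps A<->T, G<->C, negating both skews
    comp <- chartr("ACGT", "TGCA", seq)
    pc <- base_composition(comp)
    expect_equal(pc$at_skew, -p$at_skew)
    expect_equal(pc$gc_skew, -p$gc_skew)

    ## percentage-based skews agree exactly with count-based skews
    s <- skew_from_percentages(p$pct[["A"]], p$pct[["T"]],
                               p$pct[["G"]], p$pct[["C"]])
    expect_equal(s$at_skew, p$at_skew)
    expect_equal(s$gc_skew, p$gc_skew)
  }
})

test_that("region classes partition the genome and pool without double counting", {
  g <- default_genome()
  whole <- region_composition(g$genome, g$features, "whole")
  expect_equal(whole$counts, base_composition(g$genome$sequence)$counts)

  classes <- c("PCG", "tRNA", "rRNA", "intergenic")
  counts <- lapply(classes, function(cl)
    region_composition(g$genome, g$features, cl)$counts)
  expect_equal(Reduce(`+`, counts), whole$counts)

  ## a class with one member equals that gene's own profile
  one <- feature_table(list(Filter(function(f) f$name == "COI",
                                   g$features$features)[[1]]),
                       g$genome$accession)
  expect_equal(region_composition(g$genome, one, "PCG")$counts,
               base_composition(extract_feature(
                 g$genome, one$features[[1]]))$counts)

  expect_error(region_composition(g$genome, one, "tRNA"), "tRNA")

  ## overlapping features: shared bases counted once within the class
  gov <- mito_genome(strrep("ACGT", 50))
  tab <- feature_table(list(gene_feature("ND1", "PCG", cbind(1L, 30L)),
                            gene_feature("ND2", "PCG", cbind(21L, 50L))))
  expect_equal(region_composition(gov, tab, "PCG")$n_effective, 50L)
})

test_that("codon-position pooling separates the three positions", {
  p <- codon_position_composition(list("ATGTAA"))
  expect_equal(p$pos1$counts[["A"]], 1L)
  expect_equal(p$pos1$counts[["T"]], 1L)
  expect_equal(p$pos3$counts[["G"]], 1L)
  expect_equal(p$pos3$counts[["A"]], 1L)

  expect_error(codon_position_composition(list()), "non-empty")
  expect_error(codon_position_composition(list(COI = "ATGT")), "COI")

  ## third positions biased toward T shift position-3 AT-skew below
  ## position-1 AT-skew
  gb <- generate_genome(genome_spec(seed = 31, pos3_t_bias = 3))
  cds <- pcg_sequences(gb$genome, gb$features)
  pp <- codon_position_composition(cds)
  expect_lt(pp$pos3$at_skew, pp$pos1$at_skew)
})
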