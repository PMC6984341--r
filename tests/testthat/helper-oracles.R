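## Independent brute-force oracles, written against Biostrings' genetic
## code directly (not the package's codon_table class) so they share no
## code path with the implementation they check.

ORACLE_CODE <- Biostrings::getGeneticCode("4")

oracle_aa <- function(codon) ORACLE_CODE[[codon]]

## Synonymous-site fraction of a codon: enumerate all 9 single-base
## mutants; mutants to stops are nonsynonymous.
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars
      mut[pos] <- b
      m <- paste(mut, collapse = "")
      if (oracle_aa(m) != "*" && oracle_aa(m) == oracle_aa(codon))
        syn <- syn + 1 / 3
    }
  }
  syn
}

## Pathway enumeration for one codon pair: recursive DFS over all
## orderings of the differing positions, each path classified step by
## step; paths through stop codons dropped (kept if none survive).
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  paths <- list()
  walk <- function(cur, remaining, sd, nd, hit_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd, hit_stop)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      nxt[pos] <- b[pos]
      to <- paste(nxt, collapse = "")
      from <- paste(cur, collapse = "")
      syn <- oracle_aa(from) == oracle_aa(to)
      walk(nxt, remaining[-k], sd + syn, nd + !syn,
           hit_stop || oracle_aa(to) == "*")
    }
  }
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) return(c(Sd = 0, Nd = 0))
  walk(a, diff_pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(Sd = mean(m[keep, 1]), Nd = mean(m[keep, 2]))
}

## Whole-CDS oracle for (S, N, Sd, Nd).
oracle_ng_counts <- function(cds1, cds2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  cod1 <- split3(cds1)
  cod2 <- split3(cds2)
  S <- (sum(vapply(cod1, oracle_syn_sites, 0)) +
        sum(vapply(cod2, oracle_syn_sites, 0))) / 2
  d <- rowSums(vapply(seq_along(cod1), function(i)
    oracle_pair_diffs(cod1[i], cod2[i]), c(Sd = 0, Nd = 0)))
  list(S = S, N = 3 * length(cod1) - S, Sd = d[["Sd"]], Nd = d[["Nd"]])
}

## Random stop-free CDS (no start/stop conventions; raw codon soup).
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  codons <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

## Brute-force base counting, independent of base_composition.
oracle_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  table(factor(chars[chars != "N"], levels = c("A", "C", "G", "T")))
}

## Shared fixtures: the default synthetic genome is used across files.
default_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(genome_spec(seed = 101))
    cache
  }
})
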