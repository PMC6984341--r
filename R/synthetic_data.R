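## Seeded synthetic mitogenomes with scleractinian architecture, plus
## controlled sequence-evolution scenarios (exact mutation counts, and
## Jukes-Cantor evolution along a tree) for end-to-end pipeline testing.
##
## Composition targeting: free codons of the protein-coding genes are
## drawn by quota (largest-remainder) sampling from the stop-excluded
## codon distribution whose per-base marginals are calibrated by fixed
## point to the target percentages; non-coding bases are quota-sampled
## from the targets directly. The achieved composition therefore deviates
## from the targets only by integer rounding and the handful of forced
## start/stop codons — approximate targeting with deterministic accuracy.

DEFAULT_TARGET_PCT <- c(A = 25.2, T = 41.6, G = 20.3, C = 12.9)

#' Specification for a synthetic mitogenome
#'
#' @param seed Integer seed; all randomness of [generate_genome()] flows
#'   from it.
#' @param gene_sizes Named integer vector overriding default gene sizes
#'   (bp); PCG sizes must be divisible by 3.
#' @param intergenic Named integer vector overriding default spacer sizes
#'   after each gene; must be non-negative (the generator lays genes out
#'   without overlaps).
#' @param target_pct Named percentages for A, T, G, C; must sum to 100.
#'   Defaults to the T-rich, A-second composition typical of merulinid
#'   mitogenomes (negative AT-skew, positive GC-skew).
#' @param code_table Genetic-code id (default 4, coelenterate
#'   mitochondrial).
#' @param pos3_t_bias Multiplier (default 1 = off) applied to the weight
#'   of T at third codon positions, to emulate the stronger third-position
#'   bias of real coding sequence.
#' @param accession,organism Identifiers for the generated record.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(seed, gene_sizes = NULL, intergenic = NULL,
                        target_pct = DEFAULT_TARGET_PCT, code_table = 4,
                        pos3_t_bias = 1, accession = NULL,
                        organism = "synthetic merulinid coral") {
  target_pct <- target_pct[c("A", "T", "G", "C")]
  if (anyNA(target_pct) || abs(sum(target_pct) - 100) > 1e-6)
    stop("target_pct must name A, T, G, C and sum to 100")
  structure(list(seed = as.integer(seed), gene_sizes = gene_sizes,
                 intergenic = intergenic, target_pct = target_pct,
                 code_table = code_table, pos3_t_bias = pos3_t_bias,
                 accession = accession %||% sprintf("SYN%06d", seed %% 1000000L),
                 organism = organism),
            class = "genome_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Fixed-point calibration: find per-position base weights whose
## stop-excluded codon distribution has average per-base marginal equal to
## the target probabilities. Returns the 62 non-stop codon weights.
calibrate_codon_weights <- function(target_probs, table, pos3_t_bias = 1,
                                    iterations = 60) {
  codons <- names(unclass(table))
  stops <- stop_codons(table)
  keep <- !(codons %in% stops)
  c1 <- substr(codons, 1, 1); c2 <- substr(codons, 2, 2)
  c3 <- substr(codons, 3, 3)
  q <- target_probs / sum(target_probs)
  bias <- setNames(rep(1, 4), BASES)
  bias[["T"]] <- pos3_t_bias
  for (it in seq_len(iterations)) {
    q3 <- q * bias; q3 <- q3 / sum(q3)
    w <- q[c1] * q[c2] * q3[c3]
    w[!keep] <- 0
    w <- w / sum(w)
    marg <- vapply(BASES, function(b)
      sum(w * ((c1 == b) + (c2 == b) + (c3 == b)) / 3), 0)
    tgt <- target_probs / sum(target_probs)
    q <- q * tgt[names(q)] / pmax(marg[names(q)], 1e-12)
    q <- q / sum(q)
  }
  q3 <- q * bias; q3 <- q3 / sum(q3)
  w <- q[c1] * q[c2] * q3[c3]
  w[!keep] <- 0
  setNames(w / sum(w), codons)[keep]
}

#' Generate a synthetic annotated mitogenome
#'
#' Produces a circular genome with the canonical merulinid gene order
#' (origin at the first base of tRNA-Met), every protein-coding gene
#' starting with its canonical initiation codon (ATG; GTG for COIII, ATA
#' for ND2), ending TAA/TAG and free of internal stops under the
#' coelenterate mitochondrial code, ND5 emitted as 5' and 3' exon
#' features separated by the gene-rich intron span, and whole-genome base
#' composition within one percentage point of the targets. Fully
#' reproducible from the seed.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` ([mito_genome()]) and `features`
#'   ([feature_table()]).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  for (attempt in 0:4) {
    out <- with_local_seed(spec$seed + attempt * 1000003L,
                           build_genome_once(spec))
    achieved <- base_composition(out$genome$sequence)$pct[names(spec$target_pct)]
    if (max(abs(achieved - spec$target_pct)) <= 1) return(out)
  }
  stop("infeasible composition targets: deviation above 1 percentage ",
       "point after bounded resampling")
}

build_genome_once <- function(spec) {
  arch <- merulinid_architecture()
  if (!is.null(spec$gene_sizes)) {
    idx <- match(names(spec$gene_sizes), arch$gene)
    if (anyNA(idx)) stop("unknown gene in gene_sizes: ",
                         paste(names(spec$gene_sizes)[is.na(idx)], collapse = ", "))
    arch$size_bp[idx] <- as.integer(spec$gene_sizes)
  }
  if (!is.null(spec$intergenic)) {
    idx <- match(names(spec$intergenic), arch$gene)
    if (anyNA(idx)) stop("unknown gene in intergenic: ",
                         paste(names(spec$intergenic)[is.na(idx)], collapse = ", "))
    arch$intergenic[idx] <- as.integer(spec$intergenic)
  }
  if (any(arch$intergenic < 0))
    stop("negative intergenic spacers are not supported by the generator")
  pcg <- arch$ftype == "PCG"
  if (any(arch$size_bp[pcg] %% 3L != 0L))
    stop("PCG sizes must be divisible by 3")

  code <- codon_table(spec$code_table)
  p <- spec$target_pct / sum(spec$target_pct)

  ## free (unforced) codon budget: ND5 exons form one joined CDS with one
  ## start and one stop; every other PCG has its own start and stop
  nd5_rows <- arch$gene %in% c("ND5-5prime", "ND5-3prime")
  other <- pcg & !nd5_rows
  free_per_gene <- setNames(integer(nrow(arch)), arch$gene)
  free_per_gene[other] <- arch$size_bp[other] %/% 3L - 2L
  nd5_total_codons <- sum(arch$size_bp[nd5_rows]) %/% 3L
  nd5_free <- nd5_total_codons - 2L
  total_free <- sum(free_per_gene[other]) + nd5_free

  w <- calibrate_codon_weights(p, code, spec$pos3_t_bias)
  pool <- sample(rep(names(w), quota_counts(w, total_free)))

  ## non-coding base budget (tRNA + rRNA + intergenic)
  nc_len <- sum(arch$size_bp[!pcg]) + sum(arch$intergenic)
  nc_pool <- sample(rep(names(p), quota_counts(p, nc_len)))

  take_codons <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  take_bases <- function(n) {
    if (n == 0) return("")
    out <- nc_pool[seq_len(n)]
    nc_pool <<- nc_pool[-seq_len(n)]
    paste(out, collapse = "")
  }

  ## pre-build the joined ND5 CDS, then split it at the 5' exon boundary
  nd5_start <- arch$start_codon[arch$gene == "ND5-5prime"]
  nd5_stop <- arch$stop_codon[arch$gene == "ND5-3prime"]
  nd5_cds <- paste(c(nd5_start, take_codons(nd5_free), nd5_stop),
                   collapse = "")
  nd5_5len <- arch$size_bp[arch$gene == "ND5-5prime"]
  nd5_parts <- c("ND5-5prime" = substr(nd5_cds, 1, nd5_5len),
                 "ND5-3prime" = substr(nd5_cds, nd5_5len + 1,
                                       nchar(nd5_cds)))

  pieces <- character(0)
  feats <- list()
  pos <- 1L
  for (i in seq_len(nrow(arch))) {
    g <- arch$gene[i]
    size <- arch$size_bp[i]
    seq_i <- if (g %in% names(nd5_parts)) {
      nd5_parts[[g]]
    } else if (arch$ftype[i] == "PCG") {
      paste(c(arch$start_codon[i], take_codons(free_per_gene[[g]]),
              arch$stop_codon[i]), collapse = "")
    } else {
      take_bases(size)
    }
    stopifnot(nchar(seq_i) == size)
    feats[[length(feats) + 1]] <-
      gene_feature(g, arch$ftype[i], cbind(pos, pos + size - 1L))
    pieces <- c(pieces, seq_i, take_bases(arch$intergenic[i]))
    pos <- pos + size + arch$intergenic[i]
  }
  genome <- mito_genome(paste(pieces, collapse = ""),
                        accession = spec$accession,
                        organism = spec$organism, is_circular = TRUE)
  list(genome = genome,
       features = feature_table(feats, genome_ref = spec$accession))
}

#' Apply exact counts of synonymous and nonsynonymous substitutions
#'
#' Introduces exactly `k_syn` synonymous and `k_nonsyn` nonsynonymous
#' single-base substitutions into a coding sequence, never creating a
#' stop codon and never touching a terminal stop. With
#' `disjoint_sites = TRUE` at most one substitution lands in any codon, so
#' a Nei-Gojobori recount of (original, mutant) recovers `Sd = k_syn` and
#' `Nd = k_nonsyn` exactly.
#'
#' @param cds In-frame coding sequence (a terminal stop is preserved
#'   untouched).
#' @param k_syn,k_nonsyn Numbers of substitutions to apply.
#' @param disjoint_sites One substitution per codon at most (default
#'   `TRUE`).
#' @param seed Integer seed.
#' @param table A [codon_table()].
#' @return Mutated CDS with attribute `mutations`: data.frame of `site`
#'   (1-based position in the CDS), `from`, `to`, `synonymous`. Applying
#'   the reverse substitutions restores the input exactly.
#' @export
mutate_cds <- function(cds, k_syn, k_nonsyn, disjoint_sites = TRUE,
                       seed = 1L, table = codon_table()) {
  with_local_seed(seed, {
    cod <- codons_of(cds)
    aa_of <- unclass(table)
    n <- length(cod)
    mutable <- seq_len(n)
    if (n > 0 && is_stop(cod[n], table)) mutable <- mutable[-n]
    if (any(vapply(cod[mutable], is_stop, TRUE, table = table)))
      stop("internal stop codon; not a valid CDS")

    need <- sample(c(rep(TRUE, k_syn), rep(FALSE, k_nonsyn)))
    used <- logical(n)
    log <- vector("list", length(need))
    for (m in seq_along(need)) {
      want_syn <- need[m]
      cand <- list()
      for (i in mutable) {
        if (disjoint_sites && used[i]) next
        chars <- seq_chars(cod[i])
        for (pos in 1:3) for (b in setdiff(BASES, chars[pos])) {
          mut <- chars; mut[pos] <- b
          mutc <- paste(mut, collapse = "")
          if (aa_of[mutc] == "*") next
          if ((aa_of[mutc] == aa_of[cod[i]]) == want_syn)
            cand[[length(cand) + 1]] <- c(i, pos, match(b, BASES))
        }
      }
      if (length(cand) == 0)
        stop("insufficient eligible sites for ",
             if (want_syn) "synonymous" else "nonsynonymous",
             " substitution ", m)
      pick <- cand[[sample.int(length(cand), 1)]]
      i <- pick[1]; pos <- pick[2]; b <- BASES[pick[3]]
      chars <- seq_chars(cod[i])
      log[[m]] <- data.frame(site = 3L * (i - 1L) + pos,
                             from = chars[pos], to = b,
                             synonymous = want_syn,
                             stringsAsFactors = FALSE)
      chars[pos] <- b
      cod[i] <- paste(chars, collapse = "")
      used[i] <- TRUE
    }
    out <- paste(cod, collapse = "")
    attr(out, "mutations") <- if (length(log)) do.call(rbind, log) else
      data.frame(site = integer(0), from = character(0),
                 to = character(0), synonymous = logical(0))
    out
  })
}

#' Evolve a genome along a phylogeny under Jukes-Cantor substitution
#'
#' Simulates substitutions along every branch of a tree (branch lengths in
#' expected substitutions per site, multiplied by `rate`), CDS-aware:
#' start and terminal stop codons are held invariant, and a substitution
#' that would create an internal stop is redrawn (or dropped if no
#' non-stop alternative exists). Tips inherit the ancestral annotation.
#'
#' @param g `list(genome =, features =)` as from [generate_genome()].
#' @param tree An [ape::phylo] object or Newick string.
#' @param rate Multiplier on branch lengths (substitutions/site); `rate 0`
#'   returns identical tips.
#' @param seed Integer seed.
#' @param table A [codon_table()].
#' @return Named list (by tip label) of `list(genome =, features =)`.
#' @export
evolve_on_tree <- function(g, tree, rate = 1, seed = 1L,
                           table = codon_table()) {
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tree)) stop("malformed Newick tree")
  }
  if (!inherits(tree, "phylo")) stop("malformed Newick tree")
  if (rate < 0) stop("rate must be non-negative")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")

  ## coding-position index: genome position -> (gene id, codon slot)
  pcgs <- Filter(function(f) f$ftype == "PCG", g$features$features)
  L <- g$genome$length_bp
  cds_pos <- lapply(pcgs, function(f)
    unlist(apply(f$segments, 1, function(s)
      circular_positions(s[1], s[2], L), simplify = FALSE)))
  names(cds_pos) <- vapply(pcgs, `[[`, "", "name")
  if (all(c("ND5-5prime", "ND5-3prime") %in% names(cds_pos))) {
    cds_pos[["ND5-5prime"]] <- c(cds_pos[["ND5-5prime"]],
                                 cds_pos[["ND5-3prime"]])
    cds_pos[["ND5-3prime"]] <- NULL
  }
  ## invariant positions: first and last codon of each (joined) CDS
  invariant <- unlist(lapply(cds_pos, function(p)
    c(head(p, 3), tail(p, 3))))
  pos_gene <- integer(L)          # 0 = non-coding
  pos_frame <- integer(L)
  for (k in seq_along(cds_pos)) {
    p <- cds_pos[[k]]
    pos_gene[p] <- k
    pos_frame[p] <- seq_along(p)
  }

  aa_of <- unclass(table)
  with_local_seed(seed, {
    ntip <- length(tree$tip.label)
    seqs <- vector("list", ntip + tree$Nnode)
    root <- ntip + 1L
    seqs[[root]] <- seq_chars(g$genome$sequence)
    tr <- ape::reorder.phylo(tree, "cladewise")
    edges <- tr$edge
    lens <- tr$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      chars <- seqs[[parent]]
      d <- lens[e] * rate
      p_sub <- 3 / 4 * (1 - exp(-4 / 3 * d))
      if (p_sub > 0) {
        hits <- which(stats::runif(L) < p_sub)
        hits <- setdiff(hits, invariant)
        for (h in hits) {
          alts <- setdiff(BASES, chars[h])
          pick <- alts[sample.int(3, 1)]
          if (pos_gene[h] > 0) {
            slot <- pos_frame[h]
            gene_p <- cds_pos[[pos_gene[h]]]
            cstart <- slot - (slot - 1) %% 3
            cpos <- gene_p[cstart:(cstart + 2)]
            trial <- chars[cpos]
            ok <- character(0)
            for (a in alts) {
              trial[(slot - 1) %% 3 + 1] <- a
              if (aa_of[paste(trial, collapse = "")] != "*")
                ok <- c(ok, a)
            }
            if (length(ok) == 0) next
            pick <- ok[sample.int(length(ok), 1)]
          }
          chars[h] <- pick
        }
      }
      seqs[[child]] <- chars
    }
    tips <- setNames(vector("list", ntip), tree$tip.label)
    for (t in seq_len(ntip)) {
      genome <- mito_genome(paste(seqs[[t]], collapse = ""),
                            accession = tree$tip.label[t],
                            organism = tree$tip.label[t],
                            is_circular = TRUE)
      tips[[t]] <- list(genome = genome,
                        features = feature_table(g$features$features,
                                                 genome_ref = genome$accession))
    }
    tips
  })
}
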