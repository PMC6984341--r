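## Nei-Gojobori (1986) counting estimator of synonymous (Ks) and
## nonsynonymous (Ka) substitution rates, with Jukes-Cantor correction.
##
## Sites: each codon position contributes the fraction of its three
## possible single-base changes that are synonymous (changes creating a
## stop codon count as nonsynonymous); S is the sum of those fractions and
## N = 3 * n_codons - S. Differences: codons differing at one position are
## classified directly; at two or three positions, every mutational
## pathway (ordering of the single-base steps) is enumerated, each step
## classified, and the counts averaged over pathways. Pathways passing
## through a stop codon are excluded and the remainder reweighted (if all
## pass through stops, all are kept). Proportions pS = Sd/S and pN = Nd/N
## are corrected as K = -(3/4) ln(1 - (4/3) p).

## Synonymous-site fraction of one codon (0 for none, up to 3).
codon_syn_sites <- function(codon, table) {
  aa_of <- unclass(table)
  if (aa_of[codon] == "*")
    stop("stop codon ", codon, " has no defined site counts")
  chars <- seq_chars(codon)
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (aa_of[mutc] != "*" && aa_of[mutc] == aa_of[codon])
        syn <- syn + 1 / 3
    }
  }
  syn
}

#' Count synonymous and nonsynonymous sites of a coding sequence
#'
#' @param cds In-frame coding sequence without stop codons (remove the
#'   terminal stop first); a stop codon anywhere is an error.
#' @param table A [codon_table()].
#' @return List with `S` (synonymous sites) and `N` (nonsynonymous sites);
#'   `S + N = 3 * n_codons` exactly.
#' @export
count_sites <- function(cds, table = codon_table()) {
  cod <- codons_of(cds)
  stops <- which(vapply(cod, is_stop, TRUE, table = table))
  if (length(stops) > 0)
    stop("stop codon ", cod[stops[1]], " at codon index ", stops[1],
         "; remove stops before site counting")
  fractions <- vapply(unique(cod), codon_syn_sites, 0, table = table)
  S <- sum(fractions[cod])
  list(S = S, N = 3 * length(cod) - S)
}

## Pathway-averaged (Sd, Nd) for one codon pair.
codon_pair_diffs <- function(c1, c2, table) {
  aa_of <- unclass(table)
  a <- seq_chars(c1)
  b <- seq_chars(c2)
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0) return(c(Sd = 0, Nd = 0))
  if (nd == 1) {
    syn <- aa_of[c1] == aa_of[c2]
    return(c(Sd = as.numeric(syn), Nd = as.numeric(!syn)))
  }
  orders <- perms(diff_pos)
  path_counts <- matrix(NA_real_, nrow = nrow(orders), ncol = 2)
  through_stop <- logical(nrow(orders))
  for (i in seq_len(nrow(orders))) {
    cur <- a
    sd <- 0; ndn <- 0
    for (pos in orders[i, ]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (aa_of[to] == "*") through_stop[i] <- TRUE
      if (aa_of[from] == aa_of[to]) sd <- sd + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    path_counts[i, ] <- c(sd, ndn)
  }
  keep <- !through_stop
  if (!any(keep)) keep <- rep(TRUE, length(keep))  # all saturated: keep all
  avg <- colMeans(path_counts[keep, , drop = FALSE])
  c(Sd = avg[1], Nd = avg[2])
}

## All permutations of a small vector (n <= 3 here).
perms <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- perms(x[-i])
    cbind(x[i], sub)
  }))
  out
}

#' Count synonymous and nonsynonymous differences between two CDS
#'
#' @param cds1,cds2 In-frame coding sequences of equal length, stop codons
#'   removed.
#' @param table A [codon_table()].
#' @return List with `Sd` and `Nd`; for each codon pair `Sd + Nd` equals
#'   the number of differing positions.
#' @export
count_differences <- function(cds1, cds2, table = codon_table()) {
  if (nchar(cds1) != nchar(cds2))
    stop("sequence length mismatch: ", nchar(cds1), " vs ", nchar(cds2),
         " (align externally; ungapped comparison only)")
  cod1 <- codons_of(cds1)
  cod2 <- codons_of(cds2)
  for (cod in list(cod1, cod2)) {
    stops <- which(vapply(cod, is_stop, TRUE, table = table))
    if (length(stops) > 0)
      stop("stop codon at codon index ", stops[1],
           "; remove stops before analysis")
  }
  totals <- c(Sd = 0, Nd = 0)
  for (i in seq_along(cod1)) {
    if (cod1[i] != cod2[i])
      totals <- totals + codon_pair_diffs(cod1[i], cod2[i], table)
  }
  list(Sd = unname(totals["Sd"]), Nd = unname(totals["Nd"]))
}

jc_correct <- function(p) {
  if (is.na(p)) return(list(K = NA_real_, saturated = FALSE))
  if (p >= 3 / 4) return(list(K = NA_real_, saturated = TRUE))
  list(K = -3 / 4 * log(1 - 4 / 3 * p), saturated = FALSE)
}

#' Nei-Gojobori Ka/Ks for a pair of coding sequences
#'
#' Terminal stop codons are stripped before analysis. Site counts are
#' averaged over the two sequences. The ratio is reported only when
#' `Ks > 0`; a proportion at or past the Jukes-Cantor saturation bound
#' (3/4) flags the corresponding rate as saturated and leaves it `NA`.
#'
#' @param cds1,cds2 In-frame coding sequences of equal length (a mismatch
#'   is an error, not an alignment trigger).
#' @param table A [codon_table()].
#' @return A `kaks_result`: list with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `ratio` (`NA` when undefined) and a `flags` character
#'   vector (`"saturated_Ks"`, `"saturated_Ka"`, `"undefined_ratio"`).
#' @export
ng86 <- function(cds1, cds2, table = codon_table()) {
  strip <- function(cds) {
    cod <- codons_of(cds)
    if (length(cod) > 0 && is_stop(cod[length(cod)], table))
      cod <- cod[-length(cod)]
    paste(cod, collapse = "")
  }
  cds1 <- strip(cds1); cds2 <- strip(cds2)
  if (nchar(cds1) != nchar(cds2))
    stop("sequence length mismatch after stop removal: ",
         nchar(cds1), " vs ", nchar(cds2))
  s1 <- count_sites(cds1, table)
  s2 <- count_sites(cds2, table)
  S <- (s1$S + s2$S) / 2
  N <- (s1$N + s2$N) / 2
  d <- count_differences(cds1, cds2, table)
  pS <- if (S > 0) d$Sd / S else NA_real_
  pN <- if (N > 0) d$Nd / N else NA_real_
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  flags <- character(0)
  if (ks$saturated) flags <- c(flags, "saturated_Ks")
  if (ka$saturated) flags <- c(flags, "saturated_Ka")
  ratio <- NA_real_
  if (!is.na(ks$K) && ks$K > 0 && !is.na(ka$K)) {
    ratio <- ka$K / ks$K
  } else {
    flags <- c(flags, "undefined_ratio")
  }
  structure(list(S = S, N = N, Sd = d$Sd, Nd = d$Nd, pS = pS, pN = pN,
                 Ks = ks$K, Ka = ka$K, ratio = ratio, flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s Ka/Ks=%s%s\n",
    x$S, x$N, x$Sd, x$Nd,
    if (is.na(x$Ka)) "NA" else sprintf("%.4f", x$Ka),
    if (is.na(x$Ks)) "NA" else sprintf("%.4f", x$Ks),
    if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Per-gene Ka/Ks table for a pair of annotated genomes
#'
#' Runs [ng86()] on each of the 13 protein-coding genes (ND5 joined from
#' its exon segments) shared by two genomes.
#'
#' @param ga,gb `list(genome =, features =)` pairs.
#' @param table A [codon_table()].
#' @return data.frame with columns `gene`, `S`, `N`, `Sd`, `Nd`, `Ka`,
#'   `Ks`, `ratio`.
#' @export
kaks_table <- function(ga, gb, table = codon_table()) {
  ca <- pcg_sequences(ga$genome, ga$features)
  cb <- pcg_sequences(gb$genome, gb$features)
  genes <- intersect(names(ca), names(cb))
  rows <- lapply(genes, function(g) {
    r <- ng86(ca[[g]], cb[[g]], table)
    data.frame(gene = g, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
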