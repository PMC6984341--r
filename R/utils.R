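#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils head tail write.table
NULL

BASES <- c("A", "C", "G", "T")

## Round half away from zero, the convention used by the published tables.
## base::round() rounds half to even, which disagrees on .5 ties.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate expr with a temporary RNG state seeded from `seed`, restoring
## the caller's state afterwards. All package randomness flows through this.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Split a nucleotide string into single characters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

## Split an in-frame coding sequence into codons.
codons_of <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("coding sequence length ", n, " is not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

## Largest-remainder integerization of expected counts summing to `total`.
quota_counts <- function(weights, total) {
  w <- weights / sum(weights)
  exact <- w * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

is_nucleotide_string <- function(seq) {
  nzchar(seq) && !grepl("[^ACGTN]", seq)
}
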