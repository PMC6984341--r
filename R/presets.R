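## Canonical scleractinian (merulinid-type) mitogenome architecture and
## published composition summaries, used as generator defaults and as
## printed-table inputs for desk-scale validation.

#' Canonical merulinid mitogenome architecture
#'
#' The gene complement and arrangement shared by merulinid corals: 13
#' protein-coding genes, two tRNAs and two rRNAs, all on the H strand, in
#' circle order starting at tRNA-Met, with ND5 split into 5' and 3' exons
#' by a group-I-type intron whose span hosts ten PCGs and one rRNA. Sizes
#' and start/stop codons are the published per-gene values;
#' `intergenic_lo`/`intergenic_hi` give the published spacer range to the
#' next gene on the circle (negative = overlap) and `intergenic` the
#' generator's default single value (range midpoint, clipped at zero
#' because the generator lays genes out without overlaps).
#'
#' @return data.frame with columns `gene`, `ftype`, `size_bp`,
#'   `start_codon`, `stop_codon`, `intergenic`, `intergenic_lo`,
#'   `intergenic_hi`, in circle order.
#' @export
merulinid_architecture <- function() {
  df <- data.frame(
    gene = c("tRNA-Met", "16S rRNA", "ND5-5prime", "ND1", "Cyt b", "ND2",
             "ND6", "ATP6", "ND4", "12S rRNA", "COIII", "COII", "ND4L",
             "ND3", "ND5-3prime", "tRNA-Trp", "ATP8", "COI"),
    ftype = c("tRNA", "rRNA", "PCG", "PCG", "PCG", "PCG", "PCG", "PCG",
              "PCG", "rRNA", "PCG", "PCG", "PCG", "PCG", "PCG", "tRNA",
              "PCG", "PCG"),
    size_bp = c(72L, 1698L, 711L, 948L, 1140L, 1287L, 561L, 678L, 1440L,
                911L, 780L, 708L, 300L, 342L, 1104L, 71L, 198L, 1590L),
    start_codon = c(NA, NA, "ATG", "ATG", "ATG", "ATA", "ATG", "ATG",
                    "ATG", NA, "GTG", "ATG", "ATG", "ATG", NA, NA, "ATG",
                    "ATG"),
    stop_codon = c(NA, NA, NA, "TAG", "TAA", "TAA", "TAA", "TAA", "TAG",
                   NA, "TAA", "TAA", "TAA", "TAA", "TAG", NA, "TAA",
                   "TAA"),
    intergenic_lo = c(674L, 0L, 0L, 109L, 2L, 25L, 1L, -1L, -1L, 108L,
                      67L, 626L, -19L, 2L, 56L, -2L, 3L, -1L),
    intergenic_hi = c(1448L, 193L, 49L, 110L, 2L, 25L, 1L, -1L, -1L,
                      138L, 125L, 713L, -19L, 2L, 56L, -2L, 3L, 724L),
    stringsAsFactors = FALSE)
  df$intergenic <- pmax(0L, as.integer(round((df$intergenic_lo +
                                              df$intergenic_hi) / 2)))
  df
}

#' Published composition summaries for 14 scleractinian mitogenomes
#'
#' Whole-genome base percentages and skews, and concatenated 13-PCG
#' product length (aa), AT% and skews, as printed in published summaries
#' of the listed GenBank accessions. Useful as a desk-scale input for
#' validating the skew formulas against printed (rounded) percentages.
#'
#' @return data.frame, one row per species.
#' @export
scleractinia_composition <- function() {
  data.frame(
    species = c("Astrangia poculata", "Colpophyllia natans",
                "Cyphastrea serailia", "Echinophyllia aspera",
                "Favites abdita", "Favites pentagona",
                "Dipsastraea rotumana", "Hydnophora exesa",
                "Mussa angulosa", "Orbicella annularis",
                "Orbicella faveolata", "Orbicella franksi",
                "Platygyra carnosa", "Sclerophyllia maxima"),
    accession = c("NC_008161", "NC_008162", "KY094484", "MG792550",
                  "NC_035879", "KY247139", "MH119077", "MH086217",
                  "NC_008163", "NC_007224", "NC_007226", "NC_007225",
                  "NC_020049", "FO904931"),
    length_bp = c(14853L, 16906L, 17138L, 17697L, 17825L, 18006L, 16466L,
                  17790L, 17245L, 16138L, 16138L, 16137L, 16463L, 18168L),
    A_pct = c(25.2, 24.9, 25.0, 25.3, 25.0, 25.3, 25.2, 25.0, 25.1, 24.9,
              24.9, 24.9, 25.6, 25.3),
    T_pct = c(42.9, 41.5, 41.4, 40.6, 41.2, 41.1, 41.6, 41.7, 41.2, 41.5,
              41.5, 41.5, 41.4, 41.0),
    C_pct = c(12.2, 13.2, 13.0, 13.4, 13.3, 13.3, 12.9, 13.0, 13.4, 13.1,
              13.2, 13.2, 12.8, 13.1),
    G_pct = c(19.7, 20.3, 20.5, 20.7, 20.5, 20.2, 20.3, 20.4, 20.3, 20.4,
              20.4, 20.4, 20.1, 20.6),
    AT_skew = c(-0.259, -0.250, -0.247, -0.231, -0.245, -0.238, -0.246,
                -0.251, -0.242, -0.251, -0.250, -0.250, -0.236, -0.237),
    GC_skew = c(0.233, 0.211, 0.225, 0.212, 0.213, 0.206, 0.221, 0.224,
                0.203, 0.217, 0.217, 0.215, 0.222, 0.221),
    pcg_aa = c(3837L, 3847L, 3916L, 3943L, 3837L, 3915L, 3915L, 3915L,
               3850L, 3912L, 3912L, 3912L, 3916L, 3943L),
    pcg_AT_pct = c(68.039, 67.040, 66.735, 66.044, 66.562, 66.502, 66.769,
                   66.863, 66.814, 66.385, 66.377, 66.402, 66.658, 66.863),
    pcg_AT_skew = c(-0.345, -0.351, -0.350, -0.349, -0.349, -0.349,
                    -0.351, -0.350, -0.349, -0.352, -0.352, -0.351,
                    -0.349, -0.354),
    pcg_GC_skew = c(0.231, 0.224, 0.219, 0.211, 0.217, 0.216, 0.223,
                    0.223, 0.220, 0.220, 0.220, 0.219, 0.221, 0.231),
    stringsAsFactors = FALSE)
}

#' Audit a printed composition table for skew rounding consistency
#'
#' Recomputes each row's skews from its printed (rounded) percentages and
#' compares with the printed skews at 3 decimals. Rows computed from
#' unrounded counts can disagree in the third decimal; only
#' rounding-consistent cells are meaningful desk-scale checks.
#'
#' @param tab data.frame in the layout of [scleractinia_composition()].
#' @return `tab` with added columns `AT_skew_recomputed`,
#'   `GC_skew_recomputed`, `AT_consistent`, `GC_consistent`.
#' @export
audit_skew_consistency <- function(tab = scleractinia_composition()) {
  rec <- t(vapply(seq_len(nrow(tab)), function(i) {
    s <- skew_from_percentages(tab$A_pct[i], tab$T_pct[i],
                               tab$G_pct[i], tab$C_pct[i])
    c(round_half_up(s$at_skew, 3), round_half_up(s$gc_skew, 3))
  }, c(0, 0)))
  tab$AT_skew_recomputed <- rec[, 1]
  tab$GC_skew_recomputed <- rec[, 2]
  tab$AT_consistent <- tab$AT_skew_recomputed == tab$AT_skew
  tab$GC_consistent <- tab$GC_skew_recomputed == tab$GC_skew
  tab
}
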