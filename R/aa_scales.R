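# Amino-acid alphabets, grouping schemes and physico-chemical scales.

#' The twenty standard amino-acid letters
#'
#' One-letter codes in alphabetical order. This is the alphabet every
#' composition, logo and background table in the package is indexed by;
#' `X` (unknown residue) and `-` (alignment gap) are handled by the callers
#' and never appear here.
#'
#' @format Character vector of length 20.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy index.
.KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Display ordering by interfacial side-chain transfer free energy
# (Wimley-White), most interface-seeking first. Presentation only:
# no statistic is computed from it.
.DG_ORDER <- c("W", "F", "Y", "L", "I", "C", "M", "G", "V", "S",
               "T", "A", "H", "N", "P", "Q", "R", "K", "D", "E")

#' Amino-acid grouping schemes and hydropathy scale
#'
#' Returns the residue groupings used throughout the composition analyses:
#' a seven-member hydrophobic set (Tyr, Ile, Leu, Met, Phe, Cys, Trp) and a
#' thirteen-member hydrophilic set containing the remainder (including Val),
#' positively charged residues (Arg, His, Lys), negatively charged residues
#' (Asp, Glu), the Kyte-Doolittle hydropathy index, a display ordering of the
#' letters by interfacial side-chain transfer free energy, and the set of
#' snorkeling-capable residues used for annotation.
#'
#' Note that His is a member of both the hydrophilic and the positive set, so
#' the charged-group totals are not a sub-partition of the hydrophilic total.
#' `conventional = TRUE` swaps in the textbook hydropathy partition (positive
#' Kyte-Doolittle residues hydrophobic, the rest hydrophilic) for sensitivity
#' analyses; the default grouping is the one the regional ratio analyses are
#' defined on.
#'
#' @param conventional Logical; use the Kyte-Doolittle-sign partition instead
#'   of the default seven/thirteen grouping.
#' @param snorkeling Character vector of snorkeling-capable residues.
#' @return A list with elements `hydrophobic`, `hydrophilic`, `positive`,
#'   `negative`, `kd` (named numeric hydropathy values), `dg_order`, and
#'   `snorkeling`.
#' @examples
#' sc <- aa_scales()
#' length(sc$hydrophobic)  # 7
#' sc$kd[["I"]]            # 4.5
#' @export
aa_scales <- function(conventional = FALSE, snorkeling = c("K", "R", "W", "Y")) {
  if (conventional) {
    hydrophobic <- names(.KD_HYDROPATHY)[.KD_HYDROPATHY > 0]
  } else {
    hydrophobic <- c("Y", "I", "L", "M", "F", "C", "W")
  }
  hydrophilic <- setdiff(AA_LETTERS, hydrophobic)
  stopifnot(all(snorkeling %in% AA_LETTERS))
  list(
    hydrophobic = sort(hydrophobic),
    hydrophilic = sort(hydrophilic),
    positive    = c("R", "H", "K"),
    negative    = c("D", "E"),
    kd          = .KD_HYDROPATHY,
    dg_order    = .DG_ORDER,
    snorkeling  = sort(snorkeling)
  )
}
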