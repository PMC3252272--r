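#' Complementarity penalty parameters for duplex alignment
#'
#' Weights for the empirical plant miRNA-target complementarity score: each
#' mismatch costs `mismatch`, each G:U wobble `wobble`, each bulged (unpaired)
#' nucleotide `bulge_per_nt`, and a candidate window is reported as a target
#' site when its optimal alignment scores at most `max_score`.  By default,
#' alignments in which miRNA positions 10 and 11 (numbered from the miRNA 5'
#' end) are mismatched, bulged, or separated by a bulge are excluded: target
#' cleavage occurs opposite positions 10-11, so a site violating this cannot
#' be cleaved under the canonical model.
#'
#' @param mismatch Penalty per mismatched column. Default 1.
#' @param wobble Penalty per G:U wobble column. Default 0.5.
#' @param bulge_per_nt Penalty per bulged nucleotide. Default 1.
#' @param max_score Score cap for reporting target sites. Default 5.
#' @param require_paired_10_11 Require Watson-Crick or wobble pairing at
#'   miRNA positions 10 and 11 with no intervening bulge. Default `TRUE`;
#'   only enforced for miRNAs of length 11 or more.
#' @param max_bulge Maximum length (nt) of a single bulge run on either
#'   strand. Default 3.
#' @return An object of class `scoring_params`.
#' @examples
#' scoring_params()
#' scoring_params(wobble = 1) # count wobbles like full mismatches
#' @export
scoring_params <- function(mismatch = 1, wobble = 0.5, bulge_per_nt = 1,
                           max_score = 5, require_paired_10_11 = TRUE,
                           max_bulge = 3) {
  stopifnot(mismatch >= 0, wobble >= 0, bulge_per_nt >= 0, max_score >= 0,
            is.logical(require_paired_10_11), max_bulge >= 1)
  structure(
    list(mismatch = mismatch, wobble = wobble, bulge_per_nt = bulge_per_nt,
         max_score = max_score,
         require_paired_10_11 = isTRUE(require_paired_10_11),
         max_bulge = as.integer(max_bulge)),
    class = "scoring_params"
  )
}

# Turner 2004 nearest-neighbor stack free energies (kcal/mol at 37C),
# Watson-Crick and G:U pairs.  Rows: the 5'-ward pair on the miRNA strand;
# columns: the following pair written in reversed orientation, i.e. the
# energy of stacking pair q on pair p is stack[p, rev(q)] with
# rev(XY) = YX.  Pair codes: first base on the miRNA strand.
.turner_pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")

.turner_stack <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
), nrow = 6, byrow = TRUE, dimnames = list(.turner_pairs, .turner_pairs))

# loop initiation free energies by loop length 1..30 (kcal/mol)
.turner_bulge <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.6, 4.7, 4.8, 4.9,
                   5.0, 5.1, 5.2, 5.3, 5.4, 5.4, 5.5, 5.5, 5.6, 5.7,
                   5.7, 5.8, 5.8, 5.8, 5.9, 5.9, 6.0, 6.0, 6.0, 6.1)

.turner_internal <- c(Inf, 1.0, 1.0, 1.1, 2.0, 2.0, 2.1, 2.3, 2.4, 2.5,
                      2.6, 2.7, 2.8, 2.9, 2.9, 3.0, 3.1, 3.1, 3.2, 3.3,
                      3.3, 3.4, 3.4, 3.5, 3.5, 3.5, 3.6, 3.6, 3.7, 3.7)

#' Nearest-neighbor free-energy parameters
#'
#' The embedded Turner 2004 RNA nearest-neighbor set: stacking free energies
#' for all ordered combinations of Watson-Crick and G:U pairs, bulge and
#' internal-loop initiation energies by loop length, a terminal AU/GU
#' penalty, and the intermolecular duplex initiation term.  All values are
#' free energies at 37 degrees C in kcal/mol.  The duplex model used here is
#' purely additive: initiation + stack terms over adjacent paired columns
#' (a stack is retained across a single-nucleotide bulge) + loop penalties
#' for internal unpaired runs + terminal AU penalties; no coaxial stacking,
#' dangling ends or loop-asymmetry terms, which cancel in the
#' energy-difference comparisons the package is built for.
#'
#' @param stack 6x6 matrix of stacking energies over pair codes
#'   CG, GC, GU, UG, AU, UA (see Details in [duplex_delta_g()]).
#' @param bulge Numeric vector of bulge-loop initiation energies for loop
#'   lengths `1:length(bulge)`.
#' @param internal Numeric vector of internal-loop initiation energies for
#'   loop sizes `1:length(internal)` (size 1 is impossible and set `Inf`).
#' @param terminal_au Penalty for a terminal AU or GU closing pair.
#' @param initiation Intermolecular duplex initiation free energy.
#' @param lxc Logarithmic extrapolation coefficient for loops longer than
#'   the tabulated range.
#' @return An object of class `energy_params`.
#' @examples
#' ep <- energy_params()
#' ep$stack["GC", "CG"] # 5'GG3'/3'CC5' stack
#' @export
energy_params <- function(stack = .turner_stack, bulge = .turner_bulge,
                          internal = .turner_internal, terminal_au = 0.5,
                          initiation = 4.10, lxc = 1.07856) {
  stopifnot(is.matrix(stack), all(dim(stack) == c(6, 6)),
            identical(rownames(stack), .turner_pairs),
            identical(colnames(stack), .turner_pairs),
            all(bulge > 0), all(internal[-1] > 0), length(bulge) >= 6,
            length(internal) >= 6, terminal_au >= 0)
  structure(
    list(stack = stack, bulge = bulge, internal = internal,
         terminal_au = terminal_au, initiation = initiation, lxc = lxc),
    class = "energy_params"
  )
}
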