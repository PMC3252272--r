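# Canonical miR396 sequences and the GRF2 target-site architecture.

#' miR396 variants and the canonical GRF2 target site
#'
#' Mature miR396 sequences used throughout examples and validation:
#' the two Arabidopsis paralogs (`ath-miR396a`, `ath-miR396b`), the
#' monocot-specific variant `miR396_7-8insG` (rice miR396e/f; a G inserted
#' between positions 7 and 8 of miR396a), the `miR396b_7A>G` substitution
#' variant found in Selaginella, pine and poplar, and the 22-nt GRF2 target
#' site (`GRF2_site`).  The GRF2 site is the full complement of
#' `miR396_7-8insG`; paired with the 21-nt Arabidopsis miRNAs it therefore
#' leaves one unpaired target C between miRNA positions 7 and 8 -- the
#' conserved miR396:GRF bulge -- while the monocot variant pairs it without
#' a bulge.
#'
#' @return Named character vector of 5'->3' RNA sequences.
#' @examples
#' mir396_sequences()[["ath-miR396a"]]
#' @export
mir396_sequences <- function() {
  c(
    "ath-miR396a"     = "UUCCACAGCUUUCUUGAACUG",
    "ath-miR396b"     = "UUCCACAGCUUUCUUGAACUU",
    "miR396_7-8insG"  = "UUCCACAGGCUUUCUUGAACUG",
    "miR396b_7A>G"    = "UUCCACGGCUUUCUUGAACUU",
    "GRF2_site"       = "CAGUUCAAGAAAGCCUGUGGAA"
  )
}

#' Arabidopsis miR159/miR319 mature sequences
#'
#' The six Arabidopsis thaliana miR159/miR319 family members (miRBase mature
#' sequences), shipped as a miRBase-dialect FASTA file under `extdata`.
#' miR159 and miR319 are near-identical small RNAs that regulate different
#' target families; the two subfamilies are offset by one nucleotide at the
#' 5' end, so comparing them requires the single-gap alignment mode of
#' [consensus_shared_positions()].
#'
#' @return A `mature_mirna` data frame (see [read_mirbase_mature()]).
#' @examples
#' ath_mir159_mir319()
#' @export
ath_mir159_mir319 <- function() {
  read_mirbase_mature(system.file("extdata", "ath_mir159_mir319.fa",
                                  package = "mirduplex", mustWork = TRUE))
}
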