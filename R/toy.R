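# A small worked example: two short repeats planted on unique spacers.

#' Toy genome with two planted repeats
#'
#' An 88 bp "genome" carrying three instances of the 8 bp repeat
#' `CTCAGTAT` (each with at most one substitution at the variable fourth
#' position: A, C and G) and two exact instances of the 8 bp repeat
#' `TGGTATGA`, separated by unique spacers, in the arrangement
#' R-spacer-O-spacer-R-spacer-R-spacer-O. The spacers were constructed so
#' that no canonical 4-mer outside the planted repeats occurs twice, which
#' keeps the k = 4 de Bruijn graph legible: untangling at
#' `k_init = 4, K = 8` with the simple-bubble threshold relaxed to 0.75
#' collapses the substitution bubbles and decomposes the genome into the
#' two repeat blocks (multiplicities 3 and 2), with block string
#' `A B A A B`.
#'
#' @return a string-set tibble with one chromosome `toy`.
#' @examples
#' toy <- toy_genome()
#' d <- decompose_genome(toy, untangle_params(K = 8, k_init = 4,
#'                                            sim_strong = 0.75,
#'                                            k_schedule = c(4L, 8L)))
#' block_string(d)
#' @export
toy_genome <- function() {
  string_set(paste0(
    "CTCAGTAT", "CGTCTGGGGCGT",
    "TGGTATGA", "CCTGCATTGCCT",
    "CTCCGTAT", "AATTTTACAGCG",
    "CTCGGTAT", "TCCTAGCTTAGA",
    "TGGTATGA"), chrom = "toy", genome = "toy")
}

#' Parameters for the toy example
#'
#' The settings used to decompose [toy_genome()]: the smallest usable
#' initial k-mer size (4; at k = 3 only ten canonical 2-mer vertices exist
#' and the graph of any short sequence is saturated with aliasing), a final
#' block size of 8 (the repeat length), and the simple-bubble similarity
#' threshold relaxed to 0.75 so that a single substitution in an 8 bp
#' repeat still counts as similar.
#'
#' @return an [untangle_params()] object.
#' @export
toy_params <- function() {
  untangle_params(K = 8, k_init = 4, sim_strong = 0.75,
                  k_schedule = c(4L, 8L))
}
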