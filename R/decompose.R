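# End-to-end decomposition drivers.

#' Decompose a genome into duplication blocks
#'
#' Runs the full pipeline: iterative untangling (bubble collapsing over an
#' increasing k-mer schedule), block inference on the final graph, and
#' lift-over of the block instances to the original coordinates.
#'
#' @param ss string-set tibble (one or more chromosomes; may contain several
#'   genome labels, in which case the block alphabet is shared).
#' @param params an [untangle_params()] object.
#' @param verbose print per-scan progress.
#' @return an `sd_decomposition` in original coordinates with extra elements
#'   `disembroiled` (the decomposition in disembroiled coordinates),
#'   `untangle` (the `sd_untangle` object) and `params`.
#' @examples
#' \donttest{
#' unit <- strrep("ACGTTGCA", 40)
#' ss <- string_set(paste0(strrep("GATTACA", 60), unit, strrep("TTGACC", 60),
#'                         unit, strrep("CCAGTT", 60)))
#' d <- decompose_genome(ss, untangle_params(K = 100, k_init = 21))
#' }
#' @export
decompose_genome <- function(ss, params, verbose = FALSE) {
  u <- untangle(ss, params, verbose = verbose)
  d0 <- infer_blocks(u, min_block_len = params$min_block_len)
  d1 <- lift_decomposition(d0, u)
  d1$disembroiled <- d0
  d1$untangle <- u
  d1$params <- params
  d1
}

#' Jointly decompose several genomes over a shared block alphabet
#'
#' Applies the pipeline to the combined string-set of all genomes, so that
#' one block alphabet describes them all and per-genome edge multiplicities
#' can be compared. A genome analysed alone and jointly may legitimately
#' yield different alphabets, because the graphs differ.
#'
#' @param genomes a list of string-set tibbles (or a single tibble holding
#'   several genome labels); at least two distinct genome labels.
#' @param params an [untangle_params()] object.
#' @param verbose print per-scan progress.
#' @return an `sd_decomposition` as from [decompose_genome()].
#' @export
joint_decompose <- function(genomes, params, verbose = FALSE) {
  ss <- if (is.data.frame(genomes)) genomes else bind_rows(genomes)
  validate_string_set(ss)
  labs <- unique(ss$genome)
  if (length(labs) < 2)
    abort("joint decomposition needs >= 2 distinct genome labels")
  if (!is.data.frame(genomes)) {
    per <- vapply(genomes, function(g) length(unique(g$genome)), 0L)
    gl <- unlist(lapply(genomes, function(g) unique(g$genome)))
    if (anyDuplicated(gl)) abort("duplicate genome labels across inputs")
  }
  decompose_genome(ss, params, verbose = verbose)
}
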