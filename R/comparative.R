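# Comparing block architectures across genomes decomposed jointly.

# per-block, per-genome edge multiplicity table with explicit zeros
block_edge_mult <- function(decomp) {
  genomes <- unique(decomp$chroms$genome)
  purrr::map2(decomp$blocks$block_id, decomp$blocks$edge_mult, function(b, em) {
    em |>
      tidyr::complete(edge_id = unique(em$edge_id), genome = genomes,
                      fill = list(mult = 0L)) |>
      mutate(block_id = b)
  }) |> bind_rows()
}

#' Imbalanced blocks across genomes
#'
#' In a joint graph every edge carries one multiplicity per genome; an edge
#' is imbalanced when those counts differ, and a block is imbalanced when
#' any edge on its path is. For more than two genomes, "differ" means the
#' counts are not all equal.
#'
#' @param decomp an `sd_decomposition` from [joint_decompose()].
#' @return character vector of imbalanced block ids, in letter order.
#' @export
imbalanced_blocks <- function(decomp) {
  if (nrow(decomp$blocks) == 0) return(character())
  bem <- block_edge_mult(decomp)
  bad <- bem |>
    group_by(.data$block_id, .data$edge_id) |>
    summarise(imb = dplyr::n_distinct(.data$mult) > 1, .groups = "drop") |>
    group_by(.data$block_id) |>
    summarise(imb = any(.data$imb))
  ids <- bad$block_id[bad$imb]
  decomp$blocks$block_id[decomp$blocks$block_id %in% ids]
}

#' Differential block report across genomes
#'
#' Per block and genome: instance count, total instance length, the
#' imbalance flag, and (when annotations are supplied) the number of
#' annotated genes falling fully inside any instance of the block. A gene
#' straddling an instance boundary is not counted.
#'
#' @param decomp an `sd_decomposition` in original coordinates from
#'   [joint_decompose()].
#' @param genes optional named list of gene tibbles (as from [read_genes()]),
#'   one element per genome label.
#' @return a tibble with one row per (block, genome).
#' @export
differential_report <- function(decomp, genes = NULL) {
  genomes <- unique(decomp$chroms$genome)
  base <- tidyr::expand_grid(block_id = decomp$blocks$block_id,
                             genome = genomes)
  counts <- decomp$instances |>
    group_by(.data$block_id, .data$genome) |>
    summarise(n_instances = dplyr::n(),
              total_length = sum(.data$end - .data$start), .groups = "drop")
  out <- base |>
    left_join(counts, by = c("block_id", "genome")) |>
    mutate(n_instances = dplyr::coalesce(.data$n_instances, 0L),
           total_length = dplyr::coalesce(.data$total_length, 0L))
  imb <- imbalanced_blocks(decomp)
  out$imbalanced <- out$block_id %in% imb
  if (!is.null(genes)) {
    stopifnot(is.list(genes), !is.null(names(genes)))
    out$n_genes <- 0L
    for (gl in names(genes)) {
      gn <- genes[[gl]]
      chroms_g <- decomp$chroms |> filter(.data$genome == gl)
      unknown <- setdiff(gn$chrom, chroms_g$chrom)
      if (length(unknown) > 0)
        abort(sprintf("annotation chromosome %s not in genome %s",
                      unknown[1], gl))
      ins <- decomp$instances |> filter(.data$genome == gl)
      for (b in unique(ins$block_id)) {
        ib <- ins |> filter(.data$block_id == b)
        ng <- 0L
        for (r in seq_len(nrow(gn))) {
          hit <- any(ib$chrom == gn$chrom[r] & ib$start <= gn$start[r] &
                       ib$end >= gn$end[r])
          if (hit) ng <- ng + 1L
        }
        out$n_genes[out$block_id == b & out$genome == gl] <- ng
      }
    }
  }
  out |> arrange(.data$block_id, .data$genome)
}
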