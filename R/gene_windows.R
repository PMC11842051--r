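# Block-anchored gene analysis: align gene-centred windows across instances
# of the same block, compare gene percent identity with window percent
# identity, and classify genes as disrupted or block-annotated.

#' Parameters for the gene-window analysis
#'
#' @param window_len window length centred on the gene (default 100 bp).
#' @param min_pi window-PI threshold below which a gene copy is called
#'   disrupted (default 0.60).
#' @param max_diff maximum tolerated substitutions in the RSS heptamer plus
#'   nonamer (default 2); an indel in either motif counts as an automatic
#'   fail.
#' @return list of class `sd_gene_params`.
#' @export
gene_params <- function(window_len = 100L, min_pi = 0.60, max_diff = 2L) {
  stopifnot(window_len >= 1, min_pi >= 0, min_pi <= 1, max_diff >= 0)
  structure(list(window_len = as.integer(window_len), min_pi = min_pi,
                 max_diff = as.integer(max_diff)), class = "sd_gene_params")
}

# boundary map a-positions -> b-positions (deleted runs map to left edge)
transcript_fmap <- function(transcript) {
  ops <- strsplit(transcript$ops, "")[[1]]
  di <- ops %in% c("=", "X", "D")
  dj <- ops %in% c("=", "X", "I")
  j_after <- cumsum(dj)
  la <- sum(di)
  fmap <- integer(la + 1L)
  fmap[1L + cumsum(di)[di]] <- j_after[di]
  fmap
}

#' Align a gene-centred window from one block instance onto another
#'
#' The window (of `window_len` bp, centred on the gene midpoint and clipped
#' at the instance edges) is cut from the anchor instance, anchored onto the
#' target instance through the global instance-to-instance alignment, and
#' re-aligned there. The window PI is the percent identity of that
#' alignment; the gene PI is the percent identity of the sub-alignment of
#' the columns touching the gene.
#'
#' @param anchor_text,target_text the two instance sequences (same
#'   orientation, e.g. both in consensus orientation).
#' @param gene_start,gene_end gene interval, 0-based half-open, relative to
#'   `anchor_text`.
#' @param params an [gene_params()] object.
#' @param hept_start,nona_start optional anchor-relative starts of the RSS
#'   heptamer (7 bp) and nonamer (9 bp).
#' @param gene name carried through to the result.
#' @return one-row tibble: `gene`, `gene_pi`, `window_pi`, `hept_diffs`,
#'   `nona_diffs`, `classification`.
#' @export
window_align <- function(anchor_text, target_text, gene_start, gene_end,
                         params = gene_params(), hept_start = NA,
                         nona_start = NA, gene = NA_character_) {
  la <- str_len(anchor_text)
  if (gene_start < 0 || gene_end > la || gene_start >= gene_end)
    abort("gene does not lie inside the anchor instance")
  center <- (gene_start + gene_end) %/% 2L
  w0 <- max(0L, center - params$window_len %/% 2L)
  w1 <- min(la, w0 + params$window_len)
  w0 <- max(0L, min(w0, w1 - params$window_len))
  w0 <- min(w0, gene_start)
  w1 <- max(w1, gene_end)
  tr <- align_global(anchor_text, target_text)
  fmap <- transcript_fmap(tr)
  t0 <- fmap[w0 + 1L]; t1 <- fmap[w1 + 1L]
  wtext <- substring(anchor_text, w0 + 1L, w1)
  ttext <- substring(target_text, t0 + 1L, t1)
  tr2 <- if (str_len(ttext) == 0)
    list(ops = strrep("D", str_len(wtext)), distance = str_len(wtext))
  else align_global(wtext, ttext)
  window_pi <- if (max(str_len(wtext), str_len(ttext)) == 0) 1 else
    1 - tr2$distance / max(str_len(wtext), str_len(ttext))
  # gene sub-alignment
  ops <- strsplit(tr2$ops, "")[[1]]
  gs <- gene_start - w0; ge <- gene_end - w0
  i <- 0L; j <- 0L
  edits <- 0L; glen_t <- 0L
  for (op in ops) {
    in_gene <- switch(op,
      "=" = , "X" = , "D" = (i >= gs && i < ge),
      "I" = (i > gs && i < ge))
    if (op %in% c("=", "X", "D")) i <- i + 1L
    if (op %in% c("=", "X", "I")) j <- j + 1L
    if (in_gene) {
      if (op != "=") edits <- edits + 1L
      if (op %in% c("=", "X", "I")) glen_t <- glen_t + 1L
    }
  }
  gene_pi <- 1 - edits / max(gene_end - gene_start, glen_t)
  rss <- function(start, len) {
    if (is.na(start)) return(NA_integer_)
    if (start < 0 || start + len > la) return(params$max_diff + 1L)
    a0 <- fmap[start + 1L]; a1 <- fmap[start + len + 1L]
    if (a1 - a0 != len) return(params$max_diff + 1L) # indel in the motif
    am <- substring(anchor_text, start + 1L, start + len)
    tm <- substring(target_text, a0 + 1L, a1)
    sum(strsplit(am, "")[[1]] != strsplit(tm, "")[[1]])
  }
  res <- tibble::tibble(gene = gene, gene_pi = gene_pi, window_pi = window_pi,
                        hept_diffs = rss(hept_start, 7L),
                        nona_diffs = rss(nona_start, 9L))
  res$classification <- classify_gene(res, params)
  res
}

#' Classify a gene copy as disrupted or block-annotated
#'
#' Disrupted when the window PI falls below `min_pi`, or when the RSS
#' heptamer and nonamer together differ by more than `max_diff`
#' substitutions (an indel in either motif is an automatic fail); otherwise
#' block-annotated.
#'
#' @param result a row as produced by [window_align()].
#' @param params an [gene_params()] object.
#' @return `"disrupted"` or `"block-annotated"`.
#' @export
classify_gene <- function(result, params = gene_params()) {
  diffs <- sum(c(result$hept_diffs[[1]], result$nona_diffs[[1]]), na.rm = TRUE)
  if (result$window_pi[[1]] < params$min_pi || diffs > params$max_diff)
    "disrupted" else "block-annotated"
}

#' Gene-window analysis over a block decomposition
#'
#' For every annotated gene lying fully inside a block instance, aligns its
#' window against every other instance of the same block and reports gene
#' PI, window PI, RSS differences and the disruption call.
#'
#' @param decomp an `sd_decomposition` in original coordinates.
#' @param ss the original string-set.
#' @param genes gene tibble (as from [read_genes()]).
#' @param params an [gene_params()] object.
#' @return tibble with one row per (gene, target instance).
#' @export
gene_window_analysis <- function(decomp, ss, genes, params = gene_params()) {
  seqs <- stats::setNames(ss$seq, paste(ss$genome, ss$chrom))
  ins <- decomp$instances |> mutate(.row = dplyr::row_number())
  out <- list()
  inst_text <- function(x) {
    txt <- substring(seqs[[paste(x$genome, x$chrom)]], x$start + 1L, x$end)
    if (x$strand == "-") revcomp(txt) else txt
  }
  for (r in seq_len(nrow(genes))) {
    gn <- genes[r, ]
    anchor <- ins |> filter(.data$chrom == gn$chrom,
                            .data$start <= gn$start, .data$end >= gn$end)
    if (nrow(anchor) == 0) next
    anchor <- anchor[1, ]
    atext <- inst_text(anchor)
    al <- str_len(atext)
    to_rel <- function(p) {
      if (anchor$strand == "-") al - (p - anchor$start) else p - anchor$start
    }
    if (anchor$strand == "-") {
      gs <- to_rel(gn$end); ge <- to_rel(gn$start)
      h0 <- if (is.na(gn$hept_start)) NA else to_rel(gn$hept_start + 7L)
      n0 <- if (is.na(gn$nona_start)) NA else to_rel(gn$nona_start + 9L)
    } else {
      gs <- to_rel(gn$start); ge <- to_rel(gn$end)
      h0 <- if (is.na(gn$hept_start)) NA else to_rel(gn$hept_start)
      n0 <- if (is.na(gn$nona_start)) NA else to_rel(gn$nona_start)
    }
    targets <- ins |> filter(.data$block_id == anchor$block_id,
                             .data$.row != anchor$.row)
    for (t in seq_len(nrow(targets))) {
      tg <- targets[t, ]
      res <- window_align(atext, inst_text(tg), gs, ge, params,
                          hept_start = h0, nona_start = n0, gene = gn$name)
      res$anchor <- sprintf("%s:%s:%d-%d", anchor$genome, anchor$chrom,
                            anchor$start, anchor$end)
      res$target <- sprintf("%s:%s:%d-%d", tg$genome, tg$chrom, tg$start,
                            tg$end)
      res$block_id <- anchor$block_id
      out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0) return(tibble::tibble())
  bind_rows(out) |>
    select("gene", "block_id", "anchor", "target", "gene_pi", "window_pi",
           "hept_diffs", "nona_diffs", "classification")
}

#' Selective-pressure table
#'
#' One row per (gene, target) with the gene and window percent identities
#' and a flag marking gene-local divergence (gene PI below window PI),
#' followed by one `average` row per gene.
#'
#' @param results output of [gene_window_analysis()] (or rows from
#'   [window_align()]).
#' @return tibble with columns `gene`, `target`, `gene_pi`, `window_pi`,
#'   `gene_below_window`.
#' @export
pressure_table <- function(results) {
  if (nrow(results) == 0)
    return(tibble::tibble(gene = character(), target = character(),
                          gene_pi = double(), window_pi = double(),
                          gene_below_window = logical()))
  rows <- results |>
    mutate(gene_below_window = .data$gene_pi < .data$window_pi) |>
    select("gene", "target", "gene_pi", "window_pi", "gene_below_window")
  avg <- results |>
    group_by(.data$gene) |>
    summarise(target = "average", gene_pi = mean(.data$gene_pi),
              window_pi = mean(.data$window_pi), .groups = "drop") |>
    mutate(gene_below_window = .data$gene_pi < .data$window_pi)
  bind_rows(rows, avg) |> arrange(.data$gene)
}
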