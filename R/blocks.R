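# Block inference from the untangled graph: a non-overlapping decomposition
# of each chromosome into block instances and non-repetitive segments, with
# a minimal block alphabet.

#' Block graph: repeated edges only
#'
#' The subgraph of a condensed de Bruijn graph containing exactly the edges
#' of total multiplicity >= 2; isolated vertices are dropped. Walks are not
#' carried over (they are no longer walks of the subgraph).
#'
#' @param g an `sd_cdbg`.
#' @return an `sd_cdbg` with filtered `edges` and `vertices`.
#' @export
block_graph <- function(g) {
  e <- g$edges |> filter(.data$mult >= 2)
  keep_v <- unique(abs(c(e$from, e$to)))
  v <- g$vertices |> filter(.data$vertex_id %in% keep_v)
  structure(list(k = g$k, edges = e, vertices = v,
                 walks = g$walks[0, ], clips = g$clips[0, ],
                 strings = g$strings), class = "sd_cdbg")
}

# node indexing for signed edge ids
node_idx <- function(d) ifelse(d > 0, 2L * d - 1L, -2L * d)

# Merge relation over directed block edges: d -> e when e is the unique
# block-graph edge out of d's sink and d is the unique block-graph edge
# into it (multiplicity-1 edges are ignored, so a walk may still enter or
# leave the merged path midway: such traversals become partial instances).
block_graph_succ <- function(g, is_block) {
  ids <- which(is_block)
  dirs <- c(ids, -ids)
  nn <- 2L * nrow(g$edges)
  frm <- norm_vertex(g, step_from(g, dirs))
  tto <- norm_vertex(g, step_to(g, dirs))
  out_of <- split(dirs, frm)
  in_of <- split(dirs, tto)
  bsucc <- rep(NA_integer_, nn)
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    v <- as.character(tto[i])
    outs <- out_of[[v]]
    ins <- in_of[[v]]
    if (length(outs) == 1L && length(ins) == 1L && outs != d)
      bsucc[node_idx(d)] <- outs
  }
  bsucc
}

# chains of directed edges under msucc; returns list(chains, chain_of, pos_of)
build_chains <- function(block_dirs, msucc, n_edges) {
  nn <- 2L * n_edges
  chain_of <- rep(NA_integer_, nn); pos_of <- rep(NA_integer_, nn)
  has_pred <- logical(nn)
  for (i in which(!is.na(msucc))) has_pred[node_idx(msucc[i])] <- TRUE
  chains <- list()
  follow <- function(d0) {
    ch <- integer()
    d <- d0
    repeat {
      i <- node_idx(d)
      if (!is.na(chain_of[i])) break
      chain_of[i] <<- length(chains) + 1L
      pos_of[i] <<- length(ch) + 1L
      ch <- c(ch, d)
      nxt <- msucc[i]
      if (is.na(nxt)) break
      d <- nxt
    }
    chains[[length(chains) + 1L]] <<- ch
  }
  for (d in block_dirs) if (!has_pred[node_idx(d)] &&
                            is.na(chain_of[node_idx(d)])) follow(d)
  # junction-free cycles (e.g. tandem arrays): break at the smallest node,
  # then lay the reverse-complement cycle down explicitly so the twin pair
  # stays aligned
  for (d in block_dirs) {
    if (!is.na(chain_of[node_idx(d)])) next
    follow(d)
    ch <- chains[[length(chains)]]
    td <- -ch[length(ch)]
    if (is.na(chain_of[node_idx(td)])) {
      tc <- -rev(ch)
      id <- length(chains) + 1L
      for (q in seq_along(tc)) {
        chain_of[node_idx(tc[q])] <- id
        pos_of[node_idx(tc[q])] <- q
      }
      chains[[id]] <- tc
    }
  }
  list(chains = chains, chain_of = chain_of, pos_of = pos_of)
}

#' Infer the block decomposition from an untangled graph
#'
#' Maximal non-branching paths of the block graph (repeated edges only) are
#' merged into single blocks, which keeps the block alphabet minimal; a
#' walk that enters or leaves a merged path midway yields a partial
#' instance with recorded consensus offsets, so instances of one block may
#' have widely different lengths. Each walk's maximal runs through repeated
#' edges become instances (split where the chain position does not advance,
#' e.g. at each period of a tandem array); the (K-1)-character overlap
#' between adjacent instances is assigned to the earlier one so instances
#' never overlap. Blocks are lettered A, B, ... by first genomic
#' occurrence.
#'
#' @param u an `sd_untangle` (or an `sd_cdbg` built at K together with its
#'   walks).
#' @param min_block_len instances shorter than this are folded back into
#'   non-repetitive sequence (default: the `K` the graph was built at).
#' @return an `sd_decomposition`: list with `blocks` (tibble `block_id`,
#'   `consensus`, `length`, `n_instances`, `edges` list column,
#'   `edge_mult` list column of per-genome edge multiplicities),
#'   `instances` (tibble `block_id`, `genome`, `chrom`, `start`, `end`,
#'   `strand`, `cons_start`, `cons_end`, `pct_identity`), `chroms`, and
#'   `space = "disembroiled"`.
#' @export
infer_blocks <- function(u, min_block_len = NULL) {
  g <- if (inherits(u, "sd_untangle")) u$graph else u
  stopifnot(inherits(g, "sd_cdbg"))
  if (is.null(min_block_len)) min_block_len <- g$k
  is_block <- g$edges$mult >= 2
  n_edges <- nrow(g$edges)
  chroms <- g$strings |>
    mutate(length = str_len(.data$seq)) |>
    select("genome", "chrom", "length")

  # maximal runs of block-edge steps per walk
  runs <- list()
  for (wi in seq_len(nrow(g$walks))) {
    s <- g$walks$steps[[wi]]
    if (length(s) == 0) next
    inb <- is_block[abs(s)]
    r <- rle(inb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      runs[[length(runs) + 1L]] <- list(walk = wi, first = starts[j],
                                        last = ends[j])
  }
  if (length(runs) == 0) {
    return(new_decomposition(
      blocks = tibble::tibble(block_id = character(), consensus = character(),
                              length = integer(), n_instances = integer(),
                              edges = list(), edge_mult = list()),
      instances = empty_instances(), chroms = chroms, k = g$k))
  }
  runs_steps <- lapply(runs, function(r) g$walks$steps[[r$walk]][r$first:r$last])
  msucc <- block_graph_succ(g, is_block)
  block_dirs <- sort(c(which(is_block), -which(is_block)))
  block_dirs <- block_dirs[order(abs(block_dirs), -sign(block_dirs))]
  bc <- build_chains(block_dirs, msucc, n_edges)

  # pair each chain with its reverse-complement twin -> one block per pair
  n_ch <- length(bc$chains)
  twin <- vapply(seq_len(n_ch), function(ci) {
    ch <- bc$chains[[ci]]
    bc$chain_of[node_idx(-ch[length(ch)])]
  }, 0L)
  canon_chain <- integer(0) # canonical chain per block
  block_of_chain <- rep(NA_integer_, n_ch)
  for (ci in seq_len(n_ch)) {
    if (!is.na(block_of_chain[ci])) next
    b <- length(canon_chain) + 1L
    canon_chain[b] <- ci
    block_of_chain[ci] <- b
    block_of_chain[twin[ci]] <- b
  }
  n_blocks <- length(canon_chain)
  elen <- g$edges$length
  chain_info <- lapply(canon_chain, function(ci) {
    ch <- bc$chains[[ci]]
    lens <- elen[abs(ch)]
    offs <- c(0L, cumsum(lens[-length(lens)] - (g$k - 1L)))
    list(steps = ch, lens = lens, offs = offs,
         total = offs[length(offs)] + lens[length(lens)])
  })

  # split runs into instances at chain boundaries
  inst <- list()
  for (ri in seq_along(runs)) {
    r <- runs[[ri]]
    d <- runs_steps[[ri]]
    m <- length(d)
    cut <- if (m > 1) {
      vapply(seq_len(m - 1L), function(i) {
        ci <- bc$chain_of[node_idx(d[i])]
        cj <- bc$chain_of[node_idx(d[i + 1L])]
        ci != cj || bc$pos_of[node_idx(d[i + 1L])] !=
          bc$pos_of[node_idx(d[i])] + 1L
      }, TRUE)
    } else logical(0)
    bounds <- c(0L, which(cut), m)
    w <- g$walks[r$walk, ]
    for (j in seq_len(length(bounds) - 1L)) {
      i1 <- bounds[j] + 1L; i2 <- bounds[j + 1L]
      d1 <- d[i1]
      ci <- bc$chain_of[node_idx(d1)]
      b <- block_of_chain[ci]
      fwd <- ci == canon_chain[b]
      info <- chain_info[[b]]
      clen <- length(info$steps)
      if (fwd) {
        j1 <- bc$pos_of[node_idx(d1)]
        j2 <- j1 + (i2 - i1)
      } else {
        p1 <- bc$pos_of[node_idx(d1)]
        j2 <- clen - p1 + 1L
        j1 <- j2 - (i2 - i1)
      }
      iv <- steps_interval(g, r$walk, r$first + i1 - 1L, r$first + i2 - 1L)
      inst[[length(inst) + 1L]] <- tibble::tibble(
        block = b, genome = w$genome, chrom = w$chrom,
        start = iv[1], end = iv[2],
        strand = if (fwd) "+" else "-",
        cons_start = info$offs[j1],
        cons_end = info$offs[j2] + info$lens[j2])
    }
  }
  raw <- bind_rows(inst) |>
    arrange(.data$genome, .data$chrom, .data$start)

  # Non-overlap and length filtering interact. The (K-1) overlap between
  # adjacent instances is assigned to the LATER one: its start then sits on
  # the underlying repeat boundary, so a tandem array's instance grid lines
  # up with its periods. An instance is folded into non-repetitive sequence
  # when its raw extent is below min_block_len, or when overlap resolution
  # consumed more than two thirds of it (a boundary artifact riding on a
  # real block); trimming is then recomputed from raw coordinates until
  # stable, so folded instances stop claiming space.
  alive <- rep(TRUE, nrow(raw))
  cur <- raw[0, ]
  repeat {
    cur <- raw[alive, ]
    cur <- cur |>
      group_by(.data$genome, .data$chrom) |>
      mutate(new_end = pmin(.data$end,
                            dplyr::lead(.data$start,
                                        default = .Machine$integer.max)),
             trim = .data$end - .data$new_end) |>
      ungroup()
    raw_len <- cur$end - cur$start
    trim_len <- cur$new_end - cur$start
    short <- raw_len < min_block_len | trim_len < raw_len / 3
    few <- cur |>
      mutate(ok = !short) |>
      group_by(.data$block) |>
      mutate(n_ok = sum(.data$ok)) |>
      ungroup() |>
      (\(d) d$n_ok < 2)()
    dead <- short | few
    if (!any(dead)) break
    alive[which(alive)[dead]] <- FALSE
  }
  instances <- cur |>
    mutate(cons_end = ifelse(.data$strand == "+",
                             .data$cons_end - .data$trim, .data$cons_end),
           cons_start = ifelse(.data$strand == "-",
                               .data$cons_start + .data$trim,
                               .data$cons_start),
           end = .data$new_end) |>
    select(-"new_end", -"trim")

  if (nrow(instances) == 0) {
    return(new_decomposition(
      blocks = tibble::tibble(block_id = character(), consensus = character(),
                              length = integer(), n_instances = integer(),
                              edges = list(), edge_mult = list()),
      instances = empty_instances(), chroms = chroms, k = g$k))
  }

  # letters by first genomic occurrence
  first_occ <- instances |>
    arrange(.data$genome, .data$chrom, .data$start) |>
    distinct(.data$block, .keep_all = TRUE)
  letters_map <- stats::setNames(block_letters(nrow(first_occ)), first_occ$block)

  em <- edge_multiplicities(g)
  blocks <- purrr::map(seq_along(first_occ$block), function(i) {
    b <- first_occ$block[i]
    info <- chain_info[[b]]
    eids <- abs(info$steps)
    tibble::tibble(
      block_id = letters_map[[as.character(b)]],
      consensus = spell_steps(g, info$steps),
      length = info$total,
      n_instances = sum(instances$block == b),
      edges = list(eids),
      edge_mult = list(em |> filter(.data$edge_id %in% eids)))
  }) |> bind_rows()

  instances <- instances |>
    mutate(block_id = unname(letters_map[as.character(.data$block)])) |>
    select(-"block")
  # per-instance identity to the consensus (exact in the untangled genome)
  cons <- stats::setNames(blocks$consensus, blocks$block_id)
  seqs <- stats::setNames(g$strings$seq, paste(g$strings$genome, g$strings$chrom))
  instances$pct_identity <- vapply(seq_len(nrow(instances)), function(i) {
    x <- instances[i, ]
    txt <- substring(seqs[[paste(x$genome, x$chrom)]], x$start + 1L, x$end)
    ref <- substring(cons[[x$block_id]], x$cons_start + 1L, x$cons_end)
    if (x$strand == "-") txt <- revcomp(txt)
    percent_identity(txt, ref)
  }, 0)
  instances <- instances |>
    select("block_id", "genome", "chrom", "start", "end", "strand",
           "cons_start", "cons_end", "pct_identity")
  new_decomposition(blocks = blocks, instances = instances, chroms = chroms,
                    k = g$k)
}

empty_instances <- function() {
  tibble::tibble(block_id = character(), genome = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), cons_start = integer(),
                 cons_end = integer(), pct_identity = double())
}

new_decomposition <- function(blocks, instances, chroms, k,
                              space = "disembroiled") {
  structure(list(blocks = blocks, instances = instances, chroms = chroms,
                 k = k, space = space), class = "sd_decomposition")
}

#' @export
print.sd_decomposition <- function(x, ...) {
  cat(sprintf("block decomposition (%s coordinates): %d blocks, %d instances over %d chromosome(s)\n",
              x$space, nrow(x$blocks), nrow(x$instances), nrow(x$chroms)))
  if (nrow(x$blocks) > 0) {
    bs <- block_string(x)
    for (nm in names(bs)) cat(" ", nm, ":", bs[[nm]], "\n")
  }
  invisible(x)
}

#' Full tiling of every chromosome
#'
#' Alternating block instances and non-repetitive segments (`block_id` `NA`,
#' possibly length 0) covering `[0, length)` of every chromosome. Per
#' chromosome there is always one more non-repetitive segment than there are
#' instances.
#'
#' @param decomp an `sd_decomposition`.
#' @return tibble in the decomposition TSV schema.
#' @export
decomposition_segments <- function(decomp) {
  out <- list()
  for (i in seq_len(nrow(decomp$chroms))) {
    ch <- decomp$chroms[i, ]
    ins <- decomp$instances |>
      filter(.data$genome == ch$genome, .data$chrom == ch$chrom) |>
      arrange(.data$start)
    gaps_start <- c(0L, ins$end)
    gaps_end <- c(ins$start, ch$length)
    gaps <- tibble::tibble(
      genome = ch$genome, chrom = ch$chrom,
      start = gaps_start, end = gaps_end,
      block_id = NA_character_, strand = ".",
      pct_identity_to_consensus = NA_real_,
      partial_start_offset = NA_integer_, partial_end_offset = NA_integer_)
    ins2 <- ins |>
      mutate(pct_identity_to_consensus = .data$pct_identity,
             partial_start_offset = .data$cons_start,
             partial_end_offset = .data$cons_end) |>
      select("genome", "chrom", "start", "end", "block_id", "strand",
             "pct_identity_to_consensus", "partial_start_offset",
             "partial_end_offset")
    out[[length(out) + 1L]] <- bind_rows(gaps, ins2)
  }
  bind_rows(out) |>
    mutate(instance_length = .data$end - .data$start) |>
    arrange(.data$genome, .data$chrom, .data$start, !is.na(.data$block_id)) |>
    select(all_of(c("genome", "chrom", "start", "end", "block_id", "strand",
                    "instance_length", "pct_identity_to_consensus",
                    "partial_start_offset", "partial_end_offset")))
}

#' Represent chromosomes as strings over the block alphabet
#'
#' Block letters in genomic order; reverse-strand instances carry a `'`
#' suffix; partial instances show their consensus offsets as
#' `A[start,end]`. Non-repetitive segments are omitted.
#'
#' @param decomp an `sd_decomposition`.
#' @return named character vector, one element per chromosome (names
#'   `genome:chrom`, or `chrom` for a single genome).
#' @export
block_string <- function(decomp) {
  lens <- stats::setNames(decomp$blocks$length, decomp$blocks$block_id)
  single <- dplyr::n_distinct(decomp$chroms$genome) == 1
  out <- character(0)
  for (i in seq_len(nrow(decomp$chroms))) {
    ch <- decomp$chroms[i, ]
    ins <- decomp$instances |>
      filter(.data$genome == ch$genome, .data$chrom == ch$chrom) |>
      arrange(.data$start)
    lab <- character(nrow(ins))
    if (nrow(ins) > 0) {
      full <- ins$cons_start == 0 & ins$cons_end == lens[ins$block_id]
      lab <- paste0(ins$block_id,
                    ifelse(full, "",
                           sprintf("[%d,%d]", ins$cons_start, ins$cons_end)),
                    ifelse(ins$strand == "-", "'", ""))
    }
    nm <- if (single) ch$chrom else paste(ch$genome, ch$chrom, sep = ":")
    out[nm] <- paste(lab, collapse = " ")
  }
  out
}

#' @export
#' @importFrom generics tidy
#' @method tidy sd_decomposition
#' @rdname sd_decomposition_methods
#' @title Tidiers for block decompositions
#' @param x an `sd_decomposition`.
#' @param ... unused.
#' @description `tidy()` returns the instance table; `glance()` a one-row
#'   summary.
tidy.sd_decomposition <- function(x, ...) x$instances

#' @export
#' @importFrom generics glance
#' @method glance sd_decomposition
#' @rdname sd_decomposition_methods
glance.sd_decomposition <- function(x, ...) {
  rep_len_total <- sum(x$instances$end - x$instances$start)
  tibble::tibble(
    n_blocks = nrow(x$blocks),
    n_instances = nrow(x$instances),
    n_genomes = dplyr::n_distinct(x$chroms$genome),
    n_chroms = nrow(x$chroms),
    genome_length = sum(x$chroms$length),
    repeat_fraction = rep_len_total / sum(x$chroms$length))
}
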