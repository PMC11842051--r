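# Planted-duplication genome simulator with exact truth tracking.
#
# The generator emulates the duplication landscape the decomposer targets:
# long (kilobase-scale) blocks planted on a random backbone as dispersed
# copies, tandem arrays, or reverse-tandem (inverted) arrays, each copy
# independently mutated from its progenitor under a point-substitution +
# single-base-indel model, optionally with genes whose local mutation rate
# is elevated relative to their surrounding window.

#' Configuration for the planted-duplication simulator
#'
#' When `blocks` is `NULL`, per-block length, copy number, arrangement and
#' divergence are drawn (deterministically from `seed`) from the given
#' ranges: blocks of 3-10 kb, 2-5 copies and 1-5% pairwise divergence
#' between copies (each copy is mutated independently from the progenitor
#' at half that rate) on a 200 kb backbone, with an indel rate of one
#' tenth of the substitution rate — the duplication scale and divergence
#' typical of recent segmental duplications in loci such as IGH.
#'
#' @param seed integer seed; the whole construction is deterministic in it.
#' @param backbone_len length of the unique backbone the copies are planted
#'   into.
#' @param n_blocks number of planted blocks (when `blocks` is `NULL`).
#' @param length_range,copy_range,divergence_range sampling ranges.
#' @param arrangements arrangements to cycle through
#'   (`dispersed`/`tandem`/`reverse-tandem`).
#' @param blocks optional explicit tibble with columns `length`, `copies`,
#'   `arrangement`, `sub_rate`, `indel_rate`.
#' @param genes optional tibble with columns `block` (index), `offset`,
#'   `length`, `hept_offset`, `nona_offset` (offsets relative to gene start;
#'   `NA` to omit the RSS), `rate_mult` (gene-local substitution rate
#'   multiplier).
#' @param rt_spacer length of the unique spacer inserted between the two
#'   strands of a reverse-tandem pair (an exactly adjacent copy and its
#'   reverse complement would form a perfect palindrome whose hairpin walk
#'   hides the repeat; real inverted duplications carry a spacer too).
#' @return a list of class `sd_plant_config`.
#' @export
plant_config <- function(seed, backbone_len = 200000L, n_blocks = 5L,
                         length_range = c(3000L, 10000L),
                         copy_range = c(2L, 5L),
                         divergence_range = c(0.01, 0.05),
                         arrangements = c("dispersed", "tandem",
                                          "reverse-tandem"),
                         blocks = NULL, genes = NULL, rt_spacer = 100L) {
  stopifnot(backbone_len > 0)
  cfg <- list(seed = as.integer(seed), backbone_len = as.integer(backbone_len),
              n_blocks = as.integer(n_blocks), length_range = length_range,
              copy_range = copy_range, divergence_range = divergence_range,
              arrangements = arrangements, blocks = blocks, genes = genes,
              rt_spacer = as.integer(rt_spacer))
  if (!is.null(blocks)) {
    stopifnot(all(c("length", "copies", "arrangement", "sub_rate",
                    "indel_rate") %in% names(blocks)))
    stopifnot(all(blocks$copies >= 2), all(blocks$sub_rate >= 0),
              all(blocks$sub_rate < 0.5), all(blocks$indel_rate < 0.5))
  }
  structure(cfg, class = "sd_plant_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence; returns the mutated string, a boundary coordinate map
# (original position i in 0..n -> position in the mutated string) and the
# number of events. rate_of: per-position substitution rates.
mutate_seq <- function(s, sub_rate, indel_rate, regions = NULL) {
  n <- str_len(s)
  chars <- strsplit(s, "")[[1]]
  rates <- rep(sub_rate, n)
  if (!is.null(regions)) {
    for (r in seq_len(nrow(regions))) {
      idx <- (regions$start[r] + 1L):regions$end[r]
      rates[idx] <- rates[idx] * regions$rate_mult[r]
    }
  }
  sub_hit <- stats::runif(n) < rates
  if (any(sub_hit)) {
    alt <- vapply(chars[sub_hit], function(c)
      sample(setdiff(c("A", "C", "G", "T"), c), 1), "")
    chars[sub_hit] <- alt
  }
  out <- chars
  ind_hit <- which(stats::runif(n) < indel_rate)
  for (i in ind_hit) {
    if (stats::runif(1) < 0.5) out[i] <- "" # deletion
    else out[i] <- paste0(out[i], sample(c("A", "C", "G", "T"), 1)) # insertion
  }
  lens <- nchar(out)
  bmap <- c(0L, cumsum(lens))
  list(seq = paste(out, collapse = ""), bmap = bmap,
       n_events = sum(sub_hit) + length(ind_hit))
}

#' Plant duplications into a synthetic genome
#'
#' Deterministic in the config's seed. Returns the genome, a truth table
#' recording every planted copy (with its realized percent identity to the
#' progenitor), and the planted gene annotations.
#'
#' @param config an [plant_config()] object.
#' @return list of class `sd_plant` with `genome` (string-set), `truth`
#'   (tibble `chrom`, `start`, `end`, `block`, `copy`, `strand`, `pi`),
#'   `genes` (tibble as from [read_genes()]), and `config`.
#' @export
plant <- function(config) {
  stopifnot(inherits(config, "sd_plant_config"))
  set.seed(config$seed)
  blocks <- config$blocks
  if (is.null(blocks)) {
    n <- config$n_blocks
    div <- stats::runif(n, config$divergence_range[1],
                        config$divergence_range[2])
    # "divergence" is the pairwise divergence between copies; every copy is
    # mutated independently from the progenitor, so each accumulates half
    blocks <- tibble::tibble(
      length = sample(config$length_range[1]:config$length_range[2], n,
                      replace = TRUE),
      copies = sample(config$copy_range[1]:config$copy_range[2], n,
                      replace = TRUE),
      arrangement = rep(config$arrangements, length.out = n),
      sub_rate = div / 2, indel_rate = div / 20)
  }
  nb <- nrow(blocks)
  progenitors <- vapply(blocks$length, random_dna, "")
  # one backbone slot per dispersed copy, one per tandem/reverse group
  n_slots <- sum(ifelse(blocks$arrangement == "dispersed", blocks$copies, 1L))
  min_gap <- 500L
  if (config$backbone_len < (n_slots + 1L) * min_gap)
    abort("backbone too short for the requested number of planted copies")
  cuts <- sort(sample(seq(min_gap, config$backbone_len - min_gap), n_slots))
  if (any(diff(cuts) < min_gap))
    cuts <- round(seq(min_gap, config$backbone_len - min_gap,
                      length.out = n_slots))
  backbone <- random_dna(config$backbone_len)
  # assignment of (block, copy-or-group) to slots, shuffled deterministically
  units <- list()
  for (b in seq_len(nb)) {
    if (blocks$arrangement[b] == "dispersed") {
      for (cp in seq_len(blocks$copies[b]))
        units[[length(units) + 1L]] <- list(block = b, copies = cp:cp)
    } else {
      units[[length(units) + 1L]] <- list(block = b,
                                          copies = seq_len(blocks$copies[b]))
    }
  }
  units <- units[sample(length(units))]

  pieces <- character(0)
  truth <- list(); genes_out <- list()
  pos <- 0L # current genome position
  prev_cut <- 0L
  gene_cfg <- config$genes
  for (si in seq_along(units)) {
    seg <- substring(backbone, prev_cut + 1L, cuts[si])
    pieces <- c(pieces, seg)
    pos <- pos + str_len(seg)
    prev_cut <- cuts[si]
    u <- units[[si]]
    b <- u$block
    for (idx in seq_along(u$copies)) {
      cp <- u$copies[idx]
      arr <- blocks$arrangement[b]
      strand <- if (arr == "reverse-tandem" && idx %% 2 == 0) "-" else "+"
      regions <- NULL
      gcfg <- NULL
      if (!is.null(gene_cfg)) {
        gcfg <- gene_cfg[gene_cfg$block == b, , drop = FALSE]
        if (nrow(gcfg) > 0)
          regions <- tibble::tibble(start = gcfg$offset,
                                    end = gcfg$offset + gcfg$length,
                                    rate_mult = gcfg$rate_mult)
      }
      mut <- mutate_seq(progenitors[b], blocks$sub_rate[b],
                        blocks$indel_rate[b], regions)
      ctext <- mut$seq
      clen <- str_len(ctext)
      if (strand == "-") ctext <- revcomp(ctext)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        chrom = "chr1", start = pos, end = pos + clen,
        block = paste0("P", b), copy = cp, strand = strand,
        pi = percent_identity(mut$seq, progenitors[b]))
      if (!is.null(gcfg) && nrow(gcfg) > 0) {
        for (gi in seq_len(nrow(gcfg))) {
          g0 <- mut$bmap[gcfg$offset[gi] + 1L]
          g1 <- mut$bmap[gcfg$offset[gi] + gcfg$length[gi] + 1L]
          h0 <- if (is.na(gcfg$hept_offset[gi])) NA_integer_ else
            mut$bmap[gcfg$offset[gi] + gcfg$hept_offset[gi] + 1L]
          n0 <- if (is.na(gcfg$nona_offset[gi])) NA_integer_ else
            mut$bmap[gcfg$offset[gi] + gcfg$nona_offset[gi] + 1L]
          if (strand == "-") {
            tmp <- clen - g1; g1 <- clen - g0; g0 <- tmp
            if (!is.na(h0)) h0 <- clen - h0 - 7L
            if (!is.na(n0)) n0 <- clen - n0 - 9L
          }
          genes_out[[length(genes_out) + 1L]] <- tibble::tibble(
            chrom = "chr1", start = pos + g0, end = pos + g1,
            strand = strand,
            name = sprintf("G%d.%d_c%d", b, gi, cp), kind = "D",
            hept_start = if (is.na(h0)) NA_integer_ else pos + h0,
            nona_start = if (is.na(n0)) NA_integer_ else pos + n0)
        }
      }
      pieces <- c(pieces, ctext)
      pos <- pos + clen
      if (arr == "reverse-tandem" && idx < length(u$copies)) {
        sp <- random_dna(config$rt_spacer)
        pieces <- c(pieces, sp)
        pos <- pos + config$rt_spacer
      }
    }
  }
  tail_seg <- substring(backbone, prev_cut + 1L)
  pieces <- c(pieces, tail_seg)
  genome <- string_set(paste(pieces, collapse = ""), chrom = "chr1",
                       genome = "sim")
  structure(list(genome = genome,
                 truth = bind_rows(truth),
                 genes = if (length(genes_out)) bind_rows(genes_out) else
                   tibble::tibble(),
                 progenitors = progenitors, blocks = blocks,
                 config = config),
            class = "sd_plant")
}

#' Derive a genome variant with altered copy numbers
#'
#' Starting from a planted genome, inserts extra tandem copies (freshly
#' mutated from the progenitor) immediately after the last copy of a block,
#' or removes trailing copies, producing a second genome whose truth table
#' is updated accordingly.
#'
#' @param base an `sd_plant` from [plant()].
#' @param deltas named integer vector (names `P1`, `P2`, ...): copy-number
#'   change per planted block.
#' @param seed seed for the new copies' mutations.
#' @param genome_label label of the derived genome.
#' @return an `sd_plant` for the variant genome.
#' @export
pair_variant <- function(base, deltas, seed, genome_label = "sim2") {
  stopifnot(inherits(base, "sd_plant"))
  set.seed(seed)
  seqtext <- base$genome$seq[1]
  truth <- base$truth |> mutate(orig = dplyr::row_number())
  edits <- list() # (at, remove_len, insert_text, block, strand)
  for (bn in names(deltas)) {
    d <- deltas[[bn]]
    if (d == 0) next
    bt <- truth |> filter(.data$block == bn) |> arrange(.data$start)
    if (nrow(bt) == 0) abort(sprintf("unknown block %s", bn))
    bi <- as.integer(sub("^P", "", bn))
    if (d < 0) {
      if (nrow(bt) + d < 1)
        abort(sprintf("delta would remove all copies of %s", bn))
      rem <- utils::tail(bt, -d)
      for (r in seq_len(nrow(rem)))
        edits[[length(edits) + 1L]] <- list(at = rem$start[r],
                                            remove = rem$end[r] - rem$start[r],
                                            insert = "", block = bn,
                                            drop_orig = rem$orig[r])
    } else {
      anchor <- utils::tail(bt, 1)
      at <- anchor$end
      for (j in seq_len(d)) {
        mut <- mutate_seq(base$progenitors[bi], base$blocks$sub_rate[bi],
                          base$blocks$indel_rate[bi])
        edits[[length(edits) + 1L]] <- list(at = at, remove = 0L,
                                            insert = mut$seq, block = bn,
                                            pi = percent_identity(
                                              mut$seq, base$progenitors[bi]),
                                            drop_orig = NA)
      }
    }
  }
  # apply right-to-left; track coordinate shifts for truth and genes
  ord <- order(vapply(edits, function(e) e$at, 0), decreasing = TRUE)
  new_truth <- truth
  new_genes <- base$genes
  for (ei in ord) {
    e <- edits[[ei]]
    shift <- str_len(e$insert) - e$remove
    seqtext <- paste0(substring(seqtext, 1L, e$at),
                      e$insert,
                      substring(seqtext, e$at + e$remove + 1L))
    if (!is.na(e$drop_orig))
      new_truth <- new_truth |> filter(.data$orig != e$drop_orig)
    moved <- new_truth$start >= e$at
    new_truth$start[moved] <- new_truth$start[moved] + shift
    new_truth$end[moved] <- new_truth$end[moved] + shift
    if (nrow(new_genes) > 0) {
      inside <- new_genes$start >= e$at & new_genes$start < e$at + e$remove
      new_genes <- new_genes[!inside, , drop = FALSE]
      gm <- new_genes$start >= e$at
      for (cc in c("start", "end", "hept_start", "nona_start"))
        new_genes[[cc]][gm] <- new_genes[[cc]][gm] + shift
    }
    if (e$remove == 0L)
      new_truth <- bind_rows(new_truth, tibble::tibble(
        chrom = "chr1", start = e$at, end = e$at + str_len(e$insert),
        block = e$block, copy = NA_integer_, strand = "+", pi = e$pi,
        orig = NA_integer_))
  }
  new_truth <- new_truth |> select(-"orig") |> arrange(.data$start) |>
    group_by(.data$block) |> mutate(copy = dplyr::row_number()) |> ungroup()
  structure(list(genome = string_set(seqtext, chrom = "chr1",
                                     genome = genome_label),
                 truth = new_truth, genes = new_genes,
                 progenitors = base$progenitors, blocks = base$blocks,
                 config = base$config),
            class = "sd_plant")
}
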