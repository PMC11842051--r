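# Lifting block coordinates from the disembroiled genome back to the
# original genome through an edit-distance alignment.

#' Global edit-distance alignment with transcript
#'
#' Aligns `a` against `b` with unit costs and returns an edit transcript
#' (one character per alignment column: `=` match, `X` mismatch, `D`
#' consumes `a` only, `I` consumes `b` only) with deterministic tie-breaking
#' (match > mismatch > delete > insert). Short pairs are aligned by an
#' adaptive banded dynamic program; chromosome-scale pairs are first split
#' at shared unique 64-mer anchors (untangling only rewrites local bubble
#' regions, so original and disembroiled chromosomes are globally colinear)
#' and each piece is aligned exactly.
#'
#' @param a,b DNA strings (both non-empty).
#' @return an object of class `sd_transcript`: list with `ops` (the column
#'   string) and `distance`.
#' @export
align_global <- function(a, b) {
  la <- str_len(a); lb <- str_len(b)
  stopifnot(la > 0, lb > 0)
  if (max(la, lb) <= 20000L) {
    r <- cpp_align_global(a, b)
    return(structure(list(ops = r$ops, distance = r$distance),
                     class = "sd_transcript"))
  }
  w <- 64L
  anc <- cpp_anchor_matches(a, b, w)
  # thin candidate sync points to roughly one per kilobase
  keep <- logical(nrow(anc))
  last <- -1e18
  for (i in seq_len(nrow(anc))) {
    if (anc$a[i] - last >= 1000) { keep[i] <- TRUE; last <- anc$a[i] }
  }
  anc <- anc[keep, , drop = FALSE]
  # Offset-penalized colinear chaining. A unique k-mer can relocate when
  # untangling rewrites one repeat copy onto another's spelling, producing a
  # coherent run of anchors shifted by a repeat period; a count-maximizing
  # chain would keep that run and force the alignment off phase. Penalising
  # each diagonal jump by its size (the indel cost it forces) drops such
  # runs unless they out-earn the jump.
  anc <- anchor_chain(anc, bonus = w)
  cuts_a <- c(anc$a, la); cuts_b <- c(anc$b, lb)
  ops <- character(length(cuts_a))
  dist <- 0L
  pa <- 0L; pb <- 0L
  for (i in seq_along(cuts_a)) {
    ca <- cuts_a[i]; cb <- cuts_b[i]
    sa <- substring(a, pa + 1L, ca); sb <- substring(b, pb + 1L, cb)
    r <- cpp_align_global(sa, sb)
    ops[i] <- r$ops
    dist <- dist + r$distance
    pa <- ca; pb <- cb
  }
  structure(list(ops = paste(ops, collapse = ""), distance = dist),
            class = "sd_transcript")
}

# best colinear anchor chain maximizing (anchors * bonus - offset jumps)
anchor_chain <- function(anc, bonus = 64) {
  n <- nrow(anc)
  if (n == 0) return(anc)
  off <- anc$b - anc$a
  dp <- rep(bonus, n)
  prv <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (anc$b[j] >= anc$b[i]) next
      cand <- dp[j] + bonus - abs(off[i] - off[j])
      if (cand > dp[i]) { dp[i] <- cand; prv[i] <- j }
    }
  }
  i <- which.max(dp)
  chain <- integer()
  while (i > 0) { chain <- c(i, chain); i <- prv[i] }
  anc[chain, , drop = FALSE]
}

#' @export
print.sd_transcript <- function(x, ...) {
  cat(sprintf("edit transcript: %d columns, distance %d\n",
              str_len(x$ops), x$distance))
  invisible(x)
}

#' Transcript as a run-length (CIGAR-like) string
#'
#' @param transcript an `sd_transcript`.
#' @return a string such as `"120=1X3I40="`.
#' @export
transcript_cigar <- function(transcript) {
  r <- rle(strsplit(transcript$ops, "")[[1]])
  paste0(r$lengths, r$values, collapse = "")
}

# boundary map from b-coordinates (0..lb) to a-coordinates; a boundary
# inside an inserted run maps to the run's left edge
transcript_bmap <- function(transcript) {
  ops <- strsplit(transcript$ops, "")[[1]]
  di <- ops %in% c("=", "X", "D")
  dj <- ops %in% c("=", "X", "I")
  i_after <- cumsum(di)
  lb <- sum(dj)
  omap <- integer(lb + 1L)
  omap[1L + cumsum(dj)[dj]] <- i_after[dj]
  omap
}

#' Lift block instances through an edit transcript
#'
#' Maps instance boundaries from the disembroiled coordinates (the `b` side
#' of the transcript) to original coordinates (the `a` side); boundaries
#' inside an inserted run map to its left edge, which keeps the half-open
#' tiling exact. Optionally recomputes each instance's percent identity
#' against its block consensus.
#'
#' @param instances instance tibble (one chromosome's worth; columns as in
#'   an `sd_decomposition`).
#' @param transcript the `sd_transcript` from
#'   `align_global(original_chrom, disembroiled_chrom)`.
#' @param original the original chromosome sequence (optional; enables PI
#'   recomputation).
#' @param consensus named character vector of block consensus sequences
#'   (optional, with `original`).
#' @return the lifted instance tibble, still ordered and non-overlapping.
#' @export
lift_instances <- function(instances, transcript, original = NULL,
                           consensus = NULL) {
  if (nrow(instances) == 0) return(instances)
  omap <- transcript_bmap(transcript)
  lb <- length(omap) - 1L
  if (any(instances$end > lb) || any(instances$start < 0))
    abort("instance coordinates outside the transcript")
  out <- instances
  out$start <- omap[instances$start + 1L]
  out$end <- omap[instances$end + 1L]
  out <- out |> filter(.data$end > .data$start)
  if (any(diff(out$start) < 0) ||
      any(out$start[-1] < out$end[-nrow(out)]))
    abort("lift produced overlapping instances; corrupted transcript")
  if (!is.null(original) && !is.null(consensus)) {
    out$pct_identity <- vapply(seq_len(nrow(out)), function(i) {
      x <- out[i, ]
      txt <- substring(original, x$start + 1L, x$end)
      ref <- substring(consensus[[x$block_id]], x$cons_start + 1L, x$cons_end)
      if (x$strand == "-") txt <- revcomp(txt)
      percent_identity(txt, ref)
    }, 0)
  }
  out
}

#' Lift a whole decomposition to original coordinates
#'
#' Aligns every original chromosome against its disembroiled counterpart
#' and lifts all instances.
#'
#' @param decomp an `sd_decomposition` in disembroiled coordinates.
#' @param u the `sd_untangle` the decomposition came from.
#' @return an `sd_decomposition` with `space = "original"`, plus a
#'   `transcripts` element (one `sd_transcript` per chromosome).
#' @export
lift_decomposition <- function(decomp, u) {
  stopifnot(inherits(u, "sd_untangle"), decomp$space == "disembroiled")
  cons <- stats::setNames(decomp$blocks$consensus, decomp$blocks$block_id)
  orig <- u$original
  dis <- u$strings
  insts <- list(); trs <- list()
  chroms <- orig |> mutate(length = str_len(.data$seq)) |>
    select("genome", "chrom", "length")
  for (i in seq_len(nrow(orig))) {
    key <- paste(orig$genome[i], orig$chrom[i])
    a <- orig$seq[i]
    b <- dis$seq[dis$genome == orig$genome[i] & dis$chrom == orig$chrom[i]]
    tr <- if (identical(a, b)) {
      structure(list(ops = strrep("=", str_len(a)), distance = 0L),
                class = "sd_transcript")
    } else align_global(a, b)
    trs[[key]] <- tr
    ins <- decomp$instances |>
      filter(.data$genome == orig$genome[i], .data$chrom == orig$chrom[i])
    insts[[key]] <- lift_instances(ins, tr, original = a, consensus = cons)
  }
  out <- new_decomposition(blocks = decomp$blocks,
                           instances = bind_rows(insts) |>
                             arrange(.data$genome, .data$chrom, .data$start),
                           chroms = chroms, k = decomp$k, space = "original")
  out$blocks$n_instances <- vapply(out$blocks$block_id, function(b)
    sum(out$instances$block_id == b), 0L)
  out$transcripts <- trs
  out
}
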