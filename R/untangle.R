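# Iterative disembroiling: repeat bubble collapsing at increasing k until
# the graph at K is free of collapsible bubbles.

#' Parameters for repeat untangling
#'
#' @param K minimum block size; the final (largest) k-mer size. Commonly
#'   1-2 kb for segmental-duplication analysis at locus scale.
#' @param k_init initial k-mer size (default 21).
#' @param sim_strong similarity threshold for simple bubbles (default 0.90).
#' @param sim_weak similarity threshold for complex bubbles (default 0.65).
#' @param bubble_max complexity bound for complex bubbles (default 4).
#' @param k_schedule strictly increasing k-mer sizes ending at `K`; by
#'   default geometric doubling from `k_init` capped at `K`.
#' @param min_block_len instances shorter than this are folded into
#'   non-repetitive segments at block inference (default `K`).
#' @param max_scans safety cap on collapse scans per k-mer size.
#' @param strands passed to [build_cdbg()]: `"both"` (bidirected canonical
#'   graph, the default) or `"forward"`.
#' @return a list of class `sd_params`.
#' @export
untangle_params <- function(K, k_init = 21, sim_strong = 0.90,
                            sim_weak = 0.65, bubble_max = 4,
                            k_schedule = NULL, min_block_len = K,
                            max_scans = 50, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (missing(K)) abort("K (the minimum block size) is required")
  stopifnot(K > k_init, k_init >= 3, bubble_max >= 2,
            sim_weak > 0, sim_weak <= sim_strong, sim_strong <= 1)
  if (is.null(k_schedule)) {
    k_schedule <- k_init
    while (utils::tail(k_schedule, 1) * 2 < K)
      k_schedule <- c(k_schedule, utils::tail(k_schedule, 1) * 2)
    k_schedule <- c(k_schedule, K)
  }
  if (any(diff(k_schedule) <= 0) || utils::tail(k_schedule, 1) != K ||
      k_schedule[1] != k_init)
    abort("k_schedule must increase strictly from k_init to K")
  structure(list(K = as.integer(K), k_init = as.integer(k_init),
                 sim_strong = sim_strong, sim_weak = sim_weak,
                 bubble_max = as.integer(bubble_max),
                 k_schedule = as.integer(k_schedule),
                 min_block_len = as.integer(min_block_len),
                 max_scans = as.integer(max_scans), strands = strands),
            class = "sd_params")
}

#' @export
print.sd_params <- function(x, ...) {
  cat(sprintf("untangle parameters: k %s; sim_strong %.2f, sim_weak %.2f, bubble_max %d, min_block_len %d\n",
              paste(x$k_schedule, collapse = " -> "),
              x$sim_strong, x$sim_weak, x$bubble_max, x$min_block_len))
  invisible(x)
}

#' Untangle a genome: turn inexact repeats into exact repeats
#'
#' For each k in the schedule, the condensed de Bruijn graph is rebuilt and
#' collapsible bubbles are collapsed until none remains, then k is advanced.
#' The result is the disembroiled genome together with its graph at K, in
#' which every repeated block appears as a set of character-identical
#' substrings.
#'
#' @param ss string-set tibble.
#' @param params an [untangle_params()] object.
#' @param verbose print one line per scan.
#' @return an object of class `sd_untangle`: list with `strings` (the
#'   disembroiled string-set), `graph` (the `sd_cdbg` at K), `log` (one row
#'   per scan: k, bubbles found, collapsible, rewrites, genome length),
#'   `params`, and `original` (the input string-set).
#' @export
untangle <- function(ss, params, verbose = FALSE) {
  validate_string_set(ss)
  stopifnot(inherits(params, "sd_params"))
  ss0 <- ss
  log <- list()
  g <- NULL
  for (k in params$k_schedule) {
    prev_distinct <- Inf
    for (scan in seq_len(params$max_scans)) {
      g <- build_cdbg(ss, k, strands = params$strands)
      # distinct k-mers in the genome (edges partition them); every
      # productive collapse strictly reduces this, so a scan that fails to
      # is churning and the fixpoint at this k has been reached
      distinct <- sum(g$edges$length) - (k - 1L) * nrow(g$edges)
      if (distinct >= prev_distinct) break
      prev_distinct <- distinct
      res <- collapse_scan(ss, g, params)
      log[[length(log) + 1L]] <- tibble::tibble(
        k = k, scan = scan, bubbles = res$found,
        collapsible = res$collapsible, rewrites = res$rewrites,
        genome_length = sum(str_len(res$strings$seq)))
      if (verbose)
        cat(sprintf("k=%d scan=%d bubbles=%d collapsible=%d rewrites=%d len=%d\n",
                    k, scan, res$found, res$collapsible, res$rewrites,
                    utils::tail(log, 1)[[1]]$genome_length))
      if (res$rewrites == 0L) break
      ss <- res$strings
    }
  }
  if (g$k != params$K) g <- build_cdbg(ss, params$K, strands = params$strands)
  structure(list(strings = ss, graph = g, log = bind_rows(log),
                 params = params, original = ss0), class = "sd_untangle")
}

#' @export
print.sd_untangle <- function(x, ...) {
  cat(sprintf("untangled genome: %d chromosome(s), %d bp; %d rewrites over %d scans\n",
              nrow(x$strings), sum(str_len(x$strings$seq)),
              sum(x$log$rewrites), nrow(x$log)))
  invisible(x)
}
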