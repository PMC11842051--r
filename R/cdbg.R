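# Condensed de Bruijn graph of a string-set, with the walks recording how
# each chromosome traverses it.

# Split chromosomes at N runs. Segments of length >= k take part in graph
# construction; shorter segments (including short leading/trailing pieces)
# are carried as unrepresented clips and re-attached at spell/lift time.
split_segments <- function(ss, k) {
  res <- purrr::pmap(ss, function(genome, chrom, seq) {
    L <- str_len(seq)
    m <- gregexpr("[ACGT]+", seq)[[1]]
    if (m[1] == -1) {
      return(list(segs = tibble::tibble(genome = character(), chrom = character(),
                                        offset = integer(), seq = character()),
                  clips = tibble::tibble(genome = genome, chrom = chrom,
                                         start = 0L, end = L)))
    }
    st <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    ok <- len >= k
    seg_seq <- if (any(ok))
      substring(seq, st[ok] + 1L, st[ok] + len[ok]) else character()
    segs <- tibble::tibble(genome = rep(genome, sum(ok)),
                           chrom = rep(chrom, sum(ok)), offset = st[ok],
                           seq = seg_seq)
    clips <- tibble::tibble(genome = rep(genome, sum(!ok)),
                            chrom = rep(chrom, sum(!ok)),
                            start = st[!ok], end = st[!ok] + len[!ok])
    list(segs = segs, clips = clips)
  })
  list(segs = bind_rows(purrr::map(res, "segs")),
       clips = bind_rows(purrr::map(res, "clips")))
}

#' Build the condensed de Bruijn graph of a string-set
#'
#' The graph is bidirected over canonical k-mers: an edge and its reverse
#' complement are one object, so reverse-complement repeats appear as
#' multiplicity-2 edges. Every non-branching path is condensed into a single
#' labelled edge (with breakpoints at chromosome termini so that each
#' chromosome walk is a sequence of whole edges). k-mers containing N are
#' skipped, which splits walks at N runs.
#'
#' @param ss string-set tibble (see [string_set()]).
#' @param k k-mer size, `>= 3`.
#' @param strands `"both"` (default) builds the bidirected graph over
#'   canonical k-mers, so reverse-complement repeats are detected;
#'   `"forward"` builds the plain directed graph of the forward strands
#'   only (useful for small pedagogical examples at tiny k, where
#'   reverse-complement aliasing of short k-mers obscures the structure).
#' @return an object of class `sd_cdbg`: a list with
#'   * `k`;
#'   * `edges`: tibble `edge_id`, `label` (spelled sequence, length >= k),
#'     `length`, `from`, `to` (signed canonical vertex ids), `self_rc`,
#'     `mult` (total traversal count);
#'   * `vertices`: tibble of branching (k-1)-mers;
#'   * `walks`: tibble `genome`, `chrom`, `offset` (chromosome coordinate of
#'     the segment start), `steps` (list of signed edge ids; a negative step
#'     traverses the edge in reverse complement);
#'   * `clips`: chromosome stretches too short to carry a full k-mer;
#'   * `strings`: the input string-set.
#' @examples
#' g <- build_cdbg(string_set("ACGTTTGACCA"), k = 5)
#' g$edges
#' @export
build_cdbg <- function(ss, k, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  validate_string_set(ss)
  if (k < 3) abort("k must be >= 3")
  sp <- split_segments(ss, k)
  if (nrow(sp$segs) == 0) abort("all sequences are shorter than k")
  raw <- cpp_build_cdbg(sp$segs$seq, k, strands == "both")
  edges <- tibble::as_tibble(raw$edges)
  walks <- sp$segs |>
    select("genome", "chrom", "offset") |>
    mutate(steps = lapply(raw$walks, as.integer),
           seg_len = str_len(sp$segs$seq))
  mult <- tabulate(abs(unlist(walks$steps)), nbins = nrow(edges))
  edges$mult <- as.integer(mult)
  structure(list(k = k, strands = strands, edges = edges,
                 vertices = tibble::as_tibble(raw$vertices),
                 walks = walks, clips = sp$clips, strings = ss),
            class = "sd_cdbg")
}

#' @export
print.sd_cdbg <- function(x, ...) {
  cat(sprintf("condensed de Bruijn graph (k = %d): %d edges, %d vertices, %d walk segments\n",
              x$k, nrow(x$edges), nrow(x$vertices), nrow(x$walks)))
  invisible(x)
}

# signed source / sink vertex of a directed step
step_from <- function(g, step) {
  out <- integer(length(step))
  pos <- step > 0
  out[pos] <- g$edges$from[step[pos]]
  out[!pos] <- -g$edges$to[-step[!pos]]
  out
}
step_to <- function(g, step) {
  out <- integer(length(step))
  pos <- step > 0
  out[pos] <- g$edges$to[step[pos]]
  out[!pos] <- -g$edges$from[-step[!pos]]
  out
}

# normalise a signed vertex id: a palindromic vertex equals its own twin
norm_vertex <- function(g, v) {
  pal <- g$vertices$palindromic[abs(v)]
  ifelse(pal, abs(v), v)
}

# spell a sequence of signed steps with (k-1)-overlaps
spell_steps <- function(g, steps) {
  if (length(steps) == 0) return("")
  labs <- g$edges$label[abs(steps)]
  labs[steps < 0] <- revcomp(labs[steps < 0])
  if (length(labs) == 1) return(labs)
  paste0(labs[1], paste(substring(labs[-1], g$k), collapse = ""))
}

# start offsets of each step within the spelled walk (0-based)
step_offsets <- function(g, steps) {
  if (length(steps) == 0) return(integer())
  len <- g$edges$length[abs(steps)]
  c(0L, cumsum(len[-length(len)] - (g$k - 1L)))
}

#' Spell a walk back into its chromosome sequence
#'
#' Inverse of [build_cdbg()] on the region between clips: consecutive steps
#' overlap by k-1 characters; reverse-orientation steps contribute the
#' reverse complement of the edge label.
#'
#' @param g an `sd_cdbg`.
#' @param steps integer vector of signed edge ids (one walk).
#' @return the spelled DNA string.
#' @export
spell_walk <- function(g, steps) {
  if (length(steps) > 1) {
    tos <- step_to(g, steps[-length(steps)])
    frs <- step_from(g, steps[-1])
    if (!all(norm_vertex(g, tos) == norm_vertex(g, frs)))
      abort("consecutive steps do not share a vertex")
  }
  spell_steps(g, steps)
}

#' Per-genome edge multiplicities
#'
#' @param g an `sd_cdbg`.
#' @return tibble `edge_id`, `genome`, `mult` (0 rows omitted).
#' @export
edge_multiplicities <- function(g) {
  w <- g$walks
  if (nrow(w) == 0) return(tibble::tibble(edge_id = integer(),
                                          genome = character(), mult = integer()))
  df <- tibble::tibble(
    genome = rep(w$genome, lengths(w$steps)),
    edge_id = abs(unlist(w$steps)))
  df |> dplyr::count(.data$edge_id, .data$genome, name = "mult") |>
    arrange(.data$edge_id, .data$genome)
}

#' Export a graph in GraphViz DOT format
#'
#' Edge labels read `id, length (multiplicity)`; optionally block letters are
#' used instead of raw edge ids.
#'
#' @param g an `sd_cdbg`.
#' @param path output file; `NULL` returns the DOT text.
#' @param edge_names optional named character vector mapping `edge_id` to a
#'   display name (e.g. block letters).
#' @return the DOT text, invisibly if written to a file.
#' @export
cdbg_to_dot <- function(g, path = NULL, edge_names = NULL) {
  e <- g$edges
  nm <- as.character(e$edge_id)
  if (!is.null(edge_names)) {
    hit <- nm %in% names(edge_names)
    nm[hit] <- edge_names[nm[hit]]
  }
  lines <- c("digraph cdbg {",
             sprintf("  %d -> %d [label=\"%s, %d (%d)\"];",
                     abs(e$from), abs(e$to), nm, e$length, e$mult),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
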