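# Bubble detection and collapsing.
#
# A bubble is a pair of walk subpaths that start at the same vertex, end at
# the same vertex and share no other vertices (nor edges). Collapsing
# rewrites every genomic occurrence of the path with the shorter spelling
# into the spelling of the other path, turning similar regions into
# identical ones.

# all distinct directed subpaths of <= max_len steps occurring in the walks,
# together with their reverse complements
walk_subpaths <- function(g, max_len) {
  acc <- new.env(parent = emptyenv())
  use_rc <- !identical(g$strands, "forward")
  for (s in g$walks$steps) {
    m <- length(s)
    if (m == 0) next
    for (i in seq_len(m)) {
      for (l in seq_len(min(max_len, m - i + 1))) {
        p <- s[i:(i + l - 1L)]
        assign(paste(p, collapse = ","), p, envir = acc)
        if (use_rc) {
          rp <- -rev(p)
          assign(paste(rp, collapse = ","), rp, envir = acc)
        }
      }
    }
  }
  as.list(acc)
}

path_spell <- function(g, p) spell_steps(g, p)

path_interior <- function(g, p) {
  if (length(p) < 2) return(integer())
  abs(step_to(g, p[-length(p)]))
}

#' Find simple and short complex bubbles
#'
#' Returns every unordered pair of walk subpaths that forms a bubble of
#' complexity at most `bubble_max` (a 1-1 bubble is *simple*; complexity is
#' the larger path edge count). Each pair is reported once; `path1` is the
#' path with the shorter spelling (on ties, the lexicographically larger
#' spelling, so that `path2` is always the surviving spelling under
#' collapse).
#'
#' @param g an `sd_cdbg`.
#' @param bubble_max complexity bound for complex bubbles (default 4).
#' @return tibble with columns `source`, `sink` (signed vertex ids), `path1`,
#'   `path2` (list columns of signed steps), `n1`, `n2`, `complexity`,
#'   `simple`, `mult1`, `mult2`, `spell1`, `spell2`, ordered by (source,
#'   sink, spelling).
#' @export
find_bubbles <- function(g, bubble_max = 4) {
  paths <- walk_subpaths(g, bubble_max)
  if (length(paths) == 0) return(empty_bubbles())
  pid <- names(paths)
  np <- length(paths)
  first <- vapply(paths, `[`, 0L, 1L)
  last <- vapply(paths, function(p) p[length(p)], 0L)
  src <- norm_vertex(g, step_from(g, first))
  snk <- norm_vertex(g, step_to(g, last))
  # per-path precomputation (edges, interiors, self-validity)
  edg <- lapply(paths, abs)
  intr <- lapply(paths, function(p) path_interior(g, p))
  selfok <- !vapply(intr, anyDuplicated, 0L) > 0
  grp <- split(seq_len(np), paste(src, snk))
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (idx in grp) {
    if (length(idx) < 2) next
    idx <- idx[selfok[idx]]
    if (length(idx) < 2) next
    for (ai in seq_along(idx)) {
      a <- idx[ai]
      ea <- edg[[a]]; ia <- intr[[a]]
      ends <- abs(c(src[a], snk[a]))
      if (any(ia %in% ends)) next
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        b <- idx[bi]
        q <- paths[[b]]
        if (any(edg[[b]] %in% ea)) next
        iq <- intr[[b]]
        if (length(iq) && (any(iq %in% ia) || any(iq %in% ends))) next
        # one id for the pair and for its reverse-complement twin
        p <- paths[[a]]
        k1 <- paste(sort(c(pid[a], pid[b]), method = "radix"),
                    collapse = ";")
        rp <- paste(-rev(p), collapse = ","); rq <- paste(-rev(q), collapse = ",")
        k2 <- paste(sort(c(rp, rq), method = "radix"), collapse = ";")
        key <- if (identical(g$strands, "forward")) k1 else
          sort(c(k1, k2), method = "radix")[1]
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        rows[[length(rows) + 1L]] <- list(a = a, b = b)
      }
    }
  }
  if (length(rows) == 0) return(empty_bubbles())
  info <- list(path = paths, src = src, snk = snk)
  emult <- g$edges$mult
  out <- purrr::map(rows, function(r) {
    p <- info$path[[r$a]]; q <- info$path[[r$b]]
    sp <- path_spell(g, p); sq <- path_spell(g, q)
    # path1 carries the spelling that would be rewritten away; on equal
    # lengths the survivor is the lexicographically smaller canonical
    # spelling (orientation-invariant, hence deterministic)
    cs <- function(s) sort(c(s, revcomp(s)), method = "radix")[1]
    if (str_len(sp) > str_len(sq) ||
        (str_len(sp) == str_len(sq) &&
           identical(sort(c(cs(sp), cs(sq)), method = "radix")[1], cs(sp)) &&
           cs(sp) != cs(sq))) {
      tmp <- p; p <- q; q <- tmp
      tmp <- sp; sp <- sq; sq <- tmp
    }
    tibble::tibble(
      source = info$src[r$a], sink = info$snk[r$a],
      path1 = list(p), path2 = list(q),
      n1 = length(p), n2 = length(q),
      complexity = max(length(p), length(q)),
      simple = length(p) == 1 && length(q) == 1,
      mult1 = min(emult[abs(p)]), mult2 = min(emult[abs(q)]),
      spell1 = sp, spell2 = sq)
  }) |> bind_rows()
  out |> arrange(abs(.data$source), abs(.data$sink),
                 str_len(.data$spell1), .data$spell1, .data$spell2)
}

empty_bubbles <- function() {
  tibble::tibble(source = integer(), sink = integer(),
                 path1 = list(), path2 = list(),
                 n1 = integer(), n2 = integer(), complexity = integer(),
                 simple = logical(), mult1 = integer(), mult2 = integer(),
                 spell1 = character(), spell2 = character())
}

# Both paths of a bubble spell identical (k-1)-mer flanks. At small k the
# flanks are legitimate alignment context, but at large k they dominate the
# comparison and make any two parallel paths look similar (two unrelated
# 3 kb insertions share 2 x 1999 bp of flank at K = 2000). The similarity
# comparison therefore keeps at most 50 bp of flank context per side,
# always retaining at least 20 bp of the shorter spelling.
trim_flank_context <- function(s1, s2, k, keep = 50L) {
  t <- (k - 1L) - keep
  if (t <= 0L) return(c(s1, s2))
  t <- min(t, max(0L, (min(str_len(s1), str_len(s2)) - 20L) %/% 2L))
  c(substring(s1, t + 1L, str_len(s1) - t),
    substring(s2, t + 1L, str_len(s2) - t))
}

#' Is a bubble collapsible?
#'
#' A simple bubble is collapsible when its two edge spellings have percent
#' identity above `sim_strong`; a complex bubble when its two path spellings
#' have percent identity above `sim_weak`. Spellings enter the comparison
#' with their shared terminal (k-1)-mers trimmed to at most 50 bp of
#' context per side, so that large-k flanks cannot make dissimilar
#' interiors look alike.
#'
#' @param bubble one row of [find_bubbles()] output.
#' @param g the `sd_cdbg` the bubble was found in.
#' @param params an [untangle_params()] object (only the similarity
#'   thresholds are used).
#' @return logical.
#' @export
is_collapsible <- function(bubble, g, params) {
  k <- if (!is.null(g)) g$k else params$k_init
  sp <- trim_flank_context(bubble$spell1[[1]], bubble$spell2[[1]], k)
  pi <- percent_identity(sp[1], sp[2])
  thr <- if (isTRUE(bubble$simple[[1]])) params$sim_strong else params$sim_weak
  pi > thr
}

# per-scan context: precomputed walk offsets, a step-value occurrence index,
# and fast chromosome sequence lookup
scan_context <- function(g) {
  offs <- lapply(g$walks$steps, function(s) step_offsets(g, s))
  nst <- lengths(g$walks$steps)
  wid <- rep.int(seq_along(nst), nst)
  pos <- sequence(nst)
  val <- unlist(g$walks$steps, use.names = FALSE)
  spl <- split(seq_along(val), val)
  seqs <- stats::setNames(as.list(g$strings$seq),
                          paste(g$strings$genome, g$strings$chrom))
  list(offs = offs, wid = wid, pos = pos, spl = spl, seqs = seqs)
}

# occurrences of directed path p (or its reverse complement) in the walks:
# data.frame(walk, first, last, orient)
path_occurrences <- function(g, p, ctx = NULL) {
  if (is.null(ctx)) ctx <- scan_context(g)
  rp <- -rev(p)
  l <- length(p)
  self_rc <- identical(p, rp) || identical(g$strands, "forward")
  find1 <- function(pat) {
    cand <- ctx$spl[[as.character(pat[1])]]
    if (is.null(cand)) return(NULL)
    hits_w <- integer(); hits_i <- integer()
    for (ci in cand) {
      w <- ctx$wid[ci]; i <- ctx$pos[ci]
      s <- g$walks$steps[[w]]
      if (i + l - 1L > length(s)) next
      if (l == 1L || all(s[i:(i + l - 1L)] == pat)) {
        hits_w <- c(hits_w, w); hits_i <- c(hits_i, i)
      }
    }
    list(w = hits_w, i = hits_i)
  }
  f <- find1(p)
  r <- if (self_rc) list(w = integer(), i = integer()) else find1(rp)
  n <- length(f$w) + length(r$w)
  if (n == 0)
    return(data.frame(walk = integer(), first = integer(), last = integer(),
                      orient = integer()))
  data.frame(walk = c(f$w, r$w), first = c(f$i, r$i),
             last = c(f$i, r$i) + l - 1L,
             orient = rep(c(1L, -1L), c(length(f$w), length(r$w))))
}

# genomic interval of a step range within a walk (0-based half-open,
# chromosome coordinates)
steps_interval <- function(g, walk_idx, first, last) {
  w <- g$walks[walk_idx, ]
  s <- w$steps[[1]]
  offs <- step_offsets(g, s)
  len <- g$edges$length[abs(s)]
  c(w$offset + offs[first], w$offset + offs[last] + len[last])
}

# Plan genome rewrites for occurrences of the bubble's path1. The rewritten
# interval excludes the preserved left-flank (k-1)-mer, so occurrences that
# only touch at a shared vertex do not conflict.
#
# In strict mode (used by the scan driver) the bubble is applied only when
# (i) every edge of path1 is used exclusively inside path1 occurrences and
# (ii) all occurrences can be rewritten without conflicting with earlier
# claims. Together these guarantee that each applied collapse strictly
# reduces the number of distinct k-mers in the genome, which is what makes
# the disembroiling fixpoint terminate: every k-mer of path1's edges
# disappears and no new k-mer is created (the replacement's k-mers,
# including those spanning the junctions, are all k-mers of path2).
# Returns tibble(genome, chrom, start, end, replacement) or NULL.
plan_bubble_rewrites <- function(g, bubble, claimed, strict = TRUE,
                                 ctx = NULL) {
  if (is.null(ctx)) ctx <- scan_context(g)
  p1 <- bubble$path1[[1]]
  rep_f <- bubble$spell2[[1]]
  rep_r <- revcomp(rep_f)
  exp_f <- bubble$spell1[[1]]
  exp_r <- revcomp(exp_f)
  km1 <- g$k - 1L
  occ <- path_occurrences(g, p1, ctx)
  if (nrow(occ) == 0) return(NULL)
  if (strict) {
    # at least one path1 edge must disappear completely (all its uses lie
    # inside the rewritten occurrences): then the rewrite strictly reduces
    # the number of distinct k-mers, because that edge's k-mers vanish and
    # the replacement introduces none (its k-mers, junctions included, are
    # all k-mers of path2)
    use <- table(abs(p1))
    vanishes <- any(g$edges$mult[as.integer(names(use))] ==
                      as.integer(use) * nrow(occ))
    if (!vanishes) return(NULL)
  }
  plans <- list()
  local_claims <- list()
  wgenome <- g$walks$genome; wchrom <- g$walks$chrom; woffset <- g$walks$offset
  elen <- g$edges$length
  for (i in seq_len(nrow(occ))) {
    wi <- occ$walk[i]
    s <- g$walks$steps[[wi]]
    o <- ctx$offs[[wi]]
    iv <- c(woffset[wi] + o[occ$first[i]],
            woffset[wi] + o[occ$last[i]] + elen[abs(s[occ$last[i]])])
    key <- paste(wgenome[wi], wchrom[wi])
    cl <- claimed[[key]]
    core <- c(iv[1] + km1, iv[2]) # left flank is preserved by the rewrite
    if (!is.null(cl) && any(core[1] < cl[, 2] & core[2] > cl[, 1])) {
      if (strict) return(NULL) else next
    }
    have <- substring(ctx$seqs[[key]], iv[1] + 1L, iv[2])
    expect <- if (occ$orient[i] == 1L) exp_f else exp_r
    if (!identical(have, expect))
      abort("internal error: walk spelling out of sync with genome text")
    local_claims[[length(local_claims) + 1L]] <- list(key = key, core = core)
    # in both orientations the occurrence text and the replacement share
    # their first k-1 characters (the source vertex label, or the reverse
    # complement of the sink label), so the left flank can stay in place
    repl <- substring(if (occ$orient[i] == 1L) rep_f else rep_r, g$k)
    plans[[length(plans) + 1L]] <- list(
      genome = wgenome[wi], chrom = wchrom[wi], start = core[1],
      end = core[2], replacement = repl)
  }
  if (length(plans) == 0) return(NULL)
  # commit claims only once the whole bubble is accepted
  for (lc in local_claims)
    claimed[[lc$key]] <- rbind(claimed[[lc$key]], lc$core)
  plans
}

apply_rewrites <- function(ss, plans) {
  if (is.null(plans) || nrow(plans) == 0) return(ss)
  for (gc in unique(paste(plans$genome, plans$chrom, sep = "\r"))) {
    parts <- strsplit(gc, "\r")[[1]]
    pl <- plans |> filter(.data$genome == parts[1], .data$chrom == parts[2]) |>
      arrange(.data$start)
    i <- which(ss$genome == parts[1] & ss$chrom == parts[2])
    s <- ss$seq[i]
    pieces <- character(2 * nrow(pl) + 1)
    prev <- 0L
    for (r in seq_len(nrow(pl))) {
      pieces[2 * r - 1] <- substring(s, prev + 1L, pl$start[r])
      pieces[2 * r] <- pl$replacement[r]
      prev <- pl$end[r]
    }
    pieces[2 * nrow(pl) + 1] <- substring(s, prev + 1L)
    ss$seq[i] <- paste(pieces, collapse = "")
  }
  ss
}

#' Collapse one bubble
#'
#' Rewrites every genomic occurrence of the bubble's `path1` spelling (in
#' either orientation) into the `path2` spelling, then rebuilds the graph at
#' the same k so that multiplicities are recomputed from the walks.
#' Occurrences overlapping an already rewritten region within this call are
#' skipped (ties between overlapping occurrences are resolved left to
#' right).
#'
#' @param ss the string-set the graph was built from.
#' @param g the `sd_cdbg`.
#' @param bubble one row of [find_bubbles()] output for `g`.
#' @return list with the rewritten `strings` and the rebuilt `graph`. If the
#'   bubble no longer matches the graph a condition of class
#'   `sdblocks_stale` is signalled; the caller should rescan.
#' @export
collapse_bubble <- function(ss, g, bubble) {
  ok <- all(abs(c(bubble$path1[[1]], bubble$path2[[1]])) <= nrow(g$edges)) &&
    identical(path_spell(g, bubble$path1[[1]]), bubble$spell1[[1]]) &&
    identical(path_spell(g, bubble$path2[[1]]), bubble$spell2[[1]])
  if (!ok)
    abort("bubble is stale: graph has changed since it was found",
          class = "sdblocks_stale")
  claimed <- new.env(parent = emptyenv())
  plans <- plan_bubble_rewrites(g, bubble, claimed, strict = FALSE)
  if (!is.null(plans)) plans <- bind_rows(lapply(plans, tibble::as_tibble))
  ss2 <- apply_rewrites(ss, plans)
  list(strings = ss2, graph = build_cdbg(ss2, g$k, strands = g$strands))
}

# one scan at fixed k: find all collapsible bubbles and rewrite as many
# occurrences as possible (claims prevent conflicting surgery); returns the
# new strings and counts
collapse_scan <- function(ss, g, params) {
  bub <- find_bubbles(g, params$bubble_max)
  n_found <- nrow(bub)
  if (n_found == 0)
    return(list(strings = ss, found = 0L, collapsible = 0L, rewrites = 0L))
  # collapsibility test with an early-exit distance bound: a pair is
  # similar iff distance < (1 - threshold) * max(lengths), computed on the
  # flank-trimmed spellings
  thr <- ifelse(bub$simple, params$sim_strong, params$sim_weak)
  keep <- vapply(seq_len(n_found), function(i) {
    sp <- trim_flank_context(bub$spell1[i], bub$spell2[i], g$k)
    m <- max(str_len(sp[1]), str_len(sp[2]))
    if (m == 0) return(TRUE)
    bound <- floor((1 - thr[i]) * m) # need distance strictly below this + 1
    if (bound < 0) return(FALSE)
    d <- cpp_edit_bounded(sp[1], sp[2], bound)
    1 - d / m > thr[i]
  }, TRUE)
  bub <- bub[keep, ]
  if (nrow(bub) == 0)
    return(list(strings = ss, found = n_found, collapsible = 0L, rewrites = 0L))
  # simple bubbles first, then smaller rewrites; deterministic tie-break
  # (claims make earlier bubbles win conflicts, so small local fixes take
  # precedence over large rewrites)
  ord <- order(!bub$simple, str_len(bub$spell1) + str_len(bub$spell2),
               bub$spell1, bub$spell2)
  bub <- bub[ord, ]
  claimed <- new.env(parent = emptyenv())
  ctx <- scan_context(g)
  all_plans <- list()
  for (i in seq_len(nrow(bub))) {
    brow <- list(path1 = bub$path1[i], path2 = bub$path2[i],
                 spell1 = bub$spell1[i], spell2 = bub$spell2[i])
    pl <- plan_bubble_rewrites(g, brow, claimed, strict = TRUE, ctx = ctx)
    if (!is.null(pl)) all_plans <- c(all_plans, pl)
  }
  if (length(all_plans) == 0)
    return(list(strings = ss, found = n_found, collapsible = nrow(bub),
                rewrites = 0L))
  plans <- bind_rows(lapply(all_plans, tibble::as_tibble))
  list(strings = apply_rewrites(ss, plans), found = n_found,
       collapsible = nrow(bub), rewrites = nrow(plans))
}
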