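# Independent brute-force oracles used to cross-check the implementation.

# full quadratic edit-distance dynamic program
dp_edit <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + (A[i] != B[j]),
                             D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  D[n + 1, m + 1]
}

dp_pi <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(1)
  1 - dp_edit(a, b) / max(nchar(a), nchar(b))
}

rc_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# overlapping substring occurrence count of pattern in subject
count_occ <- function(subject, pattern) {
  L <- nchar(pattern); n <- nchar(subject)
  if (n < L) return(0L)
  sum(substring(subject, 1:(n - L + 1), L:n) == pattern)
}

# occurrences of an edge label across both strands of a string-set
oracle_label_mult <- function(ss, label) {
  cnt <- 0L
  rl <- rc_chr(label)
  for (s in ss$seq) {
    cnt <- cnt + count_occ(s, label)
    if (rl != label) cnt <- cnt + count_occ(s, rl)
  }
  cnt
}

# quadratic independent bubble enumeration: all pairs of walk subpaths (and
# their reverse complements) with shared endpoints, disjoint edges and
# interiors, complexity <= bmax; returns a set of canonical pair ids
oracle_bubble_ids <- function(g, bmax) {
  fwd_only <- identical(g$strands, "forward")
  subs <- list()
  for (s in g$walks$steps) {
    m <- length(s)
    for (i in seq_len(m)) {
      for (l in seq_len(min(bmax, m - i + 1))) {
        p <- s[i:(i + l - 1)]
        subs[[length(subs) + 1]] <- p
        if (!fwd_only) subs[[length(subs) + 1]] <- -rev(p)
      }
    }
  }
  pid <- vapply(subs, paste, "", collapse = ",")
  subs <- subs[!duplicated(pid)]
  pid <- pid[!duplicated(pid)]
  v_from <- function(d) if (d > 0) g$edges$from[d] else -g$edges$to[-d]
  v_to <- function(d) if (d > 0) g$edges$to[d] else -g$edges$from[-d]
  nv <- function(v) if (g$vertices$palindromic[abs(v)]) abs(v) else v
  ids <- character()
  n <- length(subs)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      p <- subs[[i]]; q <- subs[[j]]
      if (nv(v_from(p[1])) != nv(v_from(q[1]))) next
      if (nv(v_to(p[length(p)])) != nv(v_to(q[length(q)]))) next
      if (length(intersect(abs(p), abs(q)))) next
      ip <- if (length(p) > 1)
        abs(vapply(p[-length(p)], v_to, 0)) else integer()
      iq <- if (length(q) > 1)
        abs(vapply(q[-length(q)], v_to, 0)) else integer()
      if (anyDuplicated(ip) || anyDuplicated(iq)) next
      if (length(intersect(ip, iq))) next
      ends <- abs(c(nv(v_from(p[1])), nv(v_to(p[length(p)]))))
      if (length(intersect(c(ip, iq), ends))) next
      k1 <- paste(sort(c(paste(p, collapse = ","), paste(q, collapse = ",")),
                       method = "radix"), collapse = ";")
      k2 <- paste(sort(c(paste(-rev(p), collapse = ","),
                         paste(-rev(q), collapse = ",")), method = "radix"),
                  collapse = ";")
      ids <- c(ids, if (fwd_only) k1 else sort(c(k1, k2),
                                               method = "radix")[1])
    }
  }
  sort(unique(ids), method = "radix")
}

bubble_pair_ids <- function(b, fwd_only = FALSE) {
  if (nrow(b) == 0) return(character())
  sort(vapply(seq_len(nrow(b)), function(i) {
    p <- b$path1[[i]]; q <- b$path2[[i]]
    k1 <- paste(sort(c(paste(p, collapse = ","), paste(q, collapse = ",")),
                     method = "radix"), collapse = ";")
    k2 <- paste(sort(c(paste(-rev(p), collapse = ","),
                       paste(-rev(q), collapse = ",")), method = "radix"),
                collapse = ";")
    if (fwd_only) k1 else sort(c(k1, k2), method = "radix")[1]
  }, ""), method = "radix")
}

# brute-force dot-plot by direct window comparison
oracle_dotplot <- function(a, b, w) {
  na <- nchar(a); nb <- nchar(b)
  rows <- list()
  rb <- rc_chr(b)
  for (x in 0:(na - w)) {
    wa <- substring(a, x + 1, x + w)
    for (y in 0:(nb - w)) {
      if (wa == substring(b, y + 1, y + w))
        rows[[length(rows) + 1]] <- c(x, y, 1L)
      if (wa == substring(rb, nb - w - y + 1, nb - y))
        rows[[length(rows) + 1]] <- c(x, y, 0L)
    }
  }
  if (!length(rows)) return(data.frame(x = integer(), y = integer(),
                                       forward = logical()))
  m <- do.call(rbind, rows)
  df <- data.frame(x = m[, 1], y = m[, 2], forward = m[, 3] == 1L)
  df[order(df$x, df$y, df$forward), ]
}

# planted-genome runs are reused across acceptance checks
planted_cache <- new.env(parent = emptyenv())
planted_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(planted_cache[[key]])) {
    pl <- plant(plant_config(seed = seed))
    d <- decompose_genome(pl$genome, untangle_params(K = 2000))
    planted_cache[[key]] <- list(plant = pl, decomp = d)
  }
  planted_cache[[key]]
}

# match each planted truth copy to the recovered instance with the largest
# overlap; returns per-block summary of copy-number exactness and boundary
# error
# The dominant recovered block for a planted family is the block whose
# instances hit the most truth copies (ties: larger total overlap);
# boundary error is then measured between the reported instance boundaries
# and the truth copies paired one-to-one in genomic order.
match_truth <- function(truth, instances, blocks = NULL) {
  res <- list()
  for (bn in unique(truth$block)) {
    tb <- truth[truth$block == bn, , drop = FALSE]
    cand <- unique(instances$block_id)
    hits <- integer(length(cand)); tot <- numeric(length(cand))
    for (ci in seq_along(cand)) {
      ib <- instances[instances$block_id == cand[ci], , drop = FALSE]
      for (i in seq_len(nrow(tb))) {
        ov <- pmin(ib$end, tb$end[i]) - pmax(ib$start, tb$start[i])
        if (any(ov > 0)) {
          hits[ci] <- hits[ci] + 1L
          tot[ci] <- tot[ci] + max(ov)
        }
      }
    }
    if (all(hits == 0)) {
      res[[bn]] <- data.frame(block = bn, planted = nrow(tb), recovered = 0L,
                              max_boundary_err = Inf)
      next
    }
    dom <- cand[order(-hits, -tot)][1]
    ib <- instances[instances$block_id == dom, , drop = FALSE]
    o1 <- order(tb$start); o2 <- order(ib$start)
    npair <- min(nrow(tb), nrow(ib))
    berr <- vapply(seq_len(npair), function(r) {
      i <- o1[r]; j <- o2[r]
      max(abs(ib$start[j] - tb$start[i]), abs(ib$end[j] - tb$end[i]))
    }, 0)
    res[[bn]] <- data.frame(block = bn, planted = nrow(tb),
                            recovered = nrow(ib),
                            max_boundary_err = max(berr))
  }
  do.call(rbind, res)
}
# classify every recovered block by the planted family its instances
# overlap most (across both genomes); the imbalance call is correct when
# at least one block of the edited family is flagged and no block of an
# unedited family is
imbalance_hit <- function(d, base_truth, var_truth, edited) {
  fams <- unique(base_truth$block)
  ov_tab <- matrix(0, nrow = length(unique(d$instances$block_id)),
                   ncol = length(fams),
                   dimnames = list(unique(d$instances$block_id), fams))
  add_overlaps <- function(ins, truth) {
    for (b in rownames(ov_tab)) {
      ib <- ins[ins$block_id == b, , drop = FALSE]
      if (nrow(ib) == 0) next
      for (fn in fams) {
        tf <- truth[truth$block == fn, , drop = FALSE]
        tot <- 0
        for (i in seq_len(nrow(tf))) {
          ov <- pmin(ib$end, tf$end[i]) - pmax(ib$start, tf$start[i])
          tot <- tot + sum(ov[ov > 0])
        }
        ov_tab[b, fn] <<- ov_tab[b, fn] + tot
      }
    }
  }
  add_overlaps(d$instances[d$instances$genome == "sim", ], base_truth)
  add_overlaps(d$instances[d$instances$genome != "sim", ], var_truth)
  fam_of <- apply(ov_tab, 1, function(r)
    if (all(r == 0)) NA_character_ else colnames(ov_tab)[which.max(r)])
  imb <- imbalanced_blocks(d)
  fam_imb <- fam_of[imb]
  any(!is.na(fam_imb) & fam_imb == edited) &&
    !any(!is.na(fam_imb) & fam_imb != edited)
}
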