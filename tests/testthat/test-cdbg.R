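test_that("a repeat-free sequence condenses to a single edge and one step", {
  set.seed(11)
  s <- rand_dna(60)
  g <- build_cdbg(string_set(s), k = 15)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$walks$steps[[1]], 1L)
  expect_equal(g$edges$mult, 1L)
  expect_equal(spell_walk(g, g$walks$steps[[1]]), s)
})

test_that("walks spell their chromosomes back (round trip over random strings)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(30:400, 1)
    s <- rand_dna(n)
    # salt with a duplication half the time so walks have several steps
    if (i %% 2 == 0) {
      u <- substring(s, 1, 25)
      s <- paste0(s, u, rand_dna(20))
    }
    k <- sample(c(5L, 9L, 15L), 1)
    g <- build_cdbg(string_set(s), k)
    expect_identical(spell_walk(g, g$walks$steps[[1]]), s)
  }
})

test_that("edge multiplicities match a brute-force substring scan", {
  set.seed(7)
  for (i in 1:10) {
    u <- rand_dna(40)
    s <- paste0(rand_dna(50), u, rand_dna(30), u, rand_dna(50),
                rc_chr(u), rand_dna(40))
    ss <- string_set(s)
    g <- build_cdbg(ss, 13)
    for (e in seq_len(nrow(g$edges))) {
      expect_equal(g$edges$mult[e], oracle_label_mult(ss, g$edges$label[e]),
                   info = sprintf("iter %d edge %d", i, e))
    }
    # conservation: per-edge multiplicity equals walk usage
    expect_equal(g$edges$mult,
                 as.integer(tabulate(abs(unlist(g$walks$steps)),
                                     nbins = nrow(g$edges))))
  }
})

test_that("edge labels are consistent with their vertex labels", {
  set.seed(13)
  u <- rand_dna(30)
  s <- paste0(rand_dna(40), u, rand_dna(35), u, rand_dna(40))
  g <- build_cdbg(string_set(s), 9)
  vlab <- g$vertices$label
  for (e in seq_len(nrow(g$edges))) {
    lab <- g$edges$label[e]
    fr <- g$edges$from[e]; to <- g$edges$to[e]
    fr_lab <- if (fr > 0) vlab[fr] else rc_chr(vlab[-fr])
    to_lab <- if (to > 0) vlab[to] else rc_chr(vlab[-to])
    expect_equal(substring(lab, 1, 8), fr_lab)
    expect_equal(substring(lab, nchar(lab) - 7), to_lab)
  }
})

test_that("the graph is strand-symmetric", {
  set.seed(19)
  u <- rand_dna(30)
  s <- paste0(rand_dna(60), u, rand_dna(40), u, rand_dna(30))
  g1 <- build_cdbg(string_set(s), 11)
  g2 <- build_cdbg(string_set(rc_chr(s)), 11)
  canon <- function(g) sort(pmin(g$edges$label, rc_chr(g$edges$label)))
  expect_equal(canon(g1), canon(g2))
  expect_equal(sort(g1$edges$mult), sort(g2$edges$mult))
})

test_that("condensation is idempotent: rebuilding the spelled genome changes nothing", {
  set.seed(23)
  u <- rand_dna(35)
  s <- paste0(rand_dna(50), u, rand_dna(30), u, rand_dna(20))
  g1 <- build_cdbg(string_set(s), 9)
  g2 <- build_cdbg(g1$strings, 9)
  expect_equal(g1$edges$label, g2$edges$label)
  expect_equal(g1$walks$steps, g2$walks$steps)
})

test_that("N runs split walks and short N-side fragments become clips", {
  set.seed(29)
  a <- rand_dna(40); b <- rand_dna(50)
  s <- paste0(a, "NNNN", b, "NN", "ACG") # trailing 3 bp fragment < k
  g <- build_cdbg(string_set(s), 9)
  expect_equal(nrow(g$walks), 2L)
  expect_identical(spell_walk(g, g$walks$steps[[1]]), a)
  expect_identical(spell_walk(g, g$walks$steps[[2]]), b)
  expect_true(nrow(g$clips) >= 1)
})

test_that("a reverse-complement repeat appears as one multiplicity-2 edge", {
  set.seed(31)
  u <- rand_dna(40)
  s <- paste0(rand_dna(50), u, rand_dna(60), rc_chr(u), rand_dna(50))
  g <- build_cdbg(string_set(s), 15)
  reps <- g$edges[g$edges$mult >= 2, ]
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$mult, 2L)
  # one traversal forward, one reverse
  steps <- unlist(g$walks$steps)
  expect_true(any(steps == reps$edge_id) && any(steps == -reps$edge_id))
})

test_that("spell_walk rejects disconnected steps", {
  set.seed(37)
  u <- rand_dna(30)
  s <- paste0(rand_dna(40), u, rand_dna(40), u, rand_dna(40))
  g <- build_cdbg(string_set(s), 9)
  st <- g$walks$steps[[1]]
  expect_error(spell_walk(g, st[c(1, length(st))]), "share a vertex")
})

test_that("sequences shorter than k are rejected", {
  expect_error(build_cdbg(string_set("ACGT"), 21), "shorter than k")
})
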