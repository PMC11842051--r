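test_that("percent identity follows the edit-distance definition", {
  expect_equal(percent_identity("ACGT", "ACGT"), 1.0)
  expect_equal(percent_identity("CTCAGTAT", "CTCCGTAT"), 1 - 1 / 8)
  expect_equal(percent_identity("ACGT", ""), 0.0)
  expect_equal(percent_identity("", ""), 1.0)
  set.seed(101)
  for (i in 1:40) {
    a <- rand_dna(sample(0:60, 1))
    b <- rand_dna(sample(0:60, 1))
    expect_equal(percent_identity(a, b), dp_pi(a, b))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
})

test_that("a single-edge graph has no bubbles", {
  set.seed(103)
  g <- build_cdbg(string_set(rand_dna(80)), 15)
  expect_equal(nrow(find_bubbles(g, 4)), 0L)
})

test_that("bubble enumeration matches the exhaustive subpath-pair oracle", {
  set.seed(107)
  tries <- 0
  for (i in 1:12) {
    # small genomes with a mutated duplication induce small bubbly graphs
    u <- rand_dna(30)
    u2 <- u
    substr(u2, 15, 15) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substring(u, 15, 15)), 1)
    s <- paste0(rand_dna(25), u, rand_dna(20), u2, rand_dna(25))
    for (strands in c("both", "forward")) {
      g <- build_cdbg(string_set(s), 7, strands = strands)
      if (nrow(g$edges) > 12) next
      tries <- tries + 1
      b <- find_bubbles(g, 4)
      expect_identical(bubble_pair_ids(b, strands == "forward"),
                       oracle_bubble_ids(g, 4))
    }
  }
  expect_gt(tries, 5)
})

test_that("bubble rows satisfy their structural invariants", {
  set.seed(109)
  u <- rand_dna(40)
  u2 <- u; substr(u2, 20, 20) <- "A"; substr(u2, 21, 21) <- "T"
  s <- paste0(rand_dna(30), u, rand_dna(30), u2, rand_dna(30))
  g <- build_cdbg(string_set(s), 9)
  b <- find_bubbles(g, 4)
  expect_gt(nrow(b), 0)
  for (i in seq_len(nrow(b))) {
    p <- b$path1[[i]]; q <- b$path2[[i]]
    expect_length(intersect(abs(p), abs(q)), 0)
    expect_lte(b$complexity[i], 4)
    expect_equal(b$complexity[i], max(length(p), length(q)))
    expect_lte(str_len(b$spell1[i]), str_len(b$spell2[i]))
    # both paths occur in some walk (possibly reverse complemented)
    occ_p <- sdblocks:::path_occurrences(g, p)
    occ_q <- sdblocks:::path_occurrences(g, q)
    expect_gt(nrow(occ_p), 0)
    expect_gt(nrow(occ_q), 0)
    expect_equal(b$mult1[i], min(g$edges$mult[abs(p)]))
  }
})

test_that("collapsibility thresholds distinguish simple and complex bubbles", {
  b_simple <- tibble::tibble(path1 = list(1L), path2 = list(2L),
                             simple = TRUE,
                             spell1 = "ACGTAC", spell2 = "ACTTAC")
  g <- NULL # thresholds only
  expect_false(is_collapsible(b_simple, g, untangle_params(K = 100)))
  expect_true(is_collapsible(b_simple, g,
                             untangle_params(K = 100, sim_strong = 0.75)))
  # complex: PI 0.70 vs sim_weak 0.65
  b_cx <- tibble::tibble(path1 = list(c(1L, 2L)), path2 = list(c(3L, 4L)),
                         simple = FALSE,
                         spell1 = "ACGTACGTAC", spell2 = "ACTTACTTAC")
  expect_equal(percent_identity(b_cx$spell1, b_cx$spell2), 0.8)
  b_cx$spell2 <- "ACTTTCTTAC" # 3 substitutions -> PI 0.7
  expect_true(is_collapsible(b_cx, g, untangle_params(K = 100)))
  expect_false(is_collapsible(b_cx, g,
                              untangle_params(K = 100, sim_weak = 0.75)))
})

test_that("collapsing a simple bubble merges multiplicities and re-condenses", {
  set.seed(113)
  u <- rand_dna(60)
  u2 <- u
  substr(u2, 30, 30) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substring(u, 30, 30)), 1)
  # two clean copies and one variant: simple bubble with multiplicities 2, 1
  s <- paste0(rand_dna(40), u, rand_dna(35), u2, rand_dna(30), u,
              rand_dna(40))
  ss <- string_set(s)
  g <- build_cdbg(ss, 11)
  b <- find_bubbles(g, 4)
  b <- b[b$simple, ]
  expect_equal(nrow(b), 1L)
  expect_setequal(c(b$mult1, b$mult2), c(1L, 2L))
  res <- collapse_bubble(ss, g, b[1, ])
  g2 <- res$graph
  # all three copies now identical: one multiplicity-3 edge spans the repeat
  expect_true(any(g2$edges$mult == 3L & g2$edges$length == 60L))
  # the bubble's two edges are gone (no repeat-scale multiplicity-2 edge)
  expect_false(any(g2$edges$mult == 2L & g2$edges$length > 20L))
  # the rewritten genome is still spelled exactly by its walks
  expect_identical(spell_walk(g2, g2$walks$steps[[1]]), res$strings$seq[1])
})

test_that("a stale bubble signals instead of corrupting the genome", {
  set.seed(127)
  u <- rand_dna(50)
  u2 <- u; substr(u2, 25, 25) <- "A"
  s <- paste0(rand_dna(30), u, rand_dna(30), u2, rand_dna(30))
  ss <- string_set(s)
  g <- build_cdbg(ss, 11)
  b <- find_bubbles(g, 4)
  res <- collapse_bubble(ss, g, b[1, ])
  expect_error(collapse_bubble(res$strings, res$graph, b[1, ]),
               class = "sdblocks_stale")
})
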