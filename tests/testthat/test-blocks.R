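two_copy_decomp <- function(seed = 501, L = 1200, K = 500) {
  set.seed(seed)
  u <- rand_dna(L)
  s <- paste0(rand_dna(600), u, rand_dna(500), u, rand_dna(600))
  ss <- string_set(s)
  u <- untangle(ss, untangle_params(K = K))
  list(u = u, d = infer_blocks(u))
}

test_that("two exact copies give one block with two identical full instances", {
  r <- two_copy_decomp()
  d <- r$d
  expect_equal(nrow(d$blocks), 1L)
  expect_equal(nrow(d$instances), 2L)
  expect_equal(d$instances$block_id, c("A", "A"))
  txt <- substring(r$u$strings$seq,
                   d$instances$start + 1, d$instances$end)
  expect_identical(txt[1], txt[2])
  # full instances span the whole consensus
  expect_equal(d$instances$cons_start, c(0L, 0L))
  expect_equal(d$instances$cons_end, rep(d$blocks$length, 2))
})

test_that("block graph keeps exactly the repeated edges", {
  r <- two_copy_decomp(503)
  g <- r$u$graph
  bg <- block_graph(g)
  expect_setequal(bg$edges$edge_id, g$edges$edge_id[g$edges$mult >= 2])
  keep <- unique(abs(c(bg$edges$from, bg$edges$to)))
  expect_setequal(bg$vertices$vertex_id, keep)
  # all-multiplicity-1 graph -> empty block graph
  set.seed(504)
  g1 <- build_cdbg(string_set(rand_dna(300)), 21)
  expect_equal(nrow(block_graph(g1)$edges), 0L)
})

test_that("instances plus gaps tile every chromosome exactly", {
  set.seed(505)
  pl <- plant(plant_config(seed = 505, backbone_len = 40000L, n_blocks = 2,
                           length_range = c(2000L, 3000L),
                           copy_range = c(2L, 3L)))
  d <- decompose_genome(pl$genome, untangle_params(K = 1000))
  seg <- decomposition_segments(d)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    expect_equal(s$start[1], 0L)
    expect_equal(s$end[nrow(s)],
                 d$chroms$length[d$chroms$chrom == ch])
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))
    expect_equal(sum(is.na(s$block_id)), sum(!is.na(s$block_id)) + 1L)
  }
  # instances never overlap
  ins <- d$instances
  expect_true(all(ins$start[-1] >= ins$end[-nrow(ins)] |
                    ins$chrom[-1] != ins$chrom[-nrow(ins)]))
})

test_that("all instances of a block spell exact substrings of its consensus", {
  set.seed(507)
  pl <- plant(plant_config(seed = 507, backbone_len = 40000L, n_blocks = 2,
                           length_range = c(2500L, 4000L),
                           copy_range = c(2L, 4L)))
  u <- untangle(pl$genome, untangle_params(K = 1000))
  d <- infer_blocks(u)
  cons <- stats::setNames(d$blocks$consensus, d$blocks$block_id)
  for (i in seq_len(nrow(d$instances))) {
    x <- d$instances[i, ]
    txt <- substring(u$strings$seq, x$start + 1, x$end)
    if (x$strand == "-") txt <- rc_chr(txt)
    expect_identical(txt, substring(cons[[x$block_id]],
                                    x$cons_start + 1, x$cons_end))
    expect_equal(x$pct_identity, 1.0)
  }
  # multiplicity consistency: block instance counts match the blocks table
  expect_equal(d$blocks$n_instances,
               as.integer(table(d$instances$block_id)[d$blocks$block_id]))
})

test_that("a reverse-complement second copy is one block with a minus instance", {
  set.seed(509)
  u <- rand_dna(1500)
  s <- paste0(rand_dna(700), u, rand_dna(600), rc_chr(u), rand_dna(700))
  res <- untangle(string_set(s), untangle_params(K = 600))
  d <- infer_blocks(res)
  expect_equal(nrow(d$blocks), 1L)
  expect_setequal(d$instances$strand, c("+", "-"))
  expect_equal(unname(block_string(d)), "A A'")
})

test_that("block letters follow first genomic occurrence and extend past Z", {
  expect_equal(sdblocks:::block_letters(3), c("A", "B", "C"))
  expect_equal(sdblocks:::block_letters(28)[27:28], c("AA", "AB"))
  r <- two_copy_decomp(511)
  expect_equal(r$d$blocks$block_id[1], "A")
})

test_that("the block string encodes order, strand and partial offsets", {
  d <- decompose_genome(toy_genome(), toy_params())
  expect_equal(unname(block_string(d)), "A B A A B")
  # partial instances are bracketed
  di <- d
  di$instances$cons_start[2] <- 3L
  expect_match(unname(block_string(di)), "B\\[3,8\\]")
  # empty decomposition -> empty string
  set.seed(513)
  d0 <- decompose_genome(string_set(rand_dna(400)),
                         untangle_params(K = 100, k_init = 21))
  expect_equal(unname(block_string(d0)), "")
})

test_that("no two blocks could be merged without breaking an adjacency", {
  set.seed(515)
  pl <- plant(plant_config(seed = 515, backbone_len = 30000L, n_blocks = 2,
                           length_range = c(2500L, 3500L),
                           copy_range = c(2L, 3L)))
  u <- untangle(pl$genome, untangle_params(K = 1000))
  d <- infer_blocks(u)
  # distinct blocks never share a consensus, and for every pair of blocks
  # adjacent in the genome there is an occurrence separating them (a walk
  # where one occurs without the other right next to it)
  expect_false(anyDuplicated(d$blocks$consensus) > 0)
  ins <- d$instances[order(d$instances$start), ]
  if (nrow(ins) > 1) {
    adj <- which(ins$start[-1] == ins$end[-nrow(ins)])
    for (i in adj) {
      a <- ins$block_id[i]; b <- ins$block_id[i + 1]
      pair_count <- sum(ins$block_id[-nrow(ins)] == a &
                          ins$block_id[-1] == b &
                          ins$start[-1] == ins$end[-nrow(ins)])
      total_a <- sum(ins$block_id == a)
      expect_lt(pair_count, max(total_a, sum(ins$block_id == b)) + 1)
    }
  }
  succeed()
})

test_that("tidy and glance summarise a decomposition", {
  d <- decompose_genome(toy_genome(), toy_params())
  td <- generics::tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  gl <- generics::glance(d)
  expect_equal(gl$n_blocks, 2L)
  expect_equal(gl$n_instances, 5L)
  expect_equal(gl$genome_length, 88L)
})
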