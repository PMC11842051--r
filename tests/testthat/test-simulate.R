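small_cfg <- function(seed, ...) {
  plant_config(seed = seed, backbone_len = 20000L, n_blocks = 2,
               length_range = c(1500L, 2500L), copy_range = c(2L, 3L), ...)
}

test_that("planting is deterministic in the seed", {
  a <- plant(small_cfg(1))
  b <- plant(small_cfg(1))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  c <- plant(small_cfg(2))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("zero divergence plants identical copies at the truth coordinates", {
  cfg <- plant_config(seed = 3, backbone_len = 20000L,
                      blocks = tibble::tibble(
                        length = 2000L, copies = 2L,
                        arrangement = "dispersed",
                        sub_rate = 0, indel_rate = 0))
  pl <- plant(cfg)
  txt <- substring(pl$genome$seq, pl$truth$start + 1, pl$truth$end)
  expect_identical(txt[1], txt[2])
  expect_true(all(pl$truth$pi == 1))
})

test_that("reverse-tandem copies are reverse complements before mutation", {
  cfg <- plant_config(seed = 5, backbone_len = 20000L,
                      blocks = tibble::tibble(
                        length = 1500L, copies = 2L,
                        arrangement = "reverse-tandem",
                        sub_rate = 0, indel_rate = 0))
  pl <- plant(cfg)
  txt <- substring(pl$genome$seq, pl$truth$start + 1, pl$truth$end)
  expect_identical(txt[2], rc_chr(txt[1]))
  expect_equal(pl$truth$strand, c("+", "-"))
  # the spacer keeps the pair from being a perfect palindrome
  expect_equal(pl$truth$start[2] - pl$truth$end[1],
               cfg$rt_spacer)
})

test_that("realized substitution counts follow the binomial model", {
  L <- 4000L; rate <- 0.03
  nsub <- integer(40)
  for (s in seq_len(40)) {
    cfg <- plant_config(seed = 1000 + s, backbone_len = 12000L,
                        blocks = tibble::tibble(
                          length = L, copies = 2L,
                          arrangement = "dispersed",
                          sub_rate = rate, indel_rate = 0))
    pl <- plant(cfg)
    txt <- substring(pl$genome$seq, pl$truth$start + 1, pl$truth$end)
    prog <- pl$progenitors[1]
    nsub[s] <- sum(strsplit(txt[1], "")[[1]] != strsplit(prog, "")[[1]]) +
      sum(strsplit(txt[2], "")[[1]] != strsplit(prog, "")[[1]])
  }
  mu <- 2 * L * rate
  sigma <- sqrt(2 * L * rate * (1 - rate))
  expect_lt(abs(mean(nsub) - mu), 3 * sigma / sqrt(40))
})

test_that("recorded truth identity matches the oracle on extracted copies", {
  pl <- plant(small_cfg(7))
  for (i in seq_len(min(4, nrow(pl$truth)))) {
    x <- pl$truth[i, ]
    txt <- substring(pl$genome$seq, x$start + 1, x$end)
    if (x$strand == "-") txt <- rc_chr(txt)
    prog <- pl$progenitors[as.integer(sub("P", "", x$block))]
    expect_equal(x$pi, dp_pi(txt, prog))
  }
})

test_that("pair_variant applies copy-number deltas and keeps truth consistent", {
  pl <- plant(small_cfg(9))
  same <- pair_variant(pl, c(P1 = 0L), seed = 1)
  expect_identical(same$genome$seq, pl$genome$seq)
  plus <- pair_variant(pl, c(P1 = 1L), seed = 2)
  expect_equal(sum(plus$truth$block == "P1"),
               sum(pl$truth$block == "P1") + 1L)
  expect_gt(nchar(plus$genome$seq), nchar(pl$genome$seq))
  # truth intervals still extract the recorded sequences
  for (i in seq_len(nrow(plus$truth))) {
    x <- plus$truth[i, ]
    txt <- substring(plus$genome$seq, x$start + 1, x$end)
    if (x$strand == "-") txt <- rc_chr(txt)
    prog <- plus$progenitors[as.integer(sub("P", "", x$block))]
    expect_equal(x$pi, dp_pi(txt, prog), tolerance = 1e-12)
  }
  minus <- pair_variant(pl, c(P2 = -1L), seed = 3)
  expect_equal(sum(minus$truth$block == "P2"),
               sum(pl$truth$block == "P2") - 1L)
  expect_error(pair_variant(pl, c(P1 = -5L), seed = 4), "remove all")
})
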