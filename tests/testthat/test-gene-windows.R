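test_that("an identical target gives gene and window identity 1", {
  set.seed(801)
  anchor <- rand_dna(400)
  r <- window_align(anchor, anchor, 180, 210, gene_params())
  expect_equal(r$gene_pi, 1.0)
  expect_equal(r$window_pi, 1.0)
  expect_equal(r$classification, "block-annotated")
})

test_that("substitutions inside the gene depress gene PI more than window PI", {
  set.seed(803)
  anchor <- rand_dna(400)
  gene <- c(190L, 210L) # 20 bp gene centred in a 100 bp window
  target <- strsplit(anchor, "")[[1]]
  for (p in c(195L, 205L))
    target[p] <- setdiff(c("A", "C", "G", "T"), target[p])[1]
  target <- paste(target, collapse = "")
  r <- window_align(anchor, target, gene[1], gene[2], gene_params())
  expect_equal(r$gene_pi, 1 - 2 / 20)
  expect_equal(r$window_pi, 1 - 2 / 100)
})

test_that("a scrambled gene region is called disrupted", {
  set.seed(805)
  anchor <- rand_dna(400)
  target <- paste0(substring(anchor, 1, 150), rand_dna(100),
                   substring(anchor, 251))
  # window centred on a gene inside the scrambled region
  r <- window_align(anchor, target, 185L, 215L, gene_params())
  expect_lt(r$window_pi, 0.60)
  expect_equal(r$classification, "disrupted")
})

test_that("classification applies the window-PI and RSS rules", {
  p <- gene_params()
  mk <- function(wpi, h, n) tibble::tibble(gene_pi = 0.9, window_pi = wpi,
                                           hept_diffs = h, nona_diffs = n)
  expect_equal(classify_gene(mk(0.59, 0L, 0L), p), "disrupted")
  expect_equal(classify_gene(mk(0.90, 3L, 0L), p), "disrupted")
  expect_equal(classify_gene(mk(0.90, 2L, 0L), p), "block-annotated")
  expect_equal(classify_gene(mk(0.90, 1L, 1L), p), "block-annotated")
  expect_equal(classify_gene(mk(0.90, 1L, 2L), p), "disrupted")
  # monotonicity: raising min_pi or lowering max_diff never rescues a call
  set.seed(807)
  for (i in 1:20) {
    r <- mk(runif(1, 0.4, 1), sample(0:3, 1), sample(0:3, 1))
    base <- classify_gene(r, gene_params())
    stricter <- classify_gene(r, gene_params(min_pi = 0.8, max_diff = 1))
    if (base == "disrupted") expect_equal(stricter, "disrupted")
  }
})

test_that("an indel in the RSS motif is an automatic fail", {
  set.seed(809)
  anchor <- rand_dna(300)
  # delete one base inside the heptamer at 120..127
  target <- paste0(substring(anchor, 1, 122), substring(anchor, 124))
  r <- window_align(anchor, target, 140L, 160L, gene_params(),
                    hept_start = 120L, nona_start = 180L)
  expect_equal(r$hept_diffs, 3L) # max_diff + 1
  expect_equal(r$nona_diffs, 0L)
  expect_equal(r$classification, "disrupted")
})

test_that("window PI is symmetric in anchor and target", {
  set.seed(811)
  a <- rand_dna(300)
  b <- strsplit(a, "")[[1]]
  hit <- which(runif(300) < 0.05)
  b[hit] <- vapply(b[hit], function(c)
    sample(setdiff(c("A", "C", "G", "T"), c), 1), "")
  b <- paste(b, collapse = "")
  r1 <- window_align(a, b, 140L, 160L, gene_params())
  r2 <- window_align(b, a, 140L, 160L, gene_params())
  expect_equal(r1$window_pi, r2$window_pi, tolerance = 1e-9)
})

test_that("pressure table flags gene-local divergence and averages per gene", {
  expect_equal(nrow(pressure_table(tibble::tibble())), 0L)
  res <- tibble::tibble(gene = c("g1", "g1", "g2"),
                        target = c("t1", "t2", "t1"),
                        gene_pi = c(0.6, 0.7, 0.95),
                        window_pi = c(0.9, 0.8, 0.9))
  pt <- pressure_table(res)
  avg <- pt[pt$target == "average", ]
  expect_equal(avg$gene_pi[avg$gene == "g1"], 0.65)
  expect_true(all(pt$gene_below_window[pt$gene == "g1"]))
  expect_false(any(pt$gene_below_window[pt$gene == "g2" &
                                          pt$target != "average"]))
})

test_that("elevated gene-local mutation rates show up as gene PI below window PI", {
  genes <- tibble::tibble(block = 1L, offset = 900L, length = 40L,
                          hept_offset = NA_integer_, nona_offset = NA_integer_,
                          rate_mult = 8)
  cfg <- plant_config(seed = 813, backbone_len = 20000L,
                      blocks = tibble::tibble(length = 2000L, copies = 4L,
                                              arrangement = "dispersed",
                                              sub_rate = 0.02,
                                              indel_rate = 0),
                      genes = genes)
  pl <- plant(cfg)
  d <- decompose_genome(pl$genome, untangle_params(K = 800))
  gw <- gene_window_analysis(d, pl$genome, pl$genes, gene_params())
  expect_gt(nrow(gw), 0)
  expect_gt(mean(gw$gene_pi < gw$window_pi), 0.9)
  # under a uniform rate the two identities agree on average
  cfg0 <- plant_config(seed = 815, backbone_len = 20000L,
                       blocks = tibble::tibble(length = 2000L, copies = 4L,
                                               arrangement = "dispersed",
                                               sub_rate = 0.02,
                                               indel_rate = 0),
                       genes = transform(genes, rate_mult = 1))
  pl0 <- plant(cfg0)
  d0 <- decompose_genome(pl0$genome, untangle_params(K = 800))
  gw0 <- gene_window_analysis(d0, pl0$genome, pl0$genes, gene_params())
  expect_gt(nrow(gw0), 0)
  expect_lt(abs(mean(gw0$gene_pi) - mean(gw0$window_pi)), 0.08)
})
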