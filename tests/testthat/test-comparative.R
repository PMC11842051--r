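joint_fixture <- function(seed, deltas = NULL) {
  pl <- plant(plant_config(seed = seed, backbone_len = 30000L, n_blocks = 2,
                           length_range = c(2500L, 3500L),
                           copy_range = c(2L, 3L),
                           divergence_range = c(0.01, 0.03)))
  var <- if (is.null(deltas)) {
    v <- pl; v$genome$genome <- "sim2"; v
  } else pair_variant(pl, deltas, seed = seed + 1000)
  list(base = pl, var = var,
       joint = joint_decompose(list(pl$genome, var$genome),
                               untangle_params(K = 1500)))
}

test_that("two identical genomes decompose identically with no imbalance", {
  fx <- joint_fixture(701)
  d <- fx$joint
  expect_length(imbalanced_blocks(d), 0L)
  a <- d$instances[d$instances$genome == "sim", ]
  b <- d$instances[d$instances$genome == "sim2", ]
  expect_equal(a$block_id, b$block_id)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
})

test_that("an extra tandem copy makes exactly that block imbalanced", {
  fx <- joint_fixture(703, deltas = c(P1 = 1L))
  d <- fx$joint
  imb <- imbalanced_blocks(d)
  # locate the recovered block holding P1's truth copies
  m <- match_truth(fx$base$truth, d$instances[d$instances$genome == "sim", ], d$blocks)
  rec <- d$instances[d$instances$genome == "sim", ]
  tb <- fx$base$truth[fx$base$truth$block == "P1", ][1, ]
  ov <- pmin(rec$end, tb$end) - pmax(rec$start, tb$start)
  target <- rec$block_id[which.max(ov)]
  expect_true(target %in% imb)
  # counts differ by exactly one for the edited block
  cnt <- differential_report(d)
  cc <- cnt[cnt$block_id == target, ]
  expect_equal(abs(diff(cc$n_instances)), 1L)
  expect_true(all(cc$imbalanced))
})

test_that("the differential report agrees with a recount of the instances", {
  fx <- joint_fixture(707, deltas = c(P2 = 1L))
  d <- fx$joint
  rep <- differential_report(d)
  for (i in seq_len(nrow(rep))) {
    n <- sum(d$instances$block_id == rep$block_id[i] &
               d$instances$genome == rep$genome[i])
    expect_equal(rep$n_instances[i], n)
  }
})

test_that("genome input order only permutes the report rows", {
  fx <- joint_fixture(709)
  d12 <- fx$joint
  d21 <- joint_decompose(list(fx$var$genome, fx$base$genome),
                         untangle_params(K = 1500))
  r12 <- differential_report(d12)
  r21 <- differential_report(d21)
  key <- function(r) r[order(r$block_id, r$genome),
                       c("genome", "n_instances", "total_length")]
  a <- key(r12); b <- key(r21)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(dplyr::arrange(a, genome, n_instances, total_length),
               dplyr::arrange(b, genome, n_instances, total_length))
})

test_that("gene counting uses full containment", {
  d <- decompose_genome(toy_genome(), toy_params())
  d$chroms$genome <- "toy"
  genes <- tibble::tibble(chrom = "toy",
                          start = c(1L, 6L, 30L),
                          end = c(5L, 12L, 35L),
                          strand = "+",
                          name = c("inside", "straddle", "outside"),
                          kind = "D",
                          hept_start = NA_integer_, nona_start = NA_integer_)
  # instance A spans [0, 8): "inside" fits, "straddle" crosses the boundary
  rep <- differential_report(d, genes = list(toy = genes))
  a <- rep[rep$block_id == "A", ]
  expect_equal(sum(a$n_genes), 1L)
  expect_error(differential_report(d, genes = list(toy = transform(
    genes, chrom = "nope"))), "nope")
})

test_that("joint decomposition refuses a single genome label", {
  expect_error(joint_decompose(list(toy_genome()), toy_params()), ">= 2")
})
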