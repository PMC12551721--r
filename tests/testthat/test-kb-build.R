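test_that("consensus_topk includes frequency ties beyond the target size", {
  kb <- consensus_topk(c(3, 3, 2, 1), k_target = 2)
  expect_equal(set_members(kb$members), 1:2)
  kb_tie <- consensus_topk(c(3, 2, 2, 1), k_target = 2)
  expect_equal(set_members(kb_tie$members), 1:3)  # ties at t=2 all included
  expect_warning(kb_all <- consensus_topk(c(2, 0, 1), k_target = 5),
                 "nonzero")
  expect_equal(set_members(kb_all$members), c(1L, 3L))
})

test_that("consensus_topk equals the sort-and-threshold oracle and is monotone", {
  set.seed(3)
  freq <- rpois(10000, 1.5)
  prev <- integer()
  for (k in c(1, 50, 500, 2000, 5000)) {
    got <- set_members(consensus_topk(freq, k)$members)
    # oracle: smallest threshold whose >=-set reaches k
    t <- max(Filter(function(t) sum(freq >= t) >= k, seq_len(max(freq))))
    expect_equal(got, which(freq >= t))
    expect_true(all(prev %in% got))  # monotone in k
    prev <- got
  }
})

test_that("gene links span 10 kb upstream of the TSS to the TTS, strand-aware", {
  idx <- build_index(data.frame(
    chrom = "chr1", start = c(91000, 99000, 102000, 114000, 120000)), "g",
    chrom_sizes = c(chr1 = 2e5))
  genes <- data.frame(chrom = "chr1", start = 100000, end = 105000,
                      strand = c("+", "-"), name = c("plus", "minus"))
  kbs <- gene_link_kb(genes, idx)
  expect_equal(set_members(kbs[[1]]$members), 1:3)   # 91000 in [90000,105000)
  expect_equal(set_members(kbs[[2]]$members), c(3L, 4L))  # [100000,115000)
  expect_equal(kbs[[1]]$domain, "gene")
})

test_that("gene windows match brute-force containment on random gene sets", {
  idx <- random_index(17, n_chrom = 2, n_per_chrom = 3000, mean_gap = 60)
  set.seed(18)
  n <- 40
  chrom <- sample(idx$chroms$name, n, TRUE)
  start <- floor(runif(n, 0, 1.5e5))
  genes <- data.frame(chrom = chrom, start = start,
                      end = start + floor(runif(n, 500, 20000)),
                      strand = sample(c("+", "-"), n, TRUE),
                      name = sprintf("gene%02d", 1:n))
  kbs <- gene_link_kb(genes, idx)
  for (i in seq_len(n)) {
    win <- if (genes$strand[i] == "+") {
      c(max(0, genes$start[i] - 10000), genes$end[i])
    } else c(genes$start[i], genes$end[i] + 10000)
    len <- idx$chroms$length[match(genes$chrom[i], idx$chroms$name)]
    win[2] <- min(win[2], len)
    oracle <- brute_force_members(
      data.frame(chrom = genes$chrom[i], start = win[1], end = win[2]), idx)
    expect_equal(set_members(kbs[[i]]$members), oracle)
  }
})

test_that("motif knowledgebases extend hits by 10 bp and delegate exactly", {
  idx <- build_index(data.frame(chrom = "chr1", start = c(39, 45)), "m")
  kb <- motif_kb(data.frame(chrom = "chr1", start = 50, end = 58), idx,
                 name = "MOTIF1")
  expect_equal(set_members(kb$members), 2L)  # 45 >= 50-10; 39 < 40 excluded
  ridx <- random_index(23, n_per_chrom = 1000)
  hits <- random_intervals(24, ridx, n = 100, max_len = 20)
  expect_identical(motif_kb(hits, ridx)$members$bits,
                   intersect_to_set(hits, ridx, extend_bp = 10)$bits)
})

test_that("universes are joint-coverage intersections or fixed subspaces", {
  mk <- function(covered, n = 5) {
    m <- numeric(n); m[covered] <- 1
    mu_vector(m, 0)
  }
  u <- build_universe(list(mk(1:3), mk(2:4)))
  expect_equal(set_members(u$members), 2:3)
  u1 <- build_universe(list(mk(c(1, 5))))
  expect_equal(set_members(u1$members), c(1L, 5L))
  expect_error(build_universe(list(mk(1), mk(2))), "empty")
  expect_error(build_universe(list()), "at least one")

  samples <- lapply(1:4, function(s) random_mu(40 + s, 3000, coverage = 0.6))
  got <- build_universe(samples, cov_min = 2)
  oracle <- rep(TRUE, 3000)
  for (s in samples) oracle <- oracle & coverage(s) >= 2
  expect_identical(got$members$bits, oracle)

  pu <- platform_universe(cpg_set(10, c(1, 4)))
  expect_equal(set_members(pu$members), c(1L, 4L))
  expect_error(platform_universe(cpg_set(10)), "empty")
})

test_that("knowledgebase bundles round trip through .cgx with manifests", {
  idx <- random_index(2, n_per_chrom = 200)
  kbs <- list(
    knowledgebase("kb_a", cpg_set(idx$n, 1:50), "chromhmm", "prov a"),
    knowledgebase("kb_b", cpg_set(idx$n, 100:180), "tfbs")
  )
  path <- tempfile(fileext = ".cgx")
  on.exit(unlink(c(path, paste0(path, ".manifest.tsv"))))
  write_kb_bundle(kbs, path)
  back <- read_kb_bundle(path)
  expect_equal(vapply(back, `[[`, "", "name"), c("kb_a", "kb_b"))
  expect_equal(vapply(back, `[[`, "", "domain"), c("chromhmm", "tfbs"))
  expect_identical(back[[1]]$members$bits, kbs[[1]]$members$bits)
  expect_error(knowledgebase("x", cpg_set(5), ""), "domain")
})
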