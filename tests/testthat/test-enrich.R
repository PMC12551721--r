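make_instance <- function(N, n, K, x, domain = "d") {
  # construct sets over an N-space realising exact counts
  q <- cpg_set(N, seq_len(n))
  k_members <- c(seq_len(x), if (K > x) (n + 1):(n + K - x))
  list(query = q,
       kb = knowledgebase("kb", cpg_set(N, k_members), domain),
       universe = as_cpg_set(rep(TRUE, N)))
}

test_that("overlap counting equals the naive membership oracle", {
  a <- cpg_set(10, 1:4)
  b <- cpg_set(10, 5:8)
  expect_equal(overlap_count(a, b), 0)
  expect_equal(overlap_count(a, a), 4)
  expect_error(overlap_count(a, cpg_set(9)), "dimension")
  set.seed(61)
  for (i in 1:50) {
    n <- 500
    x <- as_cpg_set(runif(n) < 0.3)
    y <- as_cpg_set(runif(n) < 0.3)
    u <- as_cpg_set(runif(n) < 0.8)
    naive <- length(intersect(intersect(set_members(x), set_members(y)),
                              set_members(u)))
    expect_equal(overlap_count(x, y, u), naive)
  }
})

test_that("hypergeometric p-values reproduce worked examples exactly", {
  inst <- make_instance(N = 20, n = 5, K = 5, x = 5)
  res <- test_enrichment(inst$query, list(inst$kb), inst$universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  inst2 <- make_instance(N = 10, n = 4, K = 5, x = 4)
  res2 <- test_enrichment(inst2$query, list(inst2$kb), inst2$universe)
  expect_equal(res2$p_value, 5 / choose(10, 4), tolerance = 1e-12)

  # kb == universe is degenerate: the query cannot be enriched in everything
  inst3 <- make_instance(N = 20, n = 5, K = 20, x = 5)
  res3 <- test_enrichment(inst3$query, list(inst3$kb), inst3$universe)
  expect_equal(res3$p_value, 1)
  expect_true(res3$degenerate)
})

test_that("all sides match the exhaustive tail-sum oracle on random instances", {
  set.seed(303)
  for (i in 1:60) {
    N <- sample(5:120, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    supp <- max(0, n + K - N):min(n, K)
    x <- supp[sample.int(length(supp), 1)]
    inst <- make_instance(N, n, K, x)
    for (side in c("enrich", "deplete", "two_sided")) {
      got <- test_enrichment(inst$query, list(inst$kb), inst$universe,
                             side = side)$p_value
      expect_equal(got, oracle_hyper_p(x, K, n, N, side), tolerance = 1e-11)
    }
    # two-sided agrees with fisher.test on the same 2x2 table
    tab <- matrix(c(x, n - x, K - x, N - n - K + x), 2)
    expect_equal(
      test_enrichment(inst$query, list(inst$kb), inst$universe,
                      side = "two_sided")$p_value,
      stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("queries and knowledgebases are intersected into the universe first", {
  N <- 100
  q <- cpg_set(N, 1:30)
  kb <- knowledgebase("kb", cpg_set(N, 20:60), "d")
  u <- platform_universe(cpg_set(N, 10:50))
  res <- test_enrichment(q, list(kb), u)
  expect_equal(res$n_universe, 41)
  expect_equal(res$n_query, 21)    # 10..30
  expect_equal(res$n_kb, 31)       # 20..50
  expect_equal(res$overlap, 11)    # 20..30
  expect_error(test_enrichment(cpg_set(N, 90:95), list(kb), u), "no members")
})

test_that("enrichment is symmetric in query and knowledgebase", {
  set.seed(11)
  N <- 2000
  u <- as_cpg_set(runif(N) < 0.9)
  a <- as_cpg_set(runif(N) < 0.2)
  b <- as_cpg_set(runif(N) < 0.1)
  p_ab <- test_enrichment(a, list(knowledgebase("b", b, "d")), u)$p_value
  p_ba <- test_enrichment(b, list(knowledgebase("a", a, "d")), u)$p_value
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
})

test_that("empty knowledgebases yield degenerate records, and FDR is domain-wise", {
  N <- 50
  q <- cpg_set(N, 1:10)
  kbs <- list(knowledgebase("empty", cpg_set(N), "d1"),
              knowledgebase("hit", cpg_set(N, 1:10), "d1"),
              knowledgebase("other", cpg_set(N, 40:45), "d2"))
  res <- test_enrichment(q, kbs, NULL)
  expect_equal(res$p_value[1], 1)
  expect_true(res$degenerate[1])
  expect_identical(res$fdr, bh_fdr(res$p_value, res$domain))
  ranked <- rank_enrichment(res)
  expect_equal(ranked$kb[1], "hit")
})

test_that("BH within groups reproduces the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03), rep("a", 3)), rep(0.03, 3))
  expect_equal(bh_fdr(c(0.4, 0.2), c("a", "b")), c(0.4, 0.2))  # m = 1 per group
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    grp <- sample(c("g1", "g2"), length(p), TRUE)
    got <- bh_fdr(p, grp)
    for (g in unique(grp)) {
      expect_equal(got[grp == g], oracle_bh(p[grp == g]), tolerance = 1e-12)
    }
    expect_true(all(got >= p - 1e-12))
  }
})

test_that("npmi hits its endpoints and the worked independence example", {
  N <- 200
  a <- cpg_set(N, 1:20)
  expect_equal(npmi(a, a), 1)
  expect_equal(npmi(a, cpg_set(N, 30:40)), -1)
  # |U|=100, |A|=20, |B|=10, |A^B|=5 -> ln(2.5)/(-ln 0.05)
  u <- platform_universe(cpg_set(N, 1:100))
  A <- cpg_set(N, 1:20)
  B <- cpg_set(N, c(1:5, 90:94))
  expect_equal(npmi(A, B, u), log(0.05 / (0.2 * 0.1)) / (-log(0.05)),
               tolerance = 1e-12)
  expect_lt(abs(npmi(A, B, u) - 0.30587), 1e-5)
  expect_error(npmi(cpg_set(N), a), "nonempty")
})

test_that("npmi is symmetric and bounded on random set pairs", {
  set.seed(83)
  for (i in 1:40) {
    N <- 500
    a <- as_cpg_set(runif(N) < runif(1, 0.05, 0.5))
    b <- as_cpg_set(runif(N) < runif(1, 0.05, 0.5))
    if (set_size(a) == 0 || set_size(b) == 0) next
    v <- npmi(a, b)
    expect_true(v >= -1 && v <= 1)
    expect_equal(v, npmi(b, a), tolerance = 1e-12)
  }
})

test_that("enrichment survives restriction to a random sub-universe", {
  # the planted knowledgebase stays top-ranked after halving the universe
  set.seed(19)
  N <- 20000
  planted <- cpg_set(N, sample.int(N, 800))
  decoys <- lapply(1:10, function(i) {
    knowledgebase(sprintf("d%02d", i), cpg_set(N, sample.int(N, 800)), "d")
  })
  kbs <- c(list(knowledgebase("planted", planted, "d")), decoys)
  qm <- c(sample(set_members(planted), 400), sample.int(N, 1200))
  q <- cpg_set(N, unique(qm))
  full <- rank_enrichment(test_enrichment(q, kbs, NULL))
  expect_equal(full$kb[1], "planted")
  sub <- downsample_universe(as_cpg_set(rep(TRUE, N)), 1, seed = 5)
  res_sub <- rank_enrichment(test_enrichment(q, kbs, sub))
  expect_equal(res_sub$kb[1], "planted")
})
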