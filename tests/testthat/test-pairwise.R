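test_that("binary single-cell profiles at delta 1 call exact +1/-1 differences", {
  # sites: (a m,u) vs (b m,u)
  a <- mu_vector(c(1, 0, 1, 0, 0), c(0, 1, 0, 0, 1))
  b <- mu_vector(c(0, 1, 1, 0, 0), c(1, 0, 0, 0, 2))
  res <- call_dmc(a, b, delta_min = 1)
  expect_equal(set_members(res$universe$members), c(1L, 2L, 3L, 5L))
  expect_equal(set_members(res$hyper), 1L)   # beta 1 vs 0
  expect_equal(set_members(res$hypo), 2L)    # beta 0 vs 1
  # identical profiles: empty calls over the joint covered set
  same <- call_dmc(a, a, delta_min = 0.4)
  expect_equal(set_size(same$hyper), 0)
  expect_equal(set_size(same$hypo), 0)
  expect_error(call_dmc(mu_vector(0, 0), mu_vector(0, 0), 0.5), "empty")
  expect_error(call_dmc(a, b, delta_min = 1.5), "delta_min")
})

test_that("call_dmc equals the sitewise loop oracle on random sparse pairs", {
  for (seed in c(1, 2)) {
    n <- 3000
    a <- random_mu(seed, n, coverage = 0.4)
    b <- random_mu(seed + 100, n, coverage = 0.4)
    res <- call_dmc(a, b, delta_min = 0.4, cov_min = 1)
    ba <- beta_values(a); bb <- beta_values(b)
    # sitewise loop oracle applying the three rules one site at a time
    o_univ <- o_hyper <- o_hypo <- logical(n)
    for (i in seq_len(n)) {
      in_u <- coverage(a)[i] >= 1 && coverage(b)[i] >= 1
      o_univ[i] <- in_u
      o_hyper[i] <- in_u && (ba[i] - bb[i] >= 0.4 - 1e-12)
      o_hypo[i] <- in_u && (bb[i] - ba[i] >= 0.4 - 1e-12)
    }
    expect_identical(res$universe$members$bits, o_univ)
    expect_identical(res$hyper$bits, o_hyper)
    expect_identical(res$hypo$bits, o_hypo)
  }
})

test_that("swapping profiles exchanges hyper and hypo over the same universe", {
  a <- random_mu(7, 4000, coverage = 0.3)
  b <- random_mu(8, 4000, coverage = 0.3)
  ab <- call_dmc(a, b, delta_min = 0.4)
  ba <- call_dmc(b, a, delta_min = 0.4)
  expect_identical(ab$hyper$bits, ba$hypo$bits)
  expect_identical(ab$hypo$bits, ba$hyper$bits)
  expect_identical(ab$universe$members$bits, ba$universe$members$bits)
})

test_that("a user mask restricts the comparison universe", {
  a <- mu_vector(c(1, 1, 1), c(0, 0, 0))
  b <- mu_vector(c(0, 0, 0), c(1, 1, 1))
  mask <- cpg_set(3, c(1, 3))
  res <- call_dmc(a, b, delta_min = 1, mask = mask)
  expect_equal(set_members(res$universe$members), c(1L, 3L))
  expect_equal(set_members(res$hyper), c(1L, 3L))
})

test_that("dmc results tidy and glance into tabular summaries", {
  a <- mu_vector(c(1, 0, 1), c(0, 1, 0))
  b <- mu_vector(c(0, 0, 1), c(1, 1, 0))
  res <- call_dmc(a, b, delta_min = 1)
  td <- tidy(res)
  expect_equal(td$ordinal[td$direction == "hyper"], 1L)
  g <- glance(res)
  expect_equal(g$n_universe, 3)
  expect_equal(g$n_hyper, 1)
})

test_that("aggregation over knowledgebases matches the loop oracle", {
  n <- 2000
  s <- random_mu(21, n, coverage = 0.5)
  kbs <- lapply(1:5, function(i) {
    set.seed(300 + i)
    knowledgebase(sprintf("kb%d", i), cpg_set(n, sample.int(n, 200)), "d")
  })
  agg <- aggregate_kb(s, kbs)
  cov <- coverage(s)
  for (i in seq_along(kbs)) {
    sel <- set_members(kbs[[i]]$members)
    sel <- sel[cov[sel] > 0]
    expect_equal(agg$n_covered[i], length(sel))
    expect_equal(agg$sum_m[i], sum(s$m[sel]))
    expect_equal(agg$sum_u[i], sum(s$u[sel]))
    expect_equal(agg$mean_beta[i], sum(s$m[sel]) / sum(cov[sel]))
  }
  # knowledgebase with no covered member yields the NA sentinel
  uncov <- knowledgebase("empty", cpg_set(n, which(cov == 0)[1]), "d")
  expect_true(is.na(aggregate_kb(s, list(uncov))$mean_beta))
  # the all-sites knowledgebase reproduces the global pooled beta
  allkb <- knowledgebase("all", as_cpg_set(rep(TRUE, n)), "d")
  expect_equal(aggregate_kb(s, list(allkb))$mean_beta,
               sum(s$m) / sum(cov))
})

test_that("aggregation is additive under pseudobulk merging", {
  n <- 1500
  c1 <- random_mu(31, n, coverage = 0.2)
  c2 <- random_mu(32, n, coverage = 0.2)
  set.seed(33)
  kbs <- list(knowledgebase("k", cpg_set(n, sample.int(n, 400)), "d"))
  merged <- aggregate_kb(rowop(list(c1, c2), "sum_mu"), kbs)
  a1 <- aggregate_kb(c1, kbs); a2 <- aggregate_kb(c2, kbs)
  expect_equal(merged$sum_m, a1$sum_m + a2$sum_m)
  expect_equal(merged$sum_u, a1$sum_u + a2$sum_u)
  expect_equal(merged$mean_beta,
               (a1$sum_m + a2$sum_m) / (a1$sum_m + a2$sum_m + a1$sum_u + a2$sum_u))
})

test_that("per-site weighting averages betas instead of pooling counts", {
  s <- mu_vector(c(4, 1), c(0, 9))   # betas 1 and 0.1
  kb <- list(knowledgebase("k", cpg_set(2, 1:2), "d"))
  expect_equal(aggregate_kb(s, kb, weighting = "count")$mean_beta, 5 / 14)
  expect_equal(aggregate_kb(s, kb, weighting = "site")$mean_beta, 0.55)
})

test_that("feature matrices compose repeated aggregation calls", {
  n <- 1000
  samples <- list(s1 = random_mu(41, n), s2 = random_mu(42, n))
  kbs <- lapply(1:3, function(i) {
    set.seed(400 + i)
    knowledgebase(sprintf("kb%d", i), cpg_set(n, sample.int(n, 150)), "d")
  })
  fm <- feature_matrix(samples, kbs)
  expect_equal(dim(fm), c(2, 3))
  expect_equal(fm["s1", ], setNames(aggregate_kb(samples$s1, kbs)$mean_beta,
                                    colnames(fm)))
  # permuting samples permutes rows only
  fm2 <- feature_matrix(rev(samples), kbs)
  expect_equal(fm2[c("s1", "s2"), ], fm)
})
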