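small_cfg <- function(seed = 1, ...) {
  fixture_config(seed = seed, n_chromosomes = 2, cpgs_per_chromosome = 5000,
                 kb_count = 20, query_size = 1000, n_dmc = 600, ...)
}

test_that("generated indices have the configured shape and legal gaps", {
  cfg <- small_cfg()
  idx <- gen_index(cfg)
  expect_equal(idx$n, 10000)
  expect_equal(nrow(idx$chroms), 2)
  for (p in idx$positions) expect_true(all(diff(p) >= 2))
  # regeneration equality
  expect_identical(gen_index(cfg)$positions, idx$positions)
  expect_false(identical(gen_index(small_cfg(seed = 2))$positions,
                         idx$positions))
})

test_that("generated knowledgebases respect sizes and flag planted truth", {
  cfg <- small_cfg()
  idx <- gen_index(cfg)
  gk <- gen_knowledgebases(idx, cfg)
  expect_length(gk$kbs, 20)
  sizes <- vapply(gk$kbs, function(k) set_size(k$members), numeric(1))
  expect_true(all(sizes >= cfg$kb_size_range[1] &
                    sizes <= cfg$kb_size_range[2]))
  expect_equal(sum(gk$truth$planted), 1)
  expect_true(startsWith(gk$truth$name[gk$truth$planted], "planted"))
  expect_identical(
    gen_knowledgebases(idx, cfg)$kbs[[3]]$members$bits,
    gk$kbs[[3]]$members$bits)
})

test_that("decoy overlaps with a uniform query match the hypergeometric mean", {
  cfg <- small_cfg(seed = 6, planted_enrichment_fold = 1)
  idx <- gen_index(cfg)
  gk <- gen_knowledgebases(idx, cfg)
  set.seed(99)
  K <- set_size(gk$kbs[[2]]$members)
  n_draw <- 1000
  overlaps <- vapply(1:100, function(i) {
    overlap_count(cpg_set(idx$n, sample.int(idx$n, n_draw)),
                  gk$kbs[[2]]$members)
  }, numeric(1))
  mu <- n_draw * K / idx$n
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - mu), 3 * se)
})

test_that("planted queries realise the configured enrichment fold", {
  cfg <- small_cfg(seed = 3)
  idx <- gen_index(cfg)
  gk <- gen_knowledgebases(idx, cfg)
  q <- gen_query(idx, gk$kbs, gk$truth, cfg)
  expect_equal(set_size(q), cfg$query_size)
  planted <- gk$kbs[[which(gk$truth$planted)]]$members
  # realized per-site relative likelihood of planted membership (odds ratio)
  odds_fold <- function(q) {
    x <- overlap_count(q, planted)
    (x / (set_size(q) - x)) / (set_size(planted) / (idx$n - set_size(planted)))
  }
  expect_lt(abs(odds_fold(q) - cfg$planted_enrichment_fold),
            0.2 * cfg$planted_enrichment_fold)
  # fold 1 gives a uniform query over the index
  q1 <- gen_query(idx, gk$kbs, gk$truth,
                  small_cfg(seed = 3, planted_enrichment_fold = 1))
  expect_lt(abs(odds_fold(q1) - 1), 0.35)
  expect_error(small_cfg(planted_enrichment_fold = 0.5), ">= 1")
})

test_that("graded queries weight sites by their summed knowledgebase folds", {
  cfg <- small_cfg(seed = 8, kb_size_range = c(200, 350))
  idx <- gen_index(cfg)
  gk <- gen_knowledgebases(idx, cfg)
  folds <- seq(1, 10, length.out = length(gk$kbs))
  q <- gen_graded_query(idx, gk$kbs, folds, cfg)
  expect_equal(set_size(q), cfg$query_size)
  # realized query densities follow the fold grading
  r <- vapply(seq_along(gk$kbs), function(i) {
    overlap_count(q, gk$kbs[[i]]$members) / set_size(gk$kbs[[i]]$members)
  }, numeric(1))
  expect_gt(cor(folds, r, method = "spearman"), 0.8)
  expect_gt(r[length(r)], r[1])
  expect_identical(gen_graded_query(idx, gk$kbs, folds, cfg)$bits, q$bits)
  expect_error(gen_graded_query(idx, gk$kbs, folds[-1], cfg), "length")
})

test_that("methylome pairs carry recoverable planted differences", {
  cfg <- small_cfg(seed = 5, coverage_fraction = 0.3)
  idx <- gen_index(cfg)
  pair <- gen_methylome_pair(idx, cfg)
  # realized coverage within 3 SE of the target
  n <- idx$n
  se <- sqrt(cfg$coverage_fraction * (1 - cfg$coverage_fraction) / n)
  expect_lt(abs(mean(coverage(pair$a) > 0) - cfg$coverage_fraction), 3 * se)
  # planted sites jointly covered are recovered at delta 0.8
  res <- call_dmc(pair$a, pair$b, delta_min = 0.8)
  joint <- pair$truth$hyper$bits & res$universe$members$bits
  if (sum(joint) > 0) {
    sens <- sum(res$hyper$bits & joint) / sum(joint)
    expect_gte(sens, 0.95)
  }
  expect_identical(gen_methylome_pair(idx, cfg)$a$m, pair$a$m)
})

test_that("beta matrices stay in range and regenerate identically", {
  cfg <- fixture_config(seed = 9, n_chromosomes = 1,
                        cpgs_per_chromosome = 500)
  idx <- gen_index(cfg)
  gm <- gen_beta_matrix(idx, cfg)
  expect_equal(dim(gm$betas), c(24, 500))
  rng <- range(gm$betas, na.rm = TRUE)
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  expect_equal(mean(is.na(gm$betas)), cfg$missing_fraction, tolerance = 0.3)
  expect_identical(gen_beta_matrix(idx, cfg)$betas, gm$betas)
  # zero noise, no missingness: recovery is exact by construction
  cfg0 <- fixture_config(seed = 10, n_chromosomes = 1,
                         cpgs_per_chromosome = 300, beta_noise_sd = 0,
                         missing_fraction = 0)
  gm0 <- gen_beta_matrix(gen_index(cfg0), cfg0)
  sig0 <- discover_signatures(gm0$betas, gm0$contrast)
  expect_identical(sig0$hyper_markers$bits, gm0$truth$hyper$bits)
  expect_identical(sig0$hypo_markers$bits, gm0$truth$hypo$bits)
})
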