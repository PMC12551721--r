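#' Synthetic-data generator configuration
#'
#' Every generator in cgkit is a pure function of its configuration and seed:
#' regenerating with an identical config yields identical output. The
#' defaults emulate desk-scale versions of the data regimes the toolkit
#' targets: a 100,000-CpG index at human-like CpG density (one CpG per ~100
#' bp), knowledgebases of 500-2000 CpGs, single-cell-like coverage (10% of
#' sites), queries covering 10% of the index, and planted enrichment or
#' differential structure with known truth.
#'
#' @param seed Master seed.
#' @param n_chromosomes,cpgs_per_chromosome Index shape (N = their product).
#' @param mean_gap_bp Mean inter-CpG gap in bp (geometric, minimum 2).
#' @param kb_count Total knowledgebases, including the planted ones.
#' @param kb_size_range Knowledgebase size range (uniform).
#' @param planted_kb_count Number of planted (truly enriched) knowledgebases.
#' @param planted_enrichment_fold Relative enrichment of planted-kb sites in
#'   the query (>= 1; 1 = uniform query).
#' @param query_size Query cardinality.
#' @param coverage_fraction Per-sample fraction of covered sites (single-cell
#'   sparsity regime, typically 0.0005-0.1).
#' @param extra_depth_mean Mean of the Poisson extra read depth added to the
#'   single guaranteed read at covered sites.
#' @param error_rate Per-read bisulfite error/ conversion-failure rate.
#' @param n_dmc Planted differential sites for methylome pairs.
#' @param beta_noise_sd Within-group beta noise SD for beta matrices.
#' @param planted_delta_beta Planted group beta difference for beta matrices.
#' @param n_marker_hyper,n_marker_hypo Planted marker counts for beta
#'   matrices.
#' @param missing_fraction Missingness rate in beta matrices.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1,
                           n_chromosomes = 5,
                           cpgs_per_chromosome = 20000,
                           mean_gap_bp = 100,
                           kb_count = 100,
                           kb_size_range = c(500, 2000),
                           planted_kb_count = 1,
                           planted_enrichment_fold = 10,
                           query_size = 10000,
                           coverage_fraction = 0.1,
                           extra_depth_mean = 0.5,
                           error_rate = 0.002,
                           n_dmc = 5000,
                           beta_noise_sd = 0.05,
                           planted_delta_beta = 0.6,
                           n_marker_hyper = 50,
                           n_marker_hypo = 50,
                           missing_fraction = 0.05) {
  if (planted_enrichment_fold < 1) abort("`planted_enrichment_fold` must be >= 1.")
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a toy CpG index
#'
#' Inter-CpG gaps are geometric with the configured mean and a hard minimum
#' of 2 bp (CG dinucleotides cannot overlap under the merged-strand
#' convention).
#'
#' @param config A [fixture_config()].
#' @return A [build_index()] object with
#'   `n = n_chromosomes * cpgs_per_chromosome`.
#' @export
gen_index <- function(config = fixture_config()) {
  with_seed(config$seed, {
    tbl <- list_rbind(map(seq_len(config$n_chromosomes), function(ci) {
      gaps <- 2 + rgeom(config$cpgs_per_chromosome,
                        prob = 1 / (config$mean_gap_bp - 1))
      tibble(chrom = sprintf("chr%d", ci), start = cumsum(gaps))
    }))
    build_index(tbl, reference_name = sprintf("synthetic_seed%d", config$seed))
  })
}

#' Generate knowledgebases with planted truth
#'
#' Decoy knowledgebases are uniform random CpG sets; the first
#' `planted_kb_count` knowledgebases are flagged as planted in the truth
#' table (their enrichment is realised later by [gen_query()], which
#' oversamples their sites).
#'
#' @param index A [build_index()] object.
#' @param config A [fixture_config()].
#' @return A list with `kbs` (list of [knowledgebase()]s, domain
#'   `"synthetic"`) and `truth` (tibble: `name`, `planted`, `size`).
#' @export
gen_knowledgebases <- function(index, config = fixture_config()) {
  with_seed(config$seed + 1, {
    sizes <- sample(config$kb_size_range[1]:config$kb_size_range[2],
                    config$kb_count, replace = TRUE)
    planted <- seq_len(config$kb_count) <= config$planted_kb_count
    names <- ifelse(planted,
                    sprintf("planted%02d", seq_len(config$kb_count)),
                    sprintf("decoy%03d", seq_len(config$kb_count)))
    kbs <- map(seq_len(config$kb_count), function(i) {
      knowledgebase(names[i],
                    cpg_set(index$n, sample.int(index$n, sizes[i])),
                    "synthetic")
    })
    list(kbs = kbs, truth = tibble(name = names, planted = planted,
                                   size = sizes))
  })
}

#' Generate a query enriched in the planted knowledgebases
#'
#' Query members are drawn so that sites inside planted knowledgebases are
#' `planted_enrichment_fold` times more likely than background sites: the
#' planted share of the query is binomial with the fold-weighted probability,
#' then both strata are sampled uniformly without replacement.
#'
#' @param index A [build_index()] object.
#' @param kbs,truth Output of [gen_knowledgebases()].
#' @param config A [fixture_config()].
#' @return A [cpg_set()] query of `query_size` CpGs.
#' @export
gen_query <- function(index, kbs, truth, config = fixture_config()) {
  planted_bits <- Reduce(`|`, lapply(kbs[truth$planted],
                                     function(k) k$members$bits),
                         init = logical(index$n))
  p_idx <- which(planted_bits)
  b_idx <- which(!planted_bits)
  fold <- config$planted_enrichment_fold
  w_planted <- fold * length(p_idx)
  p_share <- w_planted / (w_planted + length(b_idx))
  with_seed(config$seed + 2, {
    k <- min(rbinom(1, config$query_size, p_share), length(p_idx))
    members <- c(sample(p_idx, k),
                 sample(b_idx, config$query_size - k))
    cpg_set(index$n, members)
  })
}

#' Generate a query with graded enrichment across knowledgebases
#'
#' Whereas [gen_query()] plants a single enrichment fold against a background
#' of null decoys, this generator gives every knowledgebase its own fold,
#' emulating the graded overlap structure of real annotation families
#' (chromatin states, for example, differ in their true enrichment for almost
#' any query). Site weights are `1 + sum(fold_i - 1)` over the knowledgebases
#' containing the site, and the query is a weighted sample without
#' replacement (exponential-key method).
#'
#' @param index A [build_index()] object.
#' @param kbs A list of [knowledgebase()]s.
#' @param folds Numeric vector of per-knowledgebase enrichment folds
#'   (>= 1), same length as `kbs`.
#' @param config A [fixture_config()] (supplies `query_size` and the seed).
#' @return A [cpg_set()] query.
#' @export
gen_graded_query <- function(index, kbs, folds, config = fixture_config()) {
  if (length(folds) != length(kbs)) abort("`folds` must match `kbs` in length.")
  if (any(folds < 1)) abort("all `folds` must be >= 1.")
  w <- rep(1, index$n)
  for (i in seq_along(kbs)) {
    mb <- set_members(kbs[[i]]$members)
    w[mb] <- w[mb] + (folds[i] - 1)
  }
  with_seed(config$seed + 2, {
    keys <- -log(runif(index$n)) / w
    cpg_set(index$n, sort(order(keys)[seq_len(config$query_size)]))
  })
}

sample_mu <- function(beta_true, covered, extra_depth_mean, error_rate) {
  n <- length(beta_true)
  depth <- ifelse(covered, 1 + rpois(n, extra_depth_mean), 0)
  beta_eff <- beta_true * (1 - error_rate) + (1 - beta_true) * error_rate
  m <- rbinom(n, depth, beta_eff)
  mu_vector(m, depth - m)
}

#' Generate a pair of sparse methylomes with planted differences
#'
#' Both profiles share a bimodal baseline methylome; at `n_dmc` planted sites
#' the true betas are fully separated (1 vs 0, half in each direction,
#' mimicking cell-type marker CpGs). Each profile covers a Bernoulli
#' `coverage_fraction` of sites at small read depth, and each read carries an
#' `error_rate` chance of reporting the wrong allele.
#'
#' @param index A [build_index()] object.
#' @param config A [fixture_config()].
#' @return A list with `a`, `b` ([mu_vector()]s) and `truth` (list of `hyper`
#'   and `hypo` [cpg_set()]s of planted sites, direction a-relative-to-b).
#' @export
gen_methylome_pair <- function(index, config = fixture_config()) {
  with_seed(config$seed + 3, {
    n <- index$n
    base <- stats::rbeta(n, 0.4, 0.4)
    planted <- sample.int(n, config$n_dmc)
    half <- length(planted) %/% 2
    hyper <- planted[seq_len(half)]          # methylated in a, not in b
    hypo <- planted[(half + 1):length(planted)]
    beta_a <- base; beta_b <- base
    beta_a[hyper] <- 1; beta_b[hyper] <- 0
    beta_a[hypo] <- 0; beta_b[hypo] <- 1
    a <- sample_mu(beta_a, runif(n) < config$coverage_fraction,
                   config$extra_depth_mean, config$error_rate)
    b <- sample_mu(beta_b, runif(n) < config$coverage_fraction,
                   config$extra_depth_mean, config$error_rate)
    list(a = a, b = b,
         truth = list(hyper = cpg_set(n, hyper), hypo = cpg_set(n, hypo)))
  })
}

#' Generate a group-structured beta matrix with planted markers
#'
#' Emulates the input of signature discovery: two sample groups over a CpG
#' index, with `n_marker_hyper` sites methylated high in the target group and
#' low in the background (and vice versa for hypo markers), separated by
#' `planted_delta_beta` centred on 0.5. Null sites share a common baseline.
#' Gaussian noise of SD `beta_noise_sd` is added and values are truncated to
#' `[0, 1]`; a `missing_fraction` of entries is set to `NA`.
#'
#' @param index A [build_index()] object (its `n` is the number of CpGs).
#' @param config A [fixture_config()].
#' @param n_target,n_background Group sizes (default 12 and 12).
#' @return A list with `betas` (matrix, samples x CpGs, rownames `t1..`/
#'   `b1..`), `contrast` (a [contrast_spec()]) and `truth` (list of `hyper`
#'   and `hypo` [cpg_set()]s).
#' @export
gen_beta_matrix <- function(index, config = fixture_config(),
                            n_target = 12, n_background = 12) {
  with_seed(config$seed + 4, {
    n <- index$n
    planted <- sample.int(n, config$n_marker_hyper + config$n_marker_hypo)
    hyper <- planted[seq_len(config$n_marker_hyper)]
    hypo <- planted[config$n_marker_hyper + seq_len(config$n_marker_hypo)]
    base <- runif(n, 0.2, 0.8)
    half_delta <- config$planted_delta_beta / 2
    mu_t <- base; mu_b <- base
    mu_t[hyper] <- 0.5 + half_delta; mu_b[hyper] <- 0.5 - half_delta
    mu_t[hypo] <- 0.5 - half_delta; mu_b[hypo] <- 0.5 + half_delta
    n_samples <- n_target + n_background
    means <- rbind(matrix(mu_t, n_target, n, byrow = TRUE),
                   matrix(mu_b, n_background, n, byrow = TRUE))
    betas <- means + matrix(rnorm(n_samples * n, 0, config$beta_noise_sd),
                            n_samples, n)
    betas <- pmin(pmax(betas, 0), 1)
    betas[matrix(runif(n_samples * n) < config$missing_fraction,
                 n_samples, n)] <- NA
    rownames(betas) <- c(sprintf("t%d", seq_len(n_target)),
                         sprintf("b%d", seq_len(n_background)))
    list(betas = betas,
         contrast = contrast_spec("target_vs_background",
                                  sprintf("t%d", seq_len(n_target)),
                                  sprintf("b%d", seq_len(n_background))),
         truth = list(hyper = cpg_set(n, hyper), hypo = cpg_set(n, hypo)))
  })
}
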