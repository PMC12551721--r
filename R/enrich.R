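#' Overlap count between CpG sets
#'
#' Cardinality of `a AND b` (optionally `AND universe`): vectorised bit
#' counting, with work proportional to the vector length and independent of
#' the set cardinalities.
#'
#' @param a,b [cpg_set()]s of equal dimension.
#' @param universe Optional [cpg_set()] or `universe` restricting the count.
#' @return The overlap count.
#' @export
overlap_count <- function(a, b, universe = NULL) {
  stopifnot(inherits(a, "cpg_set"), inherits(b, "cpg_set"))
  check_same_dim(a, b)
  bits <- a$bits & b$bits
  if (!is.null(universe)) bits <- bits & as_universe_bits(universe, a$n_bits)
  sum(bits)
}

hyper_p <- function(x, K, n, N, side) {
  # population N, K successes, n draws, x observed successes
  if (side == "enrich") {
    phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  } else if (side == "deplete") {
    phyper(x, K, N - K, n)
  } else {
    # Fisher-style two-sided: total probability of tables no more likely
    support <- max(0, n + K - N):min(n, K)
    d <- dhyper(support, K, N - K, n)
    sum(d[d <= d[match(x, support)] * (1 + 1e-7)])
  }
}

log2_odds <- function(x, K, n, N, correct) {
  a <- x; b <- n - x; cc <- K - x; d <- N - n - K + x
  if (correct && any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  log2((a * d) / (b * cc))
}

#' Hypergeometric CpG-set enrichment testing
#'
#' Tests the overlap of a query CpG set against each knowledgebase inside a
#' universe. With `N = |U|`, `K = |KB within U|`, `n = |Q within U|` and
#' `x = |Q and KB within U|`, the enrich-side p-value is `P(X >= x)` and the
#' deplete-side `P(X <= x)` for `X ~ Hypergeometric(N, K, n)`; the two-sided
#' p-value is Fisher's exact two-sided. Query and knowledgebases are always
#' intersected into the universe first, and all reported counts are
#' post-intersection, so results computed in a CpG subspace are directly
#' comparable to whole-genome results. FDR (Benjamini-Hochberg) is computed
#' within each knowledgebase domain, since each domain is its own hypothesis
#' space.
#'
#' The log2 odds ratio comes from the 2x2 table `(x, n-x, K-x, N-n-K+x)`;
#' `log2_or_corrected` adds 0.5 to every cell whenever any cell is zero, and
#' is the ranking tie-break after the p-value. A knowledgebase with no members
#' in the universe yields a degenerate record with `p_value = 1`.
#'
#' @param query A [cpg_set()].
#' @param kbs A list of [knowledgebase()]s (a single one is accepted).
#' @param universe A `universe`, a [cpg_set()], or `NULL` for the full index
#'   space.
#' @param side `"enrich"`, `"deplete"` or `"two_sided"`.
#' @return A tibble of class `cgkit_enrichment`, one row per knowledgebase:
#'   `kb`, `domain`, `n_universe`, `n_query`, `n_kb`, `overlap`, `log2_or`,
#'   `log2_or_corrected`, `p_value`, `fdr`, `side`, `degenerate`, ordered as
#'   supplied. Use [rank_enrichment()] for the documented ranking.
#' @export
test_enrichment <- function(query, kbs, universe = NULL,
                            side = c("enrich", "deplete", "two_sided")) {
  side <- match.arg(side)
  stopifnot(inherits(query, "cpg_set"))
  if (inherits(kbs, "knowledgebase")) kbs <- list(kbs)
  ubits <- as_universe_bits(universe, query$n_bits)
  q <- query$bits & ubits
  N <- sum(ubits)
  n <- sum(q)
  if (n == 0) abort("the query has no members inside the universe.")
  rows <- map(kbs, function(kb) {
    stopifnot(inherits(kb, "knowledgebase"))
    check_same_dim(kb$members, query)
    k <- kb$members$bits & ubits
    K <- sum(k)
    x <- sum(q & k)
    degenerate <- K == 0 || K == N
    p <- if (K == 0) 1 else hyper_p(x, K, n, N, side)
    kb_name <- kb$name
    kb_domain <- kb$domain
    tibble(
      kb = kb_name, domain = kb_domain,
      n_universe = N, n_query = n, n_kb = K, overlap = x,
      log2_or = if (K == 0) NA_real_ else log2_odds(x, K, n, N, correct = FALSE),
      log2_or_corrected = if (K == 0) NA_real_ else log2_odds(x, K, n, N, correct = TRUE),
      p_value = p, side = side, degenerate = degenerate
    )
  })
  out <- list_rbind(rows)
  out$fdr <- bh_fdr(out$p_value, out$domain)
  out <- out[c("kb", "domain", "n_universe", "n_query", "n_kb", "overlap",
               "log2_or", "log2_or_corrected", "p_value", "fdr", "side",
               "degenerate")]
  class(out) <- c("cgkit_enrichment", class(out))
  out
}

#' Rank an enrichment table
#'
#' Orders records by p-value, breaking ties by the magnitude of the
#' continuity-corrected log2 odds ratio (larger first) and then by input
#' order, giving the total order used for top-term comparisons.
#'
#' @param records A [test_enrichment()] result.
#' @return The records, ranked, with a `rank` column.
#' @export
rank_enrichment <- function(records) {
  ord <- order(records$p_value, -abs(records$log2_or_corrected),
               seq_len(nrow(records)), na.last = TRUE)
  out <- records[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Benjamini-Hochberg FDR within groups
#'
#' Applies the BH step-up procedure independently within each group label
#' (testing domain), so a large domain cannot dilute or inflate the q-values
#' of a small one.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param group_labels Group labels, same length as `p_values`.
#' @return Numeric q-values.
#' @export
bh_fdr <- function(p_values, group_labels) {
  if (length(p_values) != length(group_labels)) {
    abort("`p_values` and `group_labels` must have the same length.")
  }
  out <- numeric(length(p_values))
  for (g in unique(group_labels)) {
    sel <- group_labels == g
    out[sel] <- p.adjust(p_values[sel], method = "BH")
  }
  out
}

#' Normalized pointwise mutual information between CpG sets
#'
#' Co-occurrence score in `[-1, 1]`: -1 when the sets never co-occur in the
#' universe, 0 under independence, +1 when they always co-occur (identical
#' traces in the universe). With `p_a = |A in U| / |U|`, `p_b`, and the joint
#' `p_ab`, NPMI is `ln(p_ab / (p_a p_b)) / (-ln p_ab)`; the endpoints are the
#' limits of that expression.
#'
#' @param a,b [cpg_set()]s.
#' @param universe A `universe` or [cpg_set()]; `NULL` uses the full space.
#' @return The NPMI value.
#' @export
npmi <- function(a, b, universe = NULL) {
  stopifnot(inherits(a, "cpg_set"), inherits(b, "cpg_set"))
  check_same_dim(a, b)
  ubits <- as_universe_bits(universe, a$n_bits)
  abits <- a$bits & ubits
  bbits <- b$bits & ubits
  nu <- sum(ubits)
  na <- sum(abits)
  nb <- sum(bbits)
  if (na == 0 || nb == 0) abort("both sets must be nonempty inside the universe.")
  nab <- sum(abits & bbits)
  if (nab == 0) return(-1)
  if (nab == na && nab == nb) return(1)
  p_a <- na / nu; p_b <- nb / nu; p_ab <- nab / nu
  log(p_ab / (p_a * p_b)) / (-log(p_ab))
}

ks_statistic <- function(values, membership) {
  # two-sample KS D between values[membership] and values[!membership]
  n1 <- sum(membership)
  n2 <- sum(!membership)
  ord <- order(values)
  z <- cumsum(ifelse(membership[ord], 1 / n1, -1 / n2))
  # collapse ties: evaluate only at the last index of each tied run
  v <- values[ord]
  last <- c(v[-1] != v[-length(v)], TRUE)
  max(abs(z[last]))
}

#' Set-versus-continuous enrichment (KS permutation test)
#'
#' Compares a continuous per-CpG variable (e.g. conservation, replication
#' timing) between a target set and the rest of the universe with the
#' two-sample Kolmogorov-Smirnov statistic. Significance comes from a
#' permutation null (random relabelings of target membership within the
#' universe); a moment-matched Gaussian fitted to the permuted statistics is
#' offered as a cheaper alternative for large inputs.
#'
#' @param target A [cpg_set()] or [knowledgebase()].
#' @param values Per-CpG numeric vector over the index (NA = missing).
#' @param universe A `universe` or [cpg_set()]; `NULL` for all sites with
#'   non-missing values.
#' @param n_perm Number of permutations (at least 99 for permutation mode).
#' @param null `"permutation"` (add-one rule p-value) or `"gaussian"`
#'   (upper-tail probability of a normal moment-matched to the permuted
#'   statistics).
#' @param seed Integer seed (required).
#' @return A list with `statistic` (observed D), `p_value`, `n_target`,
#'   `n_background` and `null`.
#' @export
test_continuous <- function(target, values, universe = NULL, n_perm = 999,
                            null = c("permutation", "gaussian"), seed) {
  null <- match.arg(null)
  if (inherits(target, "knowledgebase")) target <- target$members
  stopifnot(inherits(target, "cpg_set"))
  if (length(values) != target$n_bits) abort("`values` dimension mismatch.")
  ubits <- as_universe_bits(universe, target$n_bits) & !is.na(values)
  idx <- which(ubits)
  v <- values[idx]
  memb <- target$bits[idx]
  if (sum(memb) < 2 || sum(!memb) < 2) {
    abort("need at least 2 values on each side of the split.")
  }
  if (null == "permutation" && n_perm < 99) abort("`n_perm` must be >= 99.")
  d_obs <- ks_statistic(v, memb)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) ks_statistic(v, sample(memb)),
           numeric(1))
  })
  p <- if (null == "permutation") {
    (1 + sum(d_null >= d_obs)) / (n_perm + 1)
  } else {
    pnorm(d_obs, mean = mean(d_null), sd = sd(d_null), lower.tail = FALSE)
  }
  list(statistic = d_obs, p_value = p, n_target = sum(memb),
       n_background = sum(!memb), null = null)
}

#' Poisson genomic proximity test
#'
#' Asks whether a query CpG set is more spatially clustered than random CpGs
#' from the same index. The genome is tiled into fixed consecutive windows
#' (1500 bp by default); the observed statistic counts query CpGs that share a
#' window with at least one other query CpG (`events = "members"`), or the
#' number of multi-occupancy windows (`events = "bins"`). The null rate
#' `lambda` is the mean statistic over `n_sim` uniform random draws of equally
#' many CpGs from the index, and the p-value is `P(X >= observed)` for
#' `X ~ Poisson(lambda)`.
#'
#' The member-count definition is the default reading of "CpGs co-occurring in
#' a window"; note that in the rare-pair regime it counts both members of each
#' pair and is overdispersed relative to the Poisson null, so its p-values are
#' an approximation. The bin-count statistic matches the Poisson rare-event
#' null and is the calibrated choice (see the methods vignette).
#'
#' @param query A [cpg_set()] with at least 2 members.
#' @param index The [build_index()] object the set is keyed to.
#' @param window_bp Window width in bp (default 1500).
#' @param n_sim Number of null simulations for `lambda` (default 1000).
#' @param seed Integer seed (required unless `lambda` is supplied).
#' @param events `"members"` or `"bins"`.
#' @param lambda Optional precomputed null rate (skips simulation), e.g. for
#'   batches of equally sized queries on one index.
#' @return A list with `observed_events`, `lambda`, `lambda_se` (simulation
#'   standard error; `NA` when `lambda` was supplied), `p_value`, `n_sim`,
#'   `events`.
#' @export
proximity_test <- function(query, index, window_bp = 1500, n_sim = 1000,
                           seed = NULL, events = c("members", "bins"),
                           lambda = NULL) {
  events <- match.arg(events)
  stopifnot(inherits(query, "cpg_set"), inherits(index, "cpg_index"))
  if (query$n_bits != index$n) abort("query dimension does not match the index.")
  q_size <- set_size(query)
  if (q_size < 2) abort("the query must contain at least 2 CpGs.")
  bin_ids <- global_bin_ids(index, window_bp)
  n_bins <- max(bin_ids)
  stat <- function(ordinals) {
    cnt <- tabulate(bin_ids[ordinals], nbins = n_bins)
    if (events == "members") sum(cnt[cnt >= 2]) else sum(cnt >= 2)
  }
  obs <- stat(set_members(query))
  lambda_se <- NA_real_
  if (is.null(lambda)) {
    sims <- with_seed(seed, {
      vapply(seq_len(n_sim), function(i) stat(sample.int(index$n, q_size)),
             numeric(1))
    })
    lambda <- mean(sims)
    lambda_se <- sd(sims) / sqrt(n_sim)
  }
  p <- if (lambda == 0) {
    as.numeric(obs == 0)  # degenerate null: any event is unexpected
  } else {
    ppois(obs - 1, lambda, lower.tail = FALSE)
  }
  list(observed_events = obs, lambda = lambda, lambda_se = lambda_se,
       p_value = p, n_sim = if (is.na(lambda_se)) NA_integer_ else n_sim,
       events = events)
}

global_bin_ids <- function(index, window_bp) {
  # consecutive fixed windows per chromosome, distinct across chromosomes
  ids <- integer(index$n)
  base <- 0L
  at <- 1L
  for (cn in index$chroms$name) {
    p <- index$positions[[cn]]
    local <- p %/% window_bp + 1
    ids[at:(at + length(p) - 1L)] <- base + local
    base <- base + max(local)
    at <- at + length(p)
  }
  ids
}
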