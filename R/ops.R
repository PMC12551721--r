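# Site-wise manipulation of index-keyed vectors: subsetting into a subspace,
# masking, seeded downsampling, row-wise combination, and binarization.

with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("an explicit `seed` is required.")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

vector_n <- function(v) {
  if (inherits(v, "cpg_set")) v$n_bits
  else if (inherits(v, "mu_vector") || inherits(v, "state_vector")) v$n_sites
  else length(v)
}

#' Subset a vector into the subspace of kept sites
#'
#' Re-indexes `v` into the subspace defined by `keep`, preserving site order.
#' The result has `set_size(keep)` sites; subsetting with a full mask is the
#' identity.
#'
#' @param v A [cpg_set()], [mu_vector()], [state_vector()] or numeric vector.
#' @param keep A [cpg_set()] of the same dimension naming the sites to keep.
#' @return A vector of the same type over the kept subspace.
#' @export
subset_vector <- function(v, keep) {
  stopifnot(inherits(keep, "cpg_set"))
  if (vector_n(v) != keep$n_bits) abort("dimension mismatch between `v` and `keep`.")
  idx <- which(keep$bits)
  if (inherits(v, "cpg_set")) new_cpg_set(v$bits[idx])
  else if (inherits(v, "mu_vector")) mu_vector(v$m[idx], v$u[idx])
  else if (inherits(v, "state_vector")) state_vector(v$labels[v$codes[idx]], v$labels)
  else v[idx]
}

#' Mask a vector, keeping its dimension
#'
#' Sites outside `keep` become non-members (sets), uncovered (MU vectors,
#' i.e. counts zeroed) or `NA` (float vectors). State vectors cannot be
#' masked (they have no missing state).
#'
#' @inheritParams subset_vector
#' @export
mask_vector <- function(v, keep) {
  stopifnot(inherits(keep, "cpg_set"))
  if (vector_n(v) != keep$n_bits) abort("dimension mismatch between `v` and `keep`.")
  if (inherits(v, "cpg_set")) new_cpg_set(v$bits & keep$bits)
  else if (inherits(v, "mu_vector")) {
    mu_vector(ifelse(keep$bits, v$m, 0), ifelse(keep$bits, v$u, 0))
  } else if (is.numeric(v)) {
    ifelse(keep$bits, v, NA_real_)
  } else abort("state vectors cannot be masked (no missing state).")
}

#' Seeded downsampling of a vector
#'
#' For a bit set, retains a random subset of member sites; for an MU vector, a
#' random subset of covered sites (others become uncovered); for a float
#' vector, a random subset of non-missing sites. `mode = "exact"` (default)
#' samples exactly `ceiling(fraction * k)` of the k eligible sites without
#' replacement; `mode = "bernoulli"` keeps each independently with probability
#' `fraction`. Deterministic per seed; the caller's RNG state is untouched.
#'
#' @param v The vector to downsample.
#' @param fraction Retention fraction in (0, 1] (use `1 / 2^k` for halving
#'   ladders).
#' @param seed Integer seed (required).
#' @param mode `"exact"` or `"bernoulli"`.
#' @export
downsample_vector <- function(v, fraction, seed, mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  eligible <- if (inherits(v, "cpg_set")) which(v$bits)
  else if (inherits(v, "mu_vector")) which(v$m + v$u > 0)
  else if (is.numeric(v)) which(!is.na(v))
  else abort("downsampling is defined for set, mu and float vectors.")
  kept <- with_seed(seed, {
    if (mode == "exact") {
      target <- ceiling(fraction * length(eligible))
      sort(sample(eligible, target))
    } else {
      eligible[runif(length(eligible)) < fraction]
    }
  })
  keep_bits <- logical(vector_n(v))
  keep_bits[kept] <- TRUE
  mask_vector(v, new_cpg_set(keep_bits))
}

#' Row-wise operations across samples
#'
#' Combines several vectors of equal dimension site by site: `sum_mu` adds M
#' and U counts (the pseudobulk merge), `mean_beta` averages per-sample beta
#' values over covered samples (`NA` where no sample covers a site), `union`
#' and `intersection` combine bit sets.
#'
#' @param vectors A list of vectors of one type and dimension.
#' @param op One of `"sum_mu"`, `"mean_beta"`, `"union"`, `"intersection"`.
#' @return A [mu_vector()] for `sum_mu`, a numeric vector for `mean_beta`, a
#'   [cpg_set()] for the set operations.
#' @export
rowop <- function(vectors, op = c("sum_mu", "mean_beta", "union", "intersection")) {
  op <- match.arg(op)
  if (length(vectors) == 0L) abort("`vectors` is empty.")
  ns <- vapply(vectors, vector_n, numeric(1))
  if (length(unique(ns)) != 1L) abort("all vectors must share one dimension.")
  if (op %in% c("sum_mu", "mean_beta")) {
    ok <- vapply(vectors, inherits, logical(1), what = "mu_vector")
    if (!all(ok)) abort(sprintf("`%s` requires mu vectors.", op))
    if (op == "sum_mu") {
      mu_vector(Reduce(`+`, lapply(vectors, `[[`, "m")),
                Reduce(`+`, lapply(vectors, `[[`, "u")))
    } else {
      bmat <- vapply(vectors, beta_values, numeric(ns[1]))
      out <- rowMeans(matrix(bmat, nrow = ns[1]), na.rm = TRUE)
      out[is.nan(out)] <- NA_real_
      out
    }
  } else {
    ok <- vapply(vectors, inherits, logical(1), what = "cpg_set")
    if (!all(ok)) abort(sprintf("`%s` requires cpg sets.", op))
    f <- if (op == "union") `|` else `&`
    new_cpg_set(Reduce(f, lapply(vectors, `[[`, "bits")))
  }
}

#' Binarize an MU vector into methylated and covered sets
#'
#' The standard preparation of a sparse methylome for enrichment testing:
#' `covered` holds the sites with coverage at least `cov_min`, and
#' `methylated` the covered sites whose beta value reaches `beta_min`.
#' The defaults (`beta_min = 0.3`, `cov_min = 1`) binarize low-pass data where
#' single reads are informative. `methylated` is always a subset of `covered`,
#' and the pair forms a ready-made query/universe for [test_enrichment()].
#'
#' @param mu A [mu_vector()].
#' @param beta_min Minimum beta value to call a site methylated.
#' @param cov_min Minimum coverage for a site to enter the universe.
#' @return A list with `methylated` and `covered` [cpg_set()]s.
#' @export
binarize <- function(mu, beta_min = 0.3, cov_min = 1) {
  stopifnot(inherits(mu, "mu_vector"))
  if (beta_min < 0 || beta_min > 1) abort("`beta_min` must lie in [0, 1].")
  if (cov_min < 1) abort("`cov_min` must be >= 1.")
  cov <- mu$m + mu$u
  covered <- cov >= cov_min
  # beta >= beta_min via cross-multiplication on counts (no float division)
  methylated <- covered & (mu$m >= beta_min * cov)
  list(methylated = new_cpg_set(methylated), covered = new_cpg_set(covered))
}
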