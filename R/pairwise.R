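#' Differential methylation calling between two sparse methylomes
#'
#' Compares two MU profiles site by site. The comparison universe is the set
#' of CpGs covered at `cov_min` or more reads in both profiles (optionally
#' further restricted by `mask`); within it, `hyper` holds the sites where
#' `beta_a - beta_b >= delta_min` and `hypo` those where
#' `beta_b - beta_a >= delta_min`. Beta differences are evaluated by
#' cross-multiplication on the raw counts, so threshold comparisons do not
#' depend on floating-point division. For binary single-cell profiles,
#' `delta_min = 1` selects exactly the sites with methylation differences of
#' +1 or -1.
#'
#' @param a,b [mu_vector()]s over one index.
#' @param delta_min Minimum beta difference in `(0, 1]`.
#' @param cov_min Minimum per-profile coverage (default 1).
#' @param mask Optional [cpg_set()] of comparable sites (e.g. excluding
#'   technically masked CpGs); the universe is intersected with it.
#' @return A `dmc_result` with fields `hyper`, `hypo` (both [cpg_set()]s),
#'   `universe` (a `universe`), `delta_min`, `cov_min`. [tidy()] yields one
#'   row per called site; [glance()] a one-row summary.
#' @export
call_dmc <- function(a, b, delta_min, cov_min = 1, mask = NULL) {
  stopifnot(inherits(a, "mu_vector"), inherits(b, "mu_vector"))
  check_same_dim(a, b)
  if (!is.numeric(delta_min) || delta_min <= 0 || delta_min > 1) {
    abort("`delta_min` must lie in (0, 1].")
  }
  if (cov_min < 1) abort("`cov_min` must be >= 1.")
  cov_a <- a$m + a$u
  cov_b <- b$m + b$u
  ubits <- cov_a >= cov_min & cov_b >= cov_min
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "cpg_set"))
    check_same_dim(mask, a)
    ubits <- ubits & mask$bits
  }
  if (!any(ubits)) abort("the joint-coverage universe is empty.")
  # beta_a - beta_b >= delta  <=>  m_a*cov_b - m_b*cov_a >= delta*cov_a*cov_b,
  # with delta written as an integer fraction p/10^6 so the whole comparison
  # is integer arithmetic (exact, and symmetric under swapping a and b)
  p_num <- round(delta_min * 1e6)
  diff_num <- a$m * cov_b - b$m * cov_a
  thr <- p_num * cov_a * cov_b
  hyper <- ubits & (diff_num * 1e6 >= thr)
  hypo <- ubits & (-diff_num * 1e6 >= thr)
  structure(
    list(hyper = new_cpg_set(hyper), hypo = new_cpg_set(hypo),
         universe = structure(list(members = new_cpg_set(ubits),
                                   description = "jointly covered"),
                              class = "universe"),
         delta_min = delta_min, cov_min = cov_min),
    class = "dmc_result"
  )
}

#' @export
print.dmc_result <- function(x, ...) {
  cat(sprintf("<dmc_result> universe %d CpGs: %d hyper, %d hypo (delta >= %g, cov >= %g)\n",
              set_size(x$universe$members), set_size(x$hyper), set_size(x$hypo),
              x$delta_min, x$cov_min))
  invisible(x)
}

#' @export
tidy.dmc_result <- function(x, ...) {
  bind_rows(
    tibble(ordinal = set_members(x$hyper), direction = "hyper"),
    tibble(ordinal = set_members(x$hypo), direction = "hypo")
  )
}

#' @export
glance.dmc_result <- function(x, ...) {
  tibble(
    n_universe = set_size(x$universe$members),
    n_hyper = set_size(x$hyper),
    n_hypo = set_size(x$hypo),
    delta_min = x$delta_min,
    cov_min = x$cov_min
  )
}

#' Aggregate methylation over knowledgebases
#'
#' Summarises one methylome over each knowledgebase: M and U counts are summed
#' over member sites with coverage, `n_covered` counts the covered member
#' sites, and `mean_beta` is either the pooled count-weighted beta
#' `sum_m / (sum_m + sum_u)` (default; robust under the single-read coverage
#' of single cells) or the unweighted mean of per-site betas
#' (`weighting = "site"`).
#'
#' @param sample A [mu_vector()].
#' @param kbs A list of [knowledgebase()]s.
#' @param weighting `"count"` (pooled) or `"site"` (mean of per-site betas).
#' @return A tibble with one row per knowledgebase: `kb`, `domain`,
#'   `n_covered`, `sum_m`, `sum_u`, `mean_beta` (`NA` when no member site is
#'   covered).
#' @export
aggregate_kb <- function(sample, kbs, weighting = c("count", "site")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(sample, "mu_vector"))
  if (inherits(kbs, "knowledgebase")) kbs <- list(kbs)
  cov <- sample$m + sample$u
  betas <- ifelse(cov > 0, sample$m / cov, NA_real_)
  rows <- map(kbs, function(kb) {
    check_same_dim(kb$members, sample)
    sel <- kb$members$bits & cov > 0
    sm <- sum(sample$m[sel]); su <- sum(sample$u[sel])
    nc <- sum(sel)
    mb <- if (nc == 0) NA_real_
          else if (weighting == "count") sm / (sm + su)
          else mean(betas[sel])
    kb_name <- kb$name
    kb_domain <- kb$domain
    tibble(kb = kb_name, domain = kb_domain, n_covered = nc,
           sum_m = sm, sum_u = su, mean_beta = mb)
  })
  list_rbind(rows)
}

#' Sample-by-knowledgebase feature matrix
#'
#' Aggregates every sample over every knowledgebase, producing the mean-beta
#' matrix used for dimensionality reduction and feature aggregation of sparse
#' single-cell methylomes.
#'
#' @param samples A named list of [mu_vector()]s.
#' @param kbs A list of [knowledgebase()]s.
#' @inheritParams aggregate_kb
#' @return A numeric matrix, samples in rows and knowledgebases in columns;
#'   `NA` where a sample covers no member site of a knowledgebase.
#' @export
feature_matrix <- function(samples, kbs, weighting = c("count", "site")) {
  weighting <- match.arg(weighting)
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  rows <- lapply(samples, function(s) aggregate_kb(s, kbs, weighting)$mean_beta)
  mat <- do.call(rbind, rows)
  colnames(mat) <- vapply(kbs, `[[`, "", "name")
  rownames(mat) <- names(samples)
  mat
}
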