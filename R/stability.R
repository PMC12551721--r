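#' Uniformly downsample a testing universe
#'
#' Draws `floor(|U| / 2^k)` universe sites uniformly without replacement,
#' producing the sparser universe used by the stability harness.
#'
#' @param universe A `universe` or [cpg_set()].
#' @param factor_exponent k, halving exponent (`2^k <= |U|`).
#' @param seed Integer seed (required).
#' @return A `universe` over the same index space.
#' @export
downsample_universe <- function(universe, factor_exponent, seed) {
  u <- if (inherits(universe, "universe")) universe$members else universe
  stopifnot(inherits(u, "cpg_set"))
  members <- set_members(u)
  target <- floor(length(members) / 2^factor_exponent)
  if (target < 1) abort("downsampled universe would be empty.")
  kept <- with_seed(seed, sort(sample(members, target)))
  structure(
    list(members = cpg_set(u$n_bits, kept),
         description = sprintf("downsampled 1/2^%g", factor_exponent)),
    class = "universe"
  )
}

iter_seed <- function(master, k, iteration) {
  # deterministic per (master seed, exponent, iteration), < 2^31
  (as.numeric(master) * 7919 + k * 104729 + iteration * 1299709) %% 2147483647
}

#' Enrichment-ranking stability under universe sparsity
#'
#' Quantifies how enrichment rankings degrade as the testing universe is
#' uniformly thinned. The reference ranking is [test_enrichment()] on the
#' full universe, ordered by p-value with the documented tie-break. For every
#' downsampling exponent k and iteration, the universe is re-drawn at size
#' `|U| / 2^k`, the query and knowledgebases are re-intersected into it, the
#' test is repeated in the sub-space, and two quantities are recorded: the
#' Spearman correlation of the `-log10 p` ranking against the reference, and
#' whether the top-ranked knowledgebase changed. Iterations in which the
#' query has no members in the thinned universe are recorded as failed and
#' excluded from the correlation (at extreme sparsity this is itself
#' informative). Per-iteration seeds derive deterministically from
#' `(seed, k, iteration)`, so reports are reproducible bit for bit.
#'
#' @param query A [cpg_set()].
#' @param kbs A list of [knowledgebase()]s.
#' @param universe A `universe` or [cpg_set()]; `NULL` for the full space.
#' @param exponents Downsampling exponents k (universe size `|U| / 2^k`).
#' @param n_iter Iterations per exponent (default 50).
#' @param seed Master seed.
#' @param side Test side, as in [test_enrichment()].
#' @return A `stability_report`: list with `reference` (the ranked full
#'   -universe table) and `results` (tibble: `k`, `iteration`, `rho`,
#'   `top_changed`, `failed`). [tidy()] returns `results`; [summary()] the
#'   per-exponent medians, change rates and failure counts.
#' @export
run_stability <- function(query, kbs, universe = NULL,
                          exponents = c(0, 1, 2, 4, 6, 8, 10, 12, 14),
                          n_iter = 50, seed = 1, side = "enrich") {
  stopifnot(inherits(query, "cpg_set"))
  ubits <- as_universe_bits(universe, query$n_bits)
  full_u <- new_cpg_set(ubits)
  reference <- rank_enrichment(test_enrichment(query, kbs, full_u, side = side))
  ref_logp <- -log10(reference$p_value[match(vapply(kbs, `[[`, "", "name"),
                                             reference$kb)])
  ref_top <- reference$kb[1]
  rows <- list()
  for (k in exponents) {
    for (it in seq_len(n_iter)) {
      sub_u <- downsample_universe(full_u, k, seed = iter_seed(seed, k, it))
      keep <- sub_u$members
      q_sub <- subset_vector(query, keep)
      failed <- set_size(q_sub) == 0
      rho <- NA_real_
      top_changed <- NA
      if (!failed) {
        kbs_sub <- lapply(kbs, function(kb) {
          knowledgebase(kb$name, subset_vector(kb$members, keep), kb$domain)
        })
        res <- test_enrichment(q_sub, kbs_sub, universe = NULL, side = side)
        logp <- -log10(res$p_value[match(vapply(kbs, `[[`, "", "name"), res$kb)])
        rho <- suppressWarnings(cor(logp, ref_logp, method = "spearman"))
        top_changed <- rank_enrichment(res)$kb[1] != ref_top
      }
      rows[[length(rows) + 1L]] <- tibble(
        k = k, iteration = it, rho = rho, top_changed = top_changed,
        failed = failed)
    }
  }
  structure(list(reference = reference, results = list_rbind(rows),
                 n_iter = n_iter, seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d exponent(s) x %d iteration(s); reference top term: %s\n",
              length(unique(x$results$k)), x$n_iter, x$reference$kb[1]))
  print(summary(x))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) x$results

#' @export
summary.stability_report <- function(object, ...) {
  object$results |>
    group_by(.data$k) |>
    summarise(
      n_iterations = n(),
      n_failed = sum(.data$failed),
      median_rho = median(.data$rho, na.rm = TRUE),
      top_term_change_rate = mean(.data$top_changed[!.data$failed]),
      .groups = "drop"
    )
}

#' @export
glance.stability_report <- function(x, ...) {
  s <- summary(x)
  tibble(
    n_exponents = nrow(s),
    n_iter = x$n_iter,
    max_stable_k = suppressWarnings(
      max(s$k[!is.na(s$top_term_change_rate) & s$top_term_change_rate == 0])),
    reference_top = x$reference$kb[1]
  )
}
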