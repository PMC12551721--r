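#' @export
tidy.cgkit_enrichment <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.cgkit_enrichment <- function(x, ...) {
  ranked <- rank_enrichment(x)
  tibble(
    n_tests = nrow(x),
    n_universe = x$n_universe[1],
    n_query = x$n_query[1],
    top_kb = ranked$kb[1],
    min_p = min(x$p_value),
    n_significant = sum(x$fdr < 0.05)
  )
}

#' Dot plot of enrichment results
#'
#' Knowledgebases are placed by log2 odds ratio (continuity-corrected) and
#' -log10 FDR, sized by overlap, the standard at-a-glance view of an
#' enrichment screen.
#'
#' @param object A [test_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgkit_enrichment <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot(df, aes(x = .data$log2_or_corrected,
                 y = -log10(pmax(.data$fdr, 1e-300)),
                 size = .data$overlap, colour = .data$domain)) +
    geom_point(alpha = 0.8) +
    labs(x = "log2 odds ratio (corrected)", y = "-log10 FDR",
         size = "overlap", colour = "domain") +
    theme_minimal()
}

#' Stability-report plot
#'
#' Spearman correlation of the sparse-universe enrichment ranking against the
#' full-universe reference, one box per downsampling exponent.
#'
#' @param object A [run_stability()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- object$results[!object$results$failed & !is.na(object$results$rho), ]
  ggplot(df, aes(x = factor(.data$k), y = .data$rho)) +
    geom_boxplot() +
    labs(x = "downsampling exponent k (universe size |U| / 2^k)",
         y = "Spearman rho vs full-universe ranking") +
    theme_minimal()
}
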