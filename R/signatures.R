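#' Wilcoxon rank-sum AUC between two groups of beta values
#'
#' Computes the Mann-Whitney U statistic with mid-ranks for ties and the
#' derived AUC `U / (n_t * n_b)`, oriented so that AUC above 0.5 means the
#' target values are larger. The AUC equals the fraction of (target,
#' background) pairs in which the target value is larger, counting ties as
#' half. A normal-approximation p-value with tie correction is reported for
#' transparency; marker selection filters on the AUC itself.
#'
#' @param target_values,background_values Non-empty numeric vectors (NAs are
#'   dropped).
#' @return A list with `auc`, `u_statistic`, `p_value`, `n_target`,
#'   `n_background`.
#' @export
wilcoxon_auc <- function(target_values, background_values) {
  t_v <- target_values[!is.na(target_values)]
  b_v <- background_values[!is.na(background_values)]
  if (length(t_v) == 0 || length(b_v) == 0) {
    abort("both groups must contain at least one non-missing value.")
  }
  nt <- length(t_v); nb <- length(b_v)
  r <- rank(c(t_v, b_v))  # mid-ranks for ties
  u <- sum(r[seq_len(nt)]) - nt * (nt + 1) / 2
  auc <- u / (nt * nb)
  # normal approximation with tie correction
  n <- nt + nb
  ties <- table(c(t_v, b_v))
  sigma2 <- nt * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (sigma2 <= 0) 1 else 2 * pnorm(abs(u - nt * nb / 2) / sqrt(sigma2),
                                         lower.tail = FALSE)
  list(auc = auc, u_statistic = u, p_value = min(p, 1),
       n_target = nt, n_background = nb)
}

#' Contrast specifications
#'
#' A contrast names the target and background sample groups of one cell-type
#' (or condition) comparison.
#'
#' @param name Contrast name.
#' @param target_samples,background_samples Disjoint, non-empty character
#'   vectors of sample names.
#' @export
contrast_spec <- function(name, target_samples, background_samples) {
  if (length(target_samples) == 0 || length(background_samples) == 0) {
    abort("target and background must each be nonempty.")
  }
  if (length(intersect(target_samples, background_samples)) > 0) {
    abort("target and background samples must be disjoint.")
  }
  structure(list(name = name, target_samples = target_samples,
                 background_samples = background_samples),
            class = "contrast_spec")
}

#' One-versus-rest contrasts from group labels
#'
#' @param group_labels A named character vector: sample name -> group.
#' @return A list of [contrast_spec()]s, one per group (that group versus all
#'   other samples).
#' @export
one_vs_rest_contrasts <- function(group_labels) {
  if (is.null(names(group_labels))) abort("`group_labels` must be named by sample.")
  groups <- unique(group_labels)
  if (length(groups) < 2) abort("at least 2 groups are required.")
  lapply(groups, function(g) {
    tgt <- names(group_labels)[group_labels == g]
    bkg <- names(group_labels)[group_labels != g]
    if (length(tgt) == 0) abort(sprintf("group '%s' has no samples.", g))
    contrast_spec(g, tgt, bkg)
  })
}

#' Cell-type methylation signature discovery
#'
#' Nonparametric discriminant analysis over a samples-by-CpG beta matrix: at
#' every CpG the target and background groups are compared with the Wilcoxon
#' rank-sum AUC, and the beta difference `delta = mean(target) -
#' mean(background)` is computed over non-missing values. Hypermethylation
#' markers satisfy `auc > auc_min` and `delta > delta_min`; hypomethylation
#' markers satisfy `(1 - auc) > auc_min` and `-delta > delta_min`
#' (inequalities are strict). Sites with fewer than `min_n` non-missing
#' values in either group are skipped and recorded.
#'
#' @param betas Numeric matrix, samples in rows (named), CpGs in columns;
#'   `NA` marks missing values.
#' @param contrast A [contrast_spec()].
#' @param auc_min AUC threshold (default 0.95).
#' @param delta_min Beta-difference threshold (default 0.5).
#' @param min_n Minimum non-missing values per group per site (default 2).
#' @return A `signature_result` with per-CpG `auc` and `delta_beta` vectors,
#'   `hyper_markers` / `hypo_markers` [cpg_set()]s, the `skipped` site set,
#'   and the thresholds. [tidy()] gives the per-CpG table; [glance()] a
#'   one-row summary.
#' @export
discover_signatures <- function(betas, contrast, auc_min = 0.95,
                                delta_min = 0.5, min_n = 2) {
  stopifnot(inherits(contrast, "contrast_spec"))
  betas <- as.matrix(betas)
  missing_samples <- setdiff(c(contrast$target_samples,
                               contrast$background_samples), rownames(betas))
  if (length(missing_samples) > 0) {
    abort(sprintf("samples absent from `betas`: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  tmat <- betas[contrast$target_samples, , drop = FALSE]
  bmat <- betas[contrast$background_samples, , drop = FALSE]
  n_sites <- ncol(betas)
  auc <- rep(NA_real_, n_sites)
  delta <- rep(NA_real_, n_sites)
  for (j in seq_len(n_sites)) {
    tv <- tmat[, j]; tv <- tv[!is.na(tv)]
    bv <- bmat[, j]; bv <- bv[!is.na(bv)]
    if (length(tv) < min_n || length(bv) < min_n) next
    auc[j] <- wilcoxon_auc(tv, bv)$auc
    delta[j] <- mean(tv) - mean(bv)
  }
  evaluated <- !is.na(auc)
  hyper <- evaluated & auc > auc_min & delta > delta_min
  hypo <- evaluated & (1 - auc) > auc_min & -delta > delta_min
  structure(
    list(contrast = contrast$name, auc = auc, delta_beta = delta,
         hyper_markers = new_cpg_set(hyper), hypo_markers = new_cpg_set(hypo),
         skipped = new_cpg_set(!evaluated),
         thresholds = c(auc_min = auc_min, delta_min = delta_min)),
    class = "signature_result"
  )
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %s: %d hyper, %d hypo markers (AUC > %g, |delta| > %g; %d sites skipped)\n",
              x$contrast, set_size(x$hyper_markers), set_size(x$hypo_markers),
              x$thresholds["auc_min"], x$thresholds["delta_min"],
              set_size(x$skipped)))
  invisible(x)
}

#' @export
tidy.signature_result <- function(x, ...) {
  tibble(
    ordinal = seq_along(x$auc),
    auc = x$auc,
    delta_beta = x$delta_beta,
    hyper_marker = x$hyper_markers$bits,
    hypo_marker = x$hypo_markers$bits,
    skipped = x$skipped$bits
  )
}

#' @export
glance.signature_result <- function(x, ...) {
  tibble(
    contrast = x$contrast,
    n_sites = length(x$auc),
    n_hyper = set_size(x$hyper_markers),
    n_hypo = set_size(x$hypo_markers),
    n_skipped = set_size(x$skipped),
    auc_min = unname(x$thresholds["auc_min"]),
    delta_min = unname(x$thresholds["delta_min"])
  )
}

#' Turn signature markers into knowledgebases
#'
#' @param sig A [discover_signatures()] result.
#' @return A list of two [knowledgebase()]s (hyper and hypo markers) in
#'   domain `"cell_signature"`.
#' @export
signature_kbs <- function(sig) {
  stopifnot(inherits(sig, "signature_result"))
  list(
    knowledgebase(paste0(sig$contrast, "_hyper"), sig$hyper_markers,
                  "cell_signature"),
    knowledgebase(paste0(sig$contrast, "_hypo"), sig$hypo_markers,
                  "cell_signature")
  )
}
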