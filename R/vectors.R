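#' CpG bit sets
#'
#' A `cpg_set` is a membership vector over a CpG index (or any declared
#' subspace): one bit per ordinal. It is the common currency of queries,
#' knowledgebases and universes.
#'
#' @param n_bits Size of the space the set lives in.
#' @param members Integer ordinals (1-based) of member CpGs.
#' @return A `cpg_set` object.
#' @examples
#' s <- cpg_set(10, c(2, 5, 7))
#' set_size(s)
#' @export
cpg_set <- function(n_bits, members = integer()) {
  n_bits <- as.integer(n_bits)
  stopifnot(n_bits >= 0L)
  members <- as.integer(members)
  if (length(members) && (min(members) < 1L || max(members) > n_bits)) {
    abort("`members` out of range for `n_bits`.")
  }
  bits <- logical(n_bits)
  bits[members] <- TRUE
  new_cpg_set(bits)
}

new_cpg_set <- function(bits) {
  structure(list(n_bits = length(bits), bits = bits), class = "cpg_set")
}

#' @rdname cpg_set
#' @param bits A logical vector of memberships.
#' @export
as_cpg_set <- function(bits) {
  if (inherits(bits, "cpg_set")) return(bits)
  new_cpg_set(as.logical(bits))
}

#' @rdname cpg_set
#' @param x A `cpg_set`.
#' @return [set_size()]: the cardinality (popcount); [set_members()]: the
#'   sorted member ordinals.
#' @export
set_size <- function(x) {
  stopifnot(inherits(x, "cpg_set"))
  sum(x$bits)
}

#' @rdname cpg_set
#' @export
set_members <- function(x) {
  stopifnot(inherits(x, "cpg_set"))
  which(x$bits)
}

#' @export
print.cpg_set <- function(x, ...) {
  cat(sprintf("<cpg_set> %d / %d CpGs\n", set_size(x), x$n_bits))
  invisible(x)
}

check_same_dim <- function(a, b) {
  na <- if (inherits(a, "cpg_set")) a$n_bits else a$n_sites
  nb <- if (inherits(b, "cpg_set")) b$n_bits else b$n_sites
  if (na != nb) abort(sprintf("dimension mismatch: %d vs %d sites.", na, nb))
  invisible(na)
}

#' M/U read-count vectors
#'
#' Per-CpG methylated (M) and unmethylated (U) read counts keyed to a CpG
#' index. Coverage is `M + U`; the beta value `M / (M + U)` is defined only on
#' covered sites, and coverage 0 is the missing state.
#'
#' @param m,u Non-negative integer counts (each at most `2^32 - 1`), recycled
#'   to a common length.
#' @return A `mu_vector` object.
#' @export
mu_vector <- function(m, u) {
  n <- max(length(m), length(u))
  m <- rep_len(as.numeric(m), n)
  u <- rep_len(as.numeric(u), n)
  check_counts32(m, "m")
  check_counts32(u, "u")
  structure(list(n_sites = n, m = m, u = u), class = "mu_vector")
}

check_counts32 <- function(x, what) {
  if (anyNA(x)) abort(sprintf("`%s` contains missing counts.", what))
  if (any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must hold non-negative integer counts.", what))
  }
  if (any(x > 4294967295)) {
    abort(sprintf("`%s` overflows the 32-bit count range (max 4294967295).", what))
  }
  invisible(x)
}

#' @rdname mu_vector
#' @param x A `mu_vector`.
#' @return [coverage()]: numeric vector `M + U`; [beta_values()]: numeric
#'   vector of `M / (M + U)` with `NA` at uncovered sites.
#' @export
coverage <- function(x) {
  stopifnot(inherits(x, "mu_vector"))
  x$m + x$u
}

#' @rdname mu_vector
#' @export
beta_values <- function(x) {
  stopifnot(inherits(x, "mu_vector"))
  cov <- x$m + x$u
  ifelse(cov > 0, x$m / cov, NA_real_)
}

#' @export
print.mu_vector <- function(x, ...) {
  cov <- sum(x$m + x$u > 0)
  cat(sprintf("<mu_vector> %d sites, %d covered\n", x$n_sites, cov))
  invisible(x)
}

#' Categorical state vectors
#'
#' Encodes one categorical label per CpG with the textual state definitions
#' held apart from the per-site integer codes, so repetitive annotations (for
#' example chromatin-state calls) compress well.
#'
#' @param states A character or factor vector, one label per site.
#' @param labels Optional explicit label dictionary (order defines the codes).
#' @return A `state_vector` with fields `n_sites`, `labels`, `codes`.
#' @export
state_vector <- function(states, labels = NULL) {
  states <- as.character(states)
  if (is.null(labels)) labels <- unique(states)
  codes <- match(states, labels)
  if (anyNA(codes)) abort("`states` contains values absent from `labels`.")
  structure(list(n_sites = length(states), labels = labels, codes = codes),
            class = "state_vector")
}

#' @rdname state_vector
#' @param x A `state_vector`.
#' @export
state_labels <- function(x) {
  stopifnot(inherits(x, "state_vector"))
  x$labels[x$codes]
}

#' @export
print.state_vector <- function(x, ...) {
  cat(sprintf("<state_vector> %d sites, %d state(s)\n",
              x$n_sites, length(x$labels)))
  invisible(x)
}
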