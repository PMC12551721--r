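# Shared in-code fixtures for the test suite.

toy_index <- function() {
  build_index(
    data.frame(chrom = c("chr1", "chr1", "chr2"), start = c(10, 50, 7)),
    reference_name = "toy"
  )
}

# A small random index built directly (independent of gen_index) for
# property-style tests.
random_index <- function(seed, n_chrom = 3, n_per_chrom = 500, mean_gap = 40) {
  set.seed(seed)
  tbl <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    data.frame(chrom = sprintf("chr%d", ci),
               start = cumsum(2 + rgeom(n_per_chrom, 1 / (mean_gap - 1))))
  }))
  build_index(tbl, reference_name = sprintf("rand%d", seed))
}

random_intervals <- function(seed, index, n = 200, max_len = 300) {
  set.seed(seed)
  chrom <- sample(index$chroms$name, n, replace = TRUE)
  maxpos <- index$chroms$length[match(chrom, index$chroms$name)]
  start <- floor(runif(n, 0, maxpos))
  data.frame(chrom = chrom, start = start,
             end = start + 1 + floor(runif(n, 0, max_len)))
}

# Brute-force membership oracle: all-pairs containment scan.
brute_force_members <- function(intervals, index, extend_bp = 0) {
  bed <- index_to_bed(index)
  hit <- logical(nrow(bed))
  for (i in seq_len(nrow(intervals))) {
    lo <- max(0, intervals$start[i] - extend_bp)
    hi <- intervals$end[i] + extend_bp
    hit <- hit | (bed$chrom == intervals$chrom[i] & bed$start >= lo &
                    bed$start < hi)
  }
  which(hit)
}

random_mu <- function(seed, n, coverage = 0.3, max_depth = 4) {
  set.seed(seed)
  depth <- ifelse(runif(n) < coverage, 1 + rpois(n, max_depth - 1), 0)
  m <- rbinom(n, depth, runif(n))
  mu_vector(m, depth - m)
}

# Exact hypergeometric tail-sum oracle built on choose(), independent of
# phyper/dhyper.
choose_pmf <- function(j, K, N, n) choose(K, j) * choose(N - K, n - j) / choose(N, n)

oracle_hyper_p <- function(x, K, n, N, side) {
  support <- max(0, n + K - N):min(n, K)
  pmf <- choose_pmf(support, K, N, n)
  if (side == "enrich") sum(pmf[support >= x])
  else if (side == "deplete") sum(pmf[support <= x])
  else sum(pmf[pmf <= pmf[match(x, support)] * (1 + 1e-7)])
}

# Reference BH step-up: q_i = min_{j >= i} p_(j) * m / j, applied to one group.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(1, p[o][i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
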