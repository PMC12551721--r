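#' Knowledgebase CpG sets
#'
#' A knowledgebase is a named CpG set linked to a biological or technical
#' feature (a transcription-factor binding profile, a chromatin state, a trait
#' association, an array artifact, ...). Every knowledgebase carries a
#' `domain` label: knowledgebases in one domain form one hypothesis space, and
#' multiple-testing correction in [test_enrichment()] is applied within the
#' domain.
#'
#' @param name Knowledgebase name.
#' @param members A [cpg_set()] of member CpGs.
#' @param domain Non-empty testing-domain label (e.g. `"chromhmm"`, `"tfbs"`,
#'   `"motif"`, `"trait"`, `"technical"`).
#' @param provenance Optional free-text construction record.
#' @return A `knowledgebase` object.
#' @export
knowledgebase <- function(name, members, domain, provenance = NULL) {
  stopifnot(inherits(members, "cpg_set"))
  if (!is.character(domain) || !nzchar(domain)) {
    abort("`domain` must be a non-empty label (it drives FDR grouping).")
  }
  structure(list(name = name, domain = domain, members = members,
                 provenance = provenance),
            class = "knowledgebase")
}

#' @export
print.knowledgebase <- function(x, ...) {
  cat(sprintf("<knowledgebase> %s [%s]: %d CpGs / %d\n",
              x$name, x$domain, set_size(x$members), x$members$n_bits))
  invisible(x)
}

#' Consensus top-k CpG selection with tie inclusion
#'
#' Builds a consensus set from per-CpG overlap frequencies (how many samples'
#' peaks cover each CpG): all CpGs with frequency at least `t` are returned,
#' where `t` is the largest threshold whose result size reaches `k_target`.
#' Because every CpG tied at `t` is included, the result may exceed
#' `k_target`; this is how fixed-size consensus sets (typically 50,000 to
#' 100,000 CpGs) absorb frequency ties.
#'
#' @param overlap_freq Per-CpG non-negative integer frequency vector.
#' @param k_target Minimum size of the returned set.
#' @param name,domain Passed to [knowledgebase()]; the chosen threshold is
#'   recorded in the provenance.
#' @return A `knowledgebase` whose members are the selected CpGs.
#' @export
consensus_topk <- function(overlap_freq, k_target, name = "consensus",
                           domain = "consensus") {
  if (k_target < 1) abort("`k_target` must be >= 1.")
  freq <- as.numeric(overlap_freq)
  nz <- sum(freq > 0)
  if (k_target > nz) {
    warn(sprintf(
      "k_target (%d) exceeds the %d CpGs with nonzero frequency; returning all of them.",
      k_target, nz))
    t <- if (nz > 0) min(freq[freq > 0]) else Inf
  } else {
    cnt <- rev(cumsum(rev(tabulate(freq, nbins = max(freq)))))
    # cnt[f] = number of CpGs with frequency >= f
    t <- max(which(cnt >= k_target))
  }
  members <- which(freq >= t)
  knowledgebase(name, cpg_set(length(freq), members), domain,
                provenance = sprintf("consensus_topk: k_target=%d threshold=%g size=%d",
                                     as.integer(k_target), t, length(members)))
}

#' Gene-linked knowledgebases
#'
#' Links CpGs to genes over the window from 10 kb upstream of the
#' transcription start site to the transcription termination site
#' (strand-aware: for a minus-strand gene the window extends 10 kb beyond the
#' right edge). Each gene becomes one knowledgebase in domain `"gene"`.
#' Windows are truncated at chromosome bounds; no clipping against
#' neighbouring genes is applied.
#'
#' @param genes A data frame of gene models with columns `chrom`, `start`,
#'   `end` (0-based half-open gene span), `strand` (`"+"`/`"-"`) and `name`.
#' @param index A [build_index()] object.
#' @param upstream_bp Upstream extension from the TSS in bp (default 10000).
#' @return A list of `knowledgebase` objects, one per gene.
#' @export
gene_link_kb <- function(genes, index, upstream_bp = 10000) {
  genes <- as.data.frame(genes)
  need <- c("chrom", "start", "end", "strand", "name")
  if (!all(need %in% names(genes))) {
    abort("`genes` must have columns chrom, start, end, strand, name.")
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("`strand` must be '+' or '-'.")
  lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    win <- if (g$strand == "+") {
      c(max(0, g$start - upstream_bp), g$end)
    } else {
      c(g$start, g$end + upstream_bp)
    }
    chrom_len <- index$chroms$length[match(g$chrom, index$chroms$name)]
    if (!is.na(chrom_len)) win[2] <- min(win[2], chrom_len)
    members <- intersect_to_set(
      data.frame(chrom = g$chrom, start = win[1], end = win[2]), index)
    knowledgebase(g$name, members, "gene",
                  provenance = sprintf("gene window %s:%g-%g (%s)",
                                       g$chrom, win[1], win[2], g$strand))
  })
}

#' Sequence-motif knowledgebase
#'
#' Converts motif hit locations into a CpG set, extending every hit by
#' plus/minus 10 bp before intersection so CpGs at the motif edge are
#' captured.
#'
#' @param motif_hits A data frame of motif locations (`chrom`, `start`,
#'   `end`).
#' @param index A [build_index()] object.
#' @param name Motif name.
#' @param extend_bp Symmetric extension in bp (default 10).
#' @return A `knowledgebase` in domain `"motif"`.
#' @export
motif_kb <- function(motif_hits, index, name = "motif", extend_bp = 10) {
  knowledgebase(name, intersect_to_set(motif_hits, index, extend_bp = extend_bp),
                "motif",
                provenance = sprintf("motif hits extended by +/-%d bp", extend_bp))
}

#' Testing universes
#'
#' Enrichment testing is always carried out inside a universe: the background
#' CpG set actually interrogated by the experiment. [build_universe()] forms
#' the joint-coverage universe of a set of methylomes (sites covered at
#' `cov_min` or more reads in every sample); [platform_universe()] wraps a
#' fixed probe subspace (e.g. an array manifest).
#'
#' @param samples A list of [mu_vector()]s over one index.
#' @param cov_min Minimum per-sample coverage (default 1).
#' @param description Free-text label.
#' @return A `universe` object (a [cpg_set()] plus description).
#' @export
build_universe <- function(samples, cov_min = 1, description = "joint coverage") {
  if (length(samples) == 0L) abort("at least one sample is required.")
  ok <- vapply(samples, inherits, logical(1), what = "mu_vector")
  if (!all(ok)) abort("`samples` must be mu vectors.")
  covered <- lapply(samples, function(s) s$m + s$u >= cov_min)
  bits <- Reduce(`&`, covered)
  if (!any(bits)) abort("the joint-coverage universe is empty; no test is defined.")
  structure(list(members = new_cpg_set(bits), description = description),
            class = "universe")
}

#' @rdname build_universe
#' @param probe_set A [cpg_set()] marking the platform's probes.
#' @export
platform_universe <- function(probe_set, description = "platform subspace") {
  stopifnot(inherits(probe_set, "cpg_set"))
  if (set_size(probe_set) == 0) abort("the platform universe is empty.")
  structure(list(members = probe_set, description = description),
            class = "universe")
}

#' @export
print.universe <- function(x, ...) {
  cat(sprintf("<universe> %s: %d / %d CpGs\n", x$description,
              set_size(x$members), x$members$n_bits))
  invisible(x)
}

as_universe_bits <- function(universe, n_bits) {
  if (is.null(universe)) return(rep(TRUE, n_bits))
  u <- if (inherits(universe, "universe")) universe$members else universe
  stopifnot(inherits(u, "cpg_set"))
  if (u$n_bits != n_bits) abort("universe dimension mismatch.")
  u$bits
}

#' Write a knowledgebase bundle
#'
#' Stores a list of knowledgebases in a `.cgx` container next to a sidecar
#' manifest TSV (`name<TAB>domain<TAB>size<TAB>provenance`).
#'
#' @param kbs A list of `knowledgebase` objects.
#' @param path Container path; the manifest is written to
#'   `paste0(path, ".manifest.tsv")`.
#' @export
write_kb_bundle <- function(kbs, path) {
  entries <- setNames(lapply(kbs, `[[`, "members"),
                      vapply(kbs, `[[`, "", "name"))
  write_container(entries, path)
  manifest <- tibble(
    name = vapply(kbs, `[[`, "", "name"),
    domain = vapply(kbs, `[[`, "", "domain"),
    size = vapply(kbs, function(k) set_size(k$members), numeric(1)),
    provenance = vapply(kbs, function(k) k$provenance %||% "", character(1))
  )
  write.table(manifest, paste0(path, ".manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kb_bundle
#' @export
read_kb_bundle <- function(path) {
  manifest <- read.table(paste0(path, ".manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    knowledgebase(manifest$name[i], container_read(path, manifest$name[i]),
                  manifest$domain[i],
                  provenance = if (nzchar(manifest$provenance[i])) manifest$provenance[i])
  })
}
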