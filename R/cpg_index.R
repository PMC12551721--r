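#' Build a reference CpG index
#'
#' The CpG index is the fixed whole-genome ordering of CpG sites that makes
#' every other object in cgkit coordinate-free: bit sets, M/U count vectors and
#' state vectors are all keyed to the ordinal of a CpG in this index, so no
#' genomic coordinates need to be stored alongside the data itself.
#'
#' A CpG is identified by the 0-based position of its C on the forward strand,
#' with the palindromic G on the reverse strand merged into the same site.
#' Chromosomes keep their order of first appearance in `cpg_tbl`; positions are
#' sorted within each chromosome. Ordinals are 1-based (chromosome order, then
#' position).
#'
#' @param cpg_tbl A data frame with columns `chrom` and `start` (0-based C
#'   position). An optional `end` column is ignored (a CpG always spans 2 bp).
#'   Duplicated rows are collapsed; rows may arrive unsorted.
#' @param reference_name Label for the reference assembly the positions refer
#'   to (e.g. `"toy1"`, `"GRCh38"`).
#' @param chrom_sizes Optional named vector of chromosome lengths in bp. When
#'   absent, each length is taken as the last CpG position plus 2.
#'
#' @return A `cpg_index` object with fields `reference_name`, `chroms` (a
#'   tibble of `name`, `length`), `positions` (per-chromosome sorted numeric
#'   vectors), `offsets` (ordinal offset preceding each chromosome) and `n`
#'   (total CpG count).
#'
#' @examples
#' idx <- build_index(
#'   data.frame(chrom = c("chr1", "chr1", "chr2"), start = c(10, 50, 7)),
#'   reference_name = "toy"
#' )
#' idx$n
#' ordinal_of(idx, "chr2", 7)
#' @export
build_index <- function(cpg_tbl, reference_name = "unnamed", chrom_sizes = NULL) {
  cpg_tbl <- as.data.frame(cpg_tbl)
  if (!all(c("chrom", "start") %in% names(cpg_tbl))) {
    abort("`cpg_tbl` must have columns `chrom` and `start`.")
  }
  chrom <- as.character(cpg_tbl$chrom)
  start <- as.numeric(cpg_tbl$start)
  if (anyNA(chrom) || anyNA(start)) abort("`cpg_tbl` contains missing values.")
  if (any(start < 0)) {
    abort(sprintf("negative CpG coordinate: %s:%g",
                  chrom[which(start < 0)[1]], start[which(start < 0)[1]]))
  }
  chrom_order <- unique(chrom)
  positions <- lapply(chrom_order, function(cn) {
    p <- sort(unique(start[chrom == cn]))
    if (length(p) > 1L) {
      gap <- diff(p)
      if (any(gap < 2)) {
        i <- which(gap < 2)[1]
        abort(sprintf(
          "overlapping CpGs on %s: positions %g and %g are closer than 2 bp",
          cn, p[i], p[i + 1L]))
      }
    }
    p
  })
  names(positions) <- chrom_order
  lens <- vapply(chrom_order, function(cn) {
    if (!is.null(chrom_sizes) && cn %in% names(chrom_sizes)) {
      as.numeric(chrom_sizes[[cn]])
    } else {
      max(positions[[cn]]) + 2
    }
  }, numeric(1))
  counts <- lengths(positions)
  structure(
    list(
      reference_name = reference_name,
      chroms = tibble(name = chrom_order, length = unname(lens)),
      positions = positions,
      offsets = setNames(cumsum(c(0L, unname(counts)))[seq_along(chrom_order)],
                         chrom_order),
      n = sum(counts)
    ),
    class = "cpg_index"
  )
}

#' @export
print.cpg_index <- function(x, ...) {
  cat(sprintf("<cpg_index> %s: %d CpGs on %d chromosome(s)\n",
              x$reference_name, x$n, nrow(x$chroms)))
  invisible(x)
}

#' Ordinal of a genomic position in a CpG index
#'
#' Exact-match lookup of the 1-based global ordinal of a CpG. Vectorised over
#' `chrom`/`pos`.
#'
#' @param index A [build_index()] object.
#' @param chrom,pos Chromosome name(s) and 0-based C position(s).
#' @return Integer ordinal(s); `NA` where `(chrom, pos)` is not a CpG of the
#'   index.
#' @export
ordinal_of <- function(index, chrom, pos) {
  stopifnot(inherits(index, "cpg_index"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  out <- rep(NA_integer_, length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    p <- index$positions[[cn]]
    if (is.null(p)) next
    hit <- findInterval(pos[sel], p)
    ok <- hit >= 1L & p[pmax(hit, 1L)] == pos[sel]
    out[sel][ok] <- index$offsets[[cn]] + hit[ok]
  }
  out
}

#' Genomic coordinates of index ordinals
#'
#' Inverse of [ordinal_of()]: maps 1-based global ordinals back to
#' `(chrom, pos)` pairs.
#'
#' @param index A [build_index()] object.
#' @param ordinal Integer ordinal(s) in `1:index$n`.
#' @return A tibble with columns `ordinal`, `chrom`, `pos`.
#' @export
coords_of <- function(index, ordinal) {
  stopifnot(inherits(index, "cpg_index"))
  ordinal <- as.integer(ordinal)
  if (any(ordinal < 1L | ordinal > index$n, na.rm = TRUE)) {
    abort("`ordinal` out of range for this index.")
  }
  bounds <- c(unname(index$offsets), index$n)
  ci <- findInterval(ordinal - 1L, bounds[-length(bounds)], rightmost.closed = FALSE)
  within <- ordinal - unname(index$offsets)[ci]
  tibble(
    ordinal = ordinal,
    chrom = index$chroms$name[ci],
    pos = vapply(seq_along(ordinal),
                 function(i) index$positions[[ci[i]]][within[i]], numeric(1))
  )
}

#' Map genomic intervals onto a CpG index
#'
#' Returns the membership bit set of CpGs whose C position `p` satisfies
#' `start - extend_bp <= p < end + extend_bp` for at least one interval. Each
#' interval is resolved by binary search against the per-chromosome sorted
#' position arrays, so cost scales with the number of intervals, not the index
#' size. Intervals on chromosomes absent from the index are skipped (a message
#' reports how many).
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open; standard BED semantics).
#' @param index A [build_index()] object.
#' @param extend_bp Non-negative symmetric extension in bp applied to every
#'   interval before intersection (e.g. 10 for sequence-motif hits).
#' @return A [cpg_set()] over the index space.
#' @export
intersect_to_set <- function(intervals, index, extend_bp = 0) {
  stopifnot(inherits(index, "cpg_index"))
  intervals <- as.data.frame(intervals)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    abort("`intervals` must have columns `chrom`, `start`, `end`.")
  }
  if (extend_bp < 0) abort("`extend_bp` must be >= 0.")
  if (any(intervals$end <= intervals$start)) {
    abort("all intervals must satisfy start < end.")
  }
  bits <- logical(index$n)
  skipped <- 0L
  for (cn in unique(as.character(intervals$chrom))) {
    p <- index$positions[[cn]]
    sel <- intervals$chrom == cn
    if (is.null(p)) {
      skipped <- skipped + sum(sel)
      next
    }
    lo <- pmax(0, intervals$start[sel] - extend_bp)
    hi <- intervals$end[sel] + extend_bp   # half-open: positions < hi
    off <- index$offsets[[cn]]
    for (j in seq_along(lo)) {
      # first position >= lo[j], last position <= hi[j] - 1
      i1 <- findInterval(lo[j] - 0.5, p) + 1L
      i2 <- findInterval(hi[j] - 0.5, p)
      if (i2 >= i1) bits[(off + i1):(off + i2)] <- TRUE
    }
  }
  if (skipped > 0L) {
    inform(sprintf("intersect_to_set: skipped %d interval(s) on chromosomes absent from the index.",
                   skipped))
  }
  new_cpg_set(bits)
}

#' Export a CpG index as BED records
#'
#' @param index A [build_index()] object.
#' @return A tibble with `chrom`, `start`, `end` (= start + 2) for every CpG,
#'   in ordinal order.
#' @export
index_to_bed <- function(index) {
  stopifnot(inherits(index, "cpg_index"))
  chrom <- rep(index$chroms$name, lengths(index$positions))
  start <- unlist(index$positions, use.names = FALSE)
  tibble(chrom = chrom, start = start, end = start + 2)
}

#' Read / write BED interval files
#'
#' Minimal tab-separated BED (3+ columns, 0-based half-open). Lines starting
#' with `#`, `track` or `browser` are ignored on read.
#'
#' @param path File path.
#' @param x For [write_bed()], a data frame with at least `chrom`, `start`,
#'   `end`.
#' @return [read_bed()] returns a tibble with `chrom`, `start`, `end` and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  raw <- raw[!grepl("^(track|browser)", raw[[1]]), , drop = FALSE]
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw) <- cols[seq_len(min(ncol(raw), 6L))]
  as_tibble(raw[seq_len(min(ncol(raw), 6L))])
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  write.table(as.data.frame(x)[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Persist and reload a CpG index
#'
#' The on-disk form is a plain-text hybrid: `#`-prefixed header lines carrying
#' the reference name and the ordered chromosome table, followed by one
#' `chrom<TAB>pos` line per CpG in ordinal order. Rebuilding from this export
#' reproduces the index exactly.
#'
#' @param index A [build_index()] object.
#' @param path File path (conventionally `.cgi.tsv`).
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "cpg_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#reference\t%s", index$reference_name), con)
  writeLines(sprintf("#chrom\t%s\t%.15g", index$chroms$name, index$chroms$length), con)
  bed <- index_to_bed(index)
  writeLines(sprintf("%s\t%.15g", bed$chrom, bed$start), con)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  ref <- sub("^#reference\t", "", hdr[startsWith(hdr, "#reference")])
  chrom_hdr <- hdr[startsWith(hdr, "#chrom")]
  parts <- strsplit(chrom_hdr, "\t", fixed = TRUE)
  sizes <- setNames(as.numeric(vapply(parts, `[[`, "", 3L)),
                    vapply(parts, `[[`, "", 2L))
  rec <- strsplit(body, "\t", fixed = TRUE)
  build_index(
    data.frame(chrom = vapply(rec, `[[`, "", 1L),
               start = as.numeric(vapply(rec, `[[`, "", 2L))),
    reference_name = ref, chrom_sizes = sizes
  )
}
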