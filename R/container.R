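# Indexed multi-sample container (.cgx).
#
# Byte layout:
#   "CGX1"                                      4-byte file magic
#   entry streams (compress_vector output), back to back
#   footer: n_entries (double8), then per entry
#           name length (double8), name (UTF-8), offset (double8),
#           length (double8)
#   footer offset (double8), "CGXF"             12-byte trailer
#
# Any entry is retrievable by name by reading the trailer, the footer and that
# entry's bytes only; appending writes new entries over the old footer and
# re-emits the footer, leaving existing entry bytes untouched.

cgx_trailer <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 16) abort(sprintf("'%s' is not a cgx container.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4L), charToRaw("CGX1"))) {
    abort(sprintf("'%s' is not a cgx container (bad magic).", path))
  }
  seek(con, size - 12)
  footer_offset <- readBin(con, "double", 1L, size = 8, endian = "little")
  if (!identical(readBin(con, "raw", 4L), charToRaw("CGXF"))) {
    abort(sprintf("'%s' has a damaged trailer.", path))
  }
  seek(con, footer_offset)
  n <- readBin(con, "double", 1L, size = 8, endian = "little")
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    name_len <- readBin(con, "double", 1L, size = 8, endian = "little")
    name <- rawToChar(readBin(con, "raw", name_len))
    off <- readBin(con, "double", 1L, size = 8, endian = "little")
    len <- readBin(con, "double", 1L, size = 8, endian = "little")
    entries[[i]] <- tibble(name = name, offset = off, length = len)
  }
  list(entries = if (n > 0) bind_rows(entries) else
         tibble(name = character(), offset = numeric(), length = numeric()),
       footer_offset = footer_offset)
}

cgx_footer_bytes <- function(entries) {
  body <- c(num_to_raw8(nrow(entries)),
            unlist(lapply(seq_len(nrow(entries)), function(i) {
              nm <- charToRaw(entries$name[i])
              c(num_to_raw8(length(nm)), nm,
                num_to_raw8(entries$offset[i]), num_to_raw8(entries$length[i]))
            }), use.names = FALSE))
  as.raw(body)
}

#' Write, append to, and read an indexed .cgx container
#'
#' A `.cgx` file holds many named, typed, compressed vectors with random
#' access: reading one of K entries touches only the footer and that entry's
#' compressed bytes. Appending preserves existing entries byte-identically.
#'
#' @param entries A named list of vectors ([cpg_set()], [mu_vector()],
#'   [state_vector()] or numeric). Names must be unique.
#' @param path File path.
#' @param scheme Compression scheme passed to [compress_vector()].
#' @return [write_container()] and [container_append()] return `path`
#'   invisibly; [container_names()] the entry names in storage order;
#'   [container_read()] the vector stored under `name`;
#'   [read_container()] a named list of all entries.
#' @export
write_container <- function(entries, path, scheme = "auto") {
  check_entry_names(names(entries), character())
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CGX1"), con)
  tab <- write_entry_blobs(con, entries, offset0 = 4, scheme = scheme)
  footer_offset <- 4 + sum(tab$length)
  writeBin(cgx_footer_bytes(tab), con)
  writeBin(num_to_raw8(footer_offset), con)
  writeBin(charToRaw("CGXF"), con)
  invisible(path)
}

check_entry_names <- function(new, existing) {
  if (is.null(new) || any(!nzchar(new))) abort("all entries must be named.")
  if (anyDuplicated(c(existing, new))) {
    abort("entry names must be unique within a container.")
  }
  invisible(new)
}

write_entry_blobs <- function(con, entries, offset0, scheme) {
  offs <- numeric(length(entries))
  lens <- numeric(length(entries))
  at <- offset0
  for (i in seq_along(entries)) {
    blob <- compress_vector(entries[[i]], scheme = scheme)
    writeBin(blob, con)
    offs[i] <- at
    lens[i] <- length(blob)
    at <- at + length(blob)
  }
  tibble(name = names(entries), offset = offs, length = lens)
}

#' @rdname write_container
#' @export
container_append <- function(entries, path, scheme = "auto") {
  tr <- cgx_trailer(path)
  check_entry_names(names(entries), tr$entries$name)
  con <- file(path, "r+b")
  on.exit(close(con))
  seek(con, tr$footer_offset, rw = "write")
  tab <- write_entry_blobs(con, entries, offset0 = tr$footer_offset,
                           scheme = scheme)
  all_tab <- bind_rows(tr$entries, tab)
  footer_offset <- tr$footer_offset + sum(tab$length)
  writeBin(cgx_footer_bytes(all_tab), con)
  writeBin(num_to_raw8(footer_offset), con)
  writeBin(charToRaw("CGXF"), con)
  # drop any stale bytes from the previous (longer) footer
  truncate_at <- seek(con, NA, rw = "write")
  close(con)
  on.exit(NULL)
  if (file.info(path)$size > truncate_at) {
    keep <- readBin(path, "raw", truncate_at)
    writeBin(keep, path)
  }
  invisible(path)
}

#' @rdname write_container
#' @export
container_names <- function(path) {
  cgx_trailer(path)$entries$name
}

#' @rdname write_container
#' @param name Entry name to retrieve.
#' @param expected_n Optional site count (e.g. a CpG index `n`); a stored
#'   entry whose dimension differs raises an error.
#' @export
container_read <- function(path, name, expected_n = NULL) {
  tr <- cgx_trailer(path)
  i <- match(name, tr$entries$name)
  if (is.na(i)) {
    abort(sprintf("no entry '%s' in '%s'; available: %s", name, path,
                  paste(tr$entries$name, collapse = ", ")))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, tr$entries$offset[i])
  v <- decompress_vector(readBin(con, "raw", tr$entries$length[i]))
  if (!is.null(expected_n)) {
    nv <- if (inherits(v, "cpg_set")) v$n_bits else
          if (is.numeric(v)) length(v) else v$n_sites
    if (nv != expected_n) {
      abort(sprintf("entry '%s' has %d sites but %d were expected.",
                    name, nv, expected_n))
    }
  }
  v
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  nms <- container_names(path)
  setNames(lapply(nms, function(nm) container_read(path, nm)), nms)
}
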