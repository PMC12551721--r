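# Compressed vector streams.
#
# Layout of a stream (all multi-byte numbers little-endian; lengths and site
# counts are 8-byte doubles holding exact integers):
#   bytes 1-4    magic "CGV1"
#   byte  5      format tag: 1 = set, 2 = mu, 3 = state, 4 = float
#   byte  6      scheme: 1 = bitpack (raw byte dump), 2 = RLE + DEFLATE
#   bytes 7-14   n_sites
#   bytes 15-22  metadata length (state-label dictionary; 0 otherwise)
#   ...          metadata bytes
#   8 bytes      payload length
#   4 bytes      Adler-32 checksum of the payload
#   ...          payload
#
# The RLE pass rewrites the uncompressed byte stream as (run length, value)
# byte pairs (runs longer than 255 are split) before DEFLATE, which suits the
# zero-dominated byte streams of sparse methylomes.

FMT_SET <- 1L; FMT_MU <- 2L; FMT_STATE <- 3L; FMT_FLOAT <- 4L
SCHEME_BITPACK <- 1L; SCHEME_RLE_DEFLATE <- 2L

num_to_raw8 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")
raw8_to_num <- function(r) readBin(r, "double", n = length(r) / 8, size = 8, endian = "little")

adler32 <- function(bytes) {
  s1 <- 1; s2 <- 0
  n <- length(bytes)
  if (n > 0) {
    b <- as.integer(bytes)
    block <- 4096L
    for (i in seq(1L, n, by = block)) {
      seg <- b[i:min(i + block - 1L, n)]
      s2 <- (s2 + length(seg) * s1 + sum(cumsum(seg))) %% 65521
      s1 <- (s1 + sum(seg)) %% 65521
    }
  }
  v <- s2 * 65536 + s1
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

rle_encode_bytes <- function(bytes) {
  if (length(bytes) == 0L) return(raw())
  r <- rle(as.integer(bytes))
  nfull <- r$lengths %/% 255L
  rem <- r$lengths %% 255L
  lens <- unlist(map2(nfull, rem, function(a, b) c(rep(255L, a), if (b > 0L) b)),
                 use.names = FALSE)
  vals <- rep.int(r$values, nfull + (rem > 0L))
  as.raw(as.vector(rbind(lens, vals)))
}

rle_decode_bytes <- function(bytes) {
  if (length(bytes) == 0L) return(raw())
  m <- matrix(as.integer(bytes), nrow = 2L)
  as.raw(rep.int(m[2, ], m[1, ]))
}

vector_payload <- function(v) {
  if (inherits(v, "cpg_set")) {
    list(tag = FMT_SET, n = v$n_bits, meta = raw(),
         bytes = packBits(c(v$bits, logical((8 - v$n_bits %% 8) %% 8))))
  } else if (inherits(v, "mu_vector")) {
    list(tag = FMT_MU, n = v$n_sites, meta = raw(), bytes = mu_to_raw(v$m, v$u))
  } else if (inherits(v, "state_vector")) {
    lab <- charToRaw(paste(v$labels, collapse = "\n"))
    wide <- length(v$labels) > 256L
    bytes <- if (wide) {
      writeBin(as.integer(v$codes - 1L), raw(), size = 4, endian = "little")
    } else {
      as.raw(v$codes - 1L)
    }
    list(tag = FMT_STATE, n = v$n_sites,
         meta = c(as.raw(as.integer(wide)), lab), bytes = bytes)
  } else if (is.numeric(v)) {
    list(tag = FMT_FLOAT, n = length(v),
         meta = raw(), bytes = writeBin(as.numeric(v), raw(), size = 8,
                                        endian = "little"))
  } else {
    abort("unsupported vector type for compression.")
  }
}

payload_to_vector <- function(tag, n, meta, bytes) {
  if (tag == FMT_SET) {
    bits <- as.logical(rawToBits(bytes))[seq_len(n)]
    new_cpg_set(bits)
  } else if (tag == FMT_MU) {
    p <- raw_to_mu(bytes)
    mu_vector(p$m, p$u)
  } else if (tag == FMT_STATE) {
    wide <- as.integer(meta[1]) == 1L
    labels <- strsplit(rawToChar(meta[-1]), "\n", fixed = TRUE)[[1]]
    codes <- if (wide) {
      readBin(bytes, "integer", n = n, size = 4, endian = "little") + 1L
    } else {
      as.integer(bytes) + 1L
    }
    structure(list(n_sites = n, labels = labels, codes = codes),
              class = "state_vector")
  } else if (tag == FMT_FLOAT) {
    readBin(bytes, "double", n = n, size = 8, endian = "little")
  } else {
    abort(sprintf("unknown format tag %d in stream.", tag))
  }
}

#' Compress and decompress cgkit vectors
#'
#' Serialises a [cpg_set()], [mu_vector()], [state_vector()] or plain numeric
#' (float) vector into a self-describing byte stream. Bit sets are bit-packed
#' (8 sites per byte); all streams can additionally pass through a run-length
#' encoding of identical bytes followed by DEFLATE, which is what makes
#' zero-dominated sparse methylomes small on disk. Decompression is the exact
#' inverse on every path: there is no lossy codec anywhere in cgkit.
#'
#' @param v The vector to compress.
#' @param scheme `"auto"` (default) chooses RLE + DEFLATE for bit sets with
#'   density below `density_threshold` and for all non-set types, plain
#'   bit-packing otherwise; `"bitpack"` and `"rle_deflate"` force a scheme.
#' @param density_threshold Set density below which `"auto"` uses
#'   RLE + DEFLATE (default 0.25).
#' @return [compress_vector()]: a raw vector (the stream);
#'   [decompress_vector()]: the original vector, bit for bit.
#' @export
compress_vector <- function(v, scheme = c("auto", "bitpack", "rle_deflate"),
                            density_threshold = 0.25) {
  scheme <- match.arg(scheme)
  p <- vector_payload(v)
  sch <- switch(scheme,
    bitpack = SCHEME_BITPACK,
    rle_deflate = SCHEME_RLE_DEFLATE,
    auto = if (p$tag == FMT_SET && p$n > 0 &&
               sum(v$bits) / p$n >= density_threshold) {
      SCHEME_BITPACK
    } else {
      SCHEME_RLE_DEFLATE
    }
  )
  payload <- if (sch == SCHEME_BITPACK) {
    p$bytes
  } else {
    memCompress(rle_encode_bytes(p$bytes), type = "gzip")
  }
  c(charToRaw("CGV1"), as.raw(p$tag), as.raw(sch),
    num_to_raw8(p$n), num_to_raw8(length(p$meta)), p$meta,
    num_to_raw8(length(payload)), adler32(payload), payload)
}

#' @rdname compress_vector
#' @param blob A raw stream produced by [compress_vector()].
#' @export
decompress_vector <- function(blob) {
  need <- function(upto) {
    if (length(blob) < upto) {
      abort(sprintf("truncated stream: need %d bytes, have %d.", upto, length(blob)))
    }
  }
  need(22L)
  if (!identical(blob[1:4], charToRaw("CGV1"))) {
    abort("not a cgkit vector stream (bad magic at byte 1).")
  }
  tag <- as.integer(blob[5]); sch <- as.integer(blob[6])
  n <- raw8_to_num(blob[7:14])
  meta_len <- raw8_to_num(blob[15:22])
  need(22L + meta_len + 12L)
  meta <- if (meta_len > 0) blob[23:(22 + meta_len)] else raw()
  at <- 22L + meta_len
  payload_len <- raw8_to_num(blob[(at + 1):(at + 8)])
  stored_sum <- blob[(at + 9):(at + 12)]
  need(at + 12L + payload_len)
  payload <- if (payload_len > 0) {
    blob[(at + 13):(at + 12 + payload_len)]
  } else {
    raw()
  }
  if (!identical(adler32(payload), stored_sum)) {
    abort(sprintf("corrupt stream: checksum mismatch over payload at byte %d.",
                  at + 13L))
  }
  bytes <- if (sch == SCHEME_BITPACK) {
    payload
  } else {
    rle_decode_bytes(memDecompress(payload, type = "gzip"))
  }
  payload_to_vector(tag, n, meta, bytes)
}
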