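# 64-bit MU codes: M in the upper 32 bits, U in the lower 32 bits.
# R lacks a native 64-bit integer, so a code travels as a double whose 8-byte
# payload IS the little-endian 64-bit word (the same device the bit64 package
# uses). All conversions go through raw bytes and are exact over the full
# 32-bit count range; the numeric value m*2^32 + u is recovered by exact limb
# arithmetic for display.

mu_to_raw <- function(m, u) {
  b <- rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256,
             (u %/% 16777216) %% 256,
             m %% 256, (m %/% 256) %% 256, (m %/% 65536) %% 256,
             (m %/% 16777216) %% 256)
  as.raw(as.vector(b))
}

raw_to_mu <- function(r) {
  b <- matrix(as.integer(r), nrow = 8L)
  list(m = b[5, ] + 256 * b[6, ] + 65536 * b[7, ] + 16777216 * b[8, ],
       u = b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ])
}

#' Pack and unpack 64-bit M/U codes
#'
#' A site's methylated (M) and unmethylated (U) read counts are stored in one
#' 64-bit word: M occupies the upper 32 bits and U the lower 32 bits, i.e. the
#' code value is `m * 2^32 + u`. Counts outside `[0, 2^32 - 1]` raise an
#' overflow error rather than saturating, since silently corrupted counts
#' would bias beta values.
#'
#' @param m,u Non-negative integer counts, each at most `2^32 - 1`.
#' @return [pack_mu()] returns a `mu64` vector (doubles carrying the 64-bit
#'   payload; print/format show the exact decimal code value).
#'   [unpack_mu()] returns a list with numeric fields `m` and `u` and is the
#'   exact inverse of [pack_mu()].
#' @examples
#' format(pack_mu(3, 5))   # "12884901893" == 3 * 2^32 + 5
#' unpack_mu(pack_mu(3, 5))
#' @export
pack_mu <- function(m, u) {
  n <- max(length(m), length(u))
  m <- rep_len(as.numeric(m), n)
  u <- rep_len(as.numeric(u), n)
  check_counts32(m, "m")
  check_counts32(u, "u")
  codes <- readBin(mu_to_raw(m, u), "double", n, endian = "little")
  structure(codes, class = "mu64")
}

#' @rdname pack_mu
#' @param code A `mu64` vector produced by [pack_mu()].
#' @export
unpack_mu <- function(code) {
  stopifnot(inherits(code, "mu64"))
  raw_to_mu(writeBin(unclass(code), raw(), endian = "little"))
}

u64_decimal <- function(m, u) {
  # exact decimal of m*2^32 + u via base-1e6 limb arithmetic
  vapply(seq_along(m), function(i) {
    limbs <- c(m[i] %/% 65536, m[i] %% 65536, u[i] %/% 65536, u[i] %% 65536)
    big <- 0  # little-endian base-1e6 digit vector
    for (l in limbs) {
      big <- big * 65536
      big[1] <- big[1] + l
      carry <- big %/% 1e6
      big <- big %% 1e6
      while (any(carry > 0)) {
        big <- c(big, 0)[seq_len(max(length(big), length(carry) + 1L))]
        idx <- seq_along(carry) + 1L
        big[idx] <- big[idx] + carry
        carry <- big %/% 1e6
        big <- big %% 1e6
      }
    }
    while (length(big) > 1L && big[length(big)] == 0) big <- big[-length(big)]
    paste0(c(format(big[length(big)], scientific = FALSE),
             sprintf("%06d", rev(big[-length(big)]))), collapse = "")
  }, character(1))
}

#' @export
format.mu64 <- function(x, ...) {
  p <- unpack_mu(x)
  u64_decimal(p$m, p$u)
}

#' @export
print.mu64 <- function(x, ...) {
  cat(sprintf("<mu64> %d code(s)\n", length(unclass(x))))
  print(format(x))
  invisible(x)
}

#' @export
as.character.mu64 <- function(x, ...) format(x)

#' @export
`[.mu64` <- function(x, i) structure(unclass(x)[i], class = "mu64")

#' @export
length.mu64 <- function(x) length(unclass(x))
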