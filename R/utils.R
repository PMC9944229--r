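# Internal helpers: conditions, path handling, seeded randomness, digests.

`%||%` <- function(x, y) if (is.null(x)) y else x

wfr_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "wfr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

nonempty_string <- function(x) is_string(x) && nzchar(x)

#' @keywords internal
#' @noRd
compact <- function(x) x[!vapply(x, is.null, logical(1))]

# POSIX-style normalization of a registry-relative target path.
# Returns NA_character_ when the path is not a clean relative path.
normalize_target <- function(path) {
  if (!is_string(path) || !nzchar(path)) return(NA_character_)
  if (grepl("^/", path) || grepl("^[A-Za-z]:", path)) return(NA_character_)
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  parts <- parts[parts != "." & nzchar(parts)]
  if (any(parts == "..")) return(NA_character_)
  if (length(parts) == 0L) return(NA_character_)
  paste(parts, collapse = "/")
}

is_uuid <- function(x) {
  nonempty_string(x) && grepl(
    "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
    tolower(x)
  )
}

is_dotted_version <- function(x) {
  nonempty_string(x) && grepl("^[0-9]+(\\.[0-9]+)*$", x)
}

is_orcid <- function(x) {
  nonempty_string(x) && grepl("^[0-9]{4}-[0-9]{4}-[0-9]{4}-[0-9]{3}[0-9X]$", x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards; with seed = NULL the global stream is used.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a workflow identifier
#'
#' Draws a fresh version-4 UUID for use as a workflow `id`. With a seed the
#' draw is reproducible and leaves the caller's random-number stream
#' untouched; without one it consumes the session stream.
#'
#' @param seed Optional integer seed for a reproducible identifier.
#' @return A UUID string in 8-4-4-4-12 form with version nibble 4.
#' @examples
#' new_workflow_id(seed = 1)
#' @export
new_workflow_id <- function(seed = NULL) {
  hex <- c(as.character(0:9), letters[1:6])
  with_local_seed(seed, {
    nib <- sample(hex, 32L, replace = TRUE)
    nib[13L] <- "4"
    nib[17L] <- sample(c("8", "9", "a", "b"), 1L)
    paste0(
      paste(nib[1:8], collapse = ""), "-",
      paste(nib[9:12], collapse = ""), "-",
      paste(nib[13:16], collapse = ""), "-",
      paste(nib[17:20], collapse = ""), "-",
      paste(nib[21:32], collapse = "")
    )
  })
}

# --- file URL helpers --------------------------------------------------------

url_scheme <- function(url) {
  m <- regmatches(url, regexpr("^[A-Za-z][A-Za-z0-9+.-]*(?=://)", url, perl = TRUE))
  if (length(m) == 0L) NA_character_ else tolower(m)
}

file_url_to_path <- function(url) {
  path <- sub("^file://", "", url)
  utils::URLdecode(path)
}

path_to_file_url <- function(path) {
  paste0("file://", normalizePath(path, winslash = "/", mustWork = FALSE))
}

# --- SHA-256 -----------------------------------------------------------------
# Self-contained FIPS 180-4 SHA-256 over 32-bit words held as doubles in
# [0, 2^32); bitwise ops route through R's signed-integer bitwAnd/bitwXor.

u32_to_i32 <- function(x) as.integer(x - (x >= 2^31) * 2^32)
i32_to_u32 <- function(x) {
  x <- as.numeric(x)
  x + (x < 0) * 2^32
}
bxor32 <- function(a, b) i32_to_u32(bitwXor(u32_to_i32(a), u32_to_i32(b)))
band32 <- function(a, b) i32_to_u32(bitwAnd(u32_to_i32(a), u32_to_i32(b)))
bnot32 <- function(a) (2^32 - 1) - a
shr32 <- function(x, n) floor(x / 2^n)
rotr32 <- function(x, n) (floor(x / 2^n) + (x %% 2^n) * 2^(32 - n)) %% 2^32

sha256_k <- local({
  # fractional parts of cube roots of the first 64 primes
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173, 179, 181,
              191, 193, 197, 199, 211, 223, 227, 229, 233, 239, 241, 251,
              257, 263, 269, 271, 277, 281, 283, 293, 307, 311)
  floor((primes^(1 / 3) %% 1) * 2^32)
})

sha256_h0 <- local({
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19)
  floor((sqrt(primes) %% 1) * 2^32)
})

#' Compute the SHA-256 digest of raw bytes or a string
#'
#' @param data A raw vector or a single string (digested as UTF-8 bytes).
#' @return Lower-case hex digest string.
#' @export
sha256_hex <- function(data) {
  if (is.character(data)) data <- charToRaw(enc2utf8(data))
  stopifnot(is.raw(data))
  len <- length(data)
  bitlen <- len * 8
  # pad: 0x80, zeros, 64-bit big-endian length
  padlen <- (56 - (len + 1) %% 64) %% 64
  msg <- c(data, as.raw(0x80), raw(padlen),
           as.raw(floor(bitlen / 2^c(56, 48, 40, 32, 24, 16, 8, 0)) %% 256))
  bytes <- as.numeric(msg)
  nblocks <- length(bytes) / 64
  h <- sha256_h0
  w <- numeric(64)
  for (blk in seq_len(nblocks)) {
    off <- (blk - 1) * 64
    idx <- off + seq_len(64)
    b <- bytes[idx]
    w[1:16] <- b[seq(1, 64, 4)] * 2^24 + b[seq(2, 64, 4)] * 2^16 +
      b[seq(3, 64, 4)] * 2^8 + b[seq(4, 64, 4)]
    for (t in 17:64) {
      s0 <- bxor32(bxor32(rotr32(w[t - 15], 7), rotr32(w[t - 15], 18)), shr32(w[t - 15], 3))
      s1 <- bxor32(bxor32(rotr32(w[t - 2], 17), rotr32(w[t - 2], 19)), shr32(w[t - 2], 10))
      w[t] <- (w[t - 16] + s0 + w[t - 7] + s1) %% 2^32
    }
    a <- h[1]; bb <- h[2]; cc <- h[3]; d <- h[4]
    e <- h[5]; f <- h[6]; g <- h[7]; hh <- h[8]
    for (t in 1:64) {
      S1 <- bxor32(bxor32(rotr32(e, 6), rotr32(e, 11)), rotr32(e, 25))
      ch <- bxor32(band32(e, f), band32(bnot32(e), g))
      t1 <- (hh + S1 + ch + sha256_k[t] + w[t]) %% 2^32
      S0 <- bxor32(bxor32(rotr32(a, 2), rotr32(a, 13)), rotr32(a, 22))
      maj <- bxor32(bxor32(band32(a, bb), band32(a, cc)), band32(bb, cc))
      t2 <- (S0 + maj) %% 2^32
      hh <- g; g <- f; f <- e
      e <- (d + t1) %% 2^32
      d <- cc; cc <- bb; bb <- a
      a <- (t1 + t2) %% 2^32
    }
    h <- (h + c(a, bb, cc, d, e, f, g, hh)) %% 2^32
  }
  paste(sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536)),
        collapse = "")
}
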