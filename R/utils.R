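# internal helpers: hashing, RNG state preservation, logging

# 32-bit FNV-1a over UTF-8 bytes, in double arithmetic kept under 2^53
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  as.numeric(hi) * 2147483648 + as.numeric(lo)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

ucd_log <- function(fmt, ..., quiet = FALSE) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
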