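#' @keywords internal
"_PACKAGE"

# Factor levels used throughout; order is load-bearing (control first,
# nuclear first) so that column layouts and ratio orientations are stable.
CONDITIONS <- c("control", "repeat")
FRACTIONS <- c("nuclear", "cytoplasmic")

#' FNV-1a hash of a character scalar
#'
#' Tiny dependency-free 32-bit hash used to stamp result tables with a
#' fingerprint of the configuration that produced them.
#'
#' @param x character scalar
#' @return 8-character lowercase hex string
#' @keywords internal
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low 8 bits (b < 256), keeping h a plain double
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # h * 16777619 mod 2^32, split as 2^24 + 403 so every product is exact
    # in double precision: h*2^24 mod 2^32 only keeps the low 8 bits of h.
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Stable fingerprint of a flat option list, for result-table headers.
config_fingerprint <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  flat <- flat[order(names(flat))]
  fnv1a32(paste(names(flat), as.character(flat), sep = "=", collapse = ";"))
}

# Stop with a stage-prefixed message (pipeline error contract).
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
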