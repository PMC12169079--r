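# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_fraction <- function(x, open_left = FALSE, open_right = FALSE) {
  is_scalar_num(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
}

# One global seed fans out to per-stage child seeds by fixed offsets, so each
# simulation stage is independently reproducible. Offsets are arbitrary but
# frozen; the result stays inside 32-bit integer range.
STAGE_OFFSETS <- c(
  repertoire = 101L, tissue = 211L, cells = 307L, transcripts = 401L,
  enrichment = 503L, pipeline = 601L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(STAGE_OFFSETS))
  as.integer((as.numeric(seed) + STAGE_OFFSETS[[stage]]) %% 2147483647)
}

# Amino-acid alphabet used for CDR3 sequences (20 standard residues).
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Strip the allele suffix from an IMGT-style gene call: "TRBV7-9*01" -> "TRBV7-9".
strip_allele <- function(v) sub("\\*.*$", "", v)

# Nearest other point for every point (or for a subset `query`), via a grid
# index with ring expansion. Used for bleed-through target assignment where a
# dense distance matrix would not scale.
nearest_other_point <- function(x, y, query = seq_along(x)) {
  n <- length(x)
  if (n < 2L) stopf("nearest_other_point() needs at least two points")
  span_x <- max(diff(range(x)), 1e-9)
  span_y <- max(diff(range(y)), 1e-9)
  s <- max(sqrt(span_x * span_y / n) * 2, 1e-9)
  bx <- as.integer(floor((x - min(x)) / s))
  by <- as.integer(floor((y - min(y)) / s))
  nbx <- max(bx) + 1L
  key <- bx + by * nbx
  bucket_of <- split(seq_len(n), key)
  out <- integer(length(query))
  for (qi in seq_along(query)) {
    i <- query[qi]
    r <- 1L
    best <- NA_integer_
    best_d <- Inf
    repeat {
      keys <- as.vector(outer(bx[i] + (-r:r), (by[i] + (-r:r)) * nbx, "+"))
      cand <- unlist(bucket_of[as.character(keys)], use.names = FALSE)
      cand <- cand[cand != i]
      if (length(cand)) {
        d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
        j <- which.min(d2)
        if (d2[j] < best_d) {
          best_d <- d2[j]
          best <- cand[j]
        }
      }
      # Any point outside the searched block is at least r*s away.
      if (!is.na(best) && sqrt(best_d) <= r * s) break
      r <- r + 1L
    }
    out[qi] <- best
  }
  out
}
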