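# Independent oracles used to validate the package's computations. These
# deliberately use naive, brute-force implementations.

# Quadratic dynamic-programming Levenshtein distance.
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L,
        D[i, j] + (x[i] != y[j])
      )
    }
  }
  D[n + 1L, m + 1L]
}

# Benjamini-Hochberg step-up, written as the textbook procedure.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[ro]
}

# Two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins: sum the hypergeometric probabilities of every table at
# most as probable as the observed one (with the customary relative
# tolerance for ties).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force minimum Euclidean distance (micrometres, centre-to-centre)
# from every pixel to the nearest TRUE pixel of `target`; chunked so small
# rasters stay affordable.
brute_force_distance <- function(target, pixel_size_um) {
  nr <- nrow(target); nc <- ncol(target)
  idx <- which(target)
  ty <- ((idx - 1L) %% nr) + 1L
  tx <- ((idx - 1L) %/% nr) + 1L
  out <- matrix(Inf, nr, nc)
  if (!length(idx)) return(out)
  all_y <- rep(seq_len(nr), nc)
  all_x <- rep(seq_len(nc), each = nr)
  chunk <- 2000L
  for (s in seq(1L, nr * nc, by = chunk)) {
    e <- min(s + chunk - 1L, nr * nc)
    dy <- outer(all_y[s:e], ty, "-")
    dx <- outer(all_x[s:e], tx, "-")
    out[s:e] <- sqrt(apply(dy^2 + dx^2, 1L, min))
  }
  out * pixel_size_um
}
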