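# Independent brute-force implementations of the topographic peak
# definitions, written as plain loops straight from the definitions. Used as
# the oracle against which find_peaks() is checked; deliberately shares no
# code with the package internals.

oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer()
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    # walk over a possible plateau of equal values
    j <- i
    while (j + 1 <= n && x[j + 1] == x[i]) j <- j + 1
    if (j + 1 <= n && x[j + 1] < x[i]) out <- c(out, i - 1L) # 0-based
  }
  out
}

oracle_prominence <- function(x, idx0) {
  i <- idx0 + 1L
  apex <- x[i]
  n <- length(x)
  left <- apex
  for (j in rev(seq_len(i - 1))) {
    if (x[j] > apex) break
    left <- min(left, x[j])
  }
  right <- apex
  for (j in seq(i + 1, n)) {
    if (x[j] > apex) break
    right <- min(right, x[j])
  }
  apex - max(left, right)
}

oracle_width <- function(x, idx0, prom) {
  i <- idx0 + 1L
  n <- length(x)
  ref <- x[i] - prom / 2
  lc <- 0
  for (j in rev(seq_len(i - 1))) {
    if (x[j] <= ref) {
      frac <- (ref - x[j]) / (x[j + 1] - x[j])
      lc <- (j - 1) + frac
      break
    }
  }
  rc <- n - 1
  for (j in seq(i + 1, n)) {
    if (x[j] <= ref) {
      frac <- (ref - x[j - 1]) / (x[j] - x[j - 1])
      rc <- (j - 2) + frac
      break
    }
  }
  c(left = lc, right = rc, width = rc - lc)
}

oracle_find_peaks <- function(x, min_prominence, n_peaks = 1L) {
  cands <- oracle_local_maxima(x)
  rows <- list()
  for (c0 in cands) {
    p <- oracle_prominence(x, c0)
    if (p >= min_prominence) {
      w <- oracle_width(x, c0, p)
      rows[[length(rows) + 1]] <- data.frame(
        index = c0, prominence = p, width = unname(w["width"])
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(index = integer(), prominence = double(), width = double()))
  }
  out <- do.call(rbind, rows)
  out[seq_len(min(n_peaks, nrow(out))), , drop = FALSE]
}

random_trace <- function(max_len = 50L, lo = -200L, hi = 200L) {
  n <- sample(3:max_len, 1)
  as.numeric(sample(lo:hi, n, replace = TRUE))
}
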