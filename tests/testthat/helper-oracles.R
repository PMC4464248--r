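# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Brute-force motif scan: minimum mismatch count over every window in the
# allowed start range, counting only constrained positions.
bruteMotifScan <- function(protein, pattern, starts) {
  aa <- strsplit(protein, "")[[1]]
  pl <- length(pattern)
  best <- Inf; bestPos <- NA_integer_
  for (s in starts) {
    m <- 0L
    for (k in seq_len(pl)) {
      allowed <- pattern[[k]]
      if (is.null(allowed)) next
      if (!aa[s + k - 1L] %in% allowed) m <- m + 1L
    }
    if (m < best) { best <- m; bestPos <- s }
  }
  list(mismatches = best, position = bestPos)
}

# Plain Needleman-Wunsch with linear gap penalty, returning the aligned
# strings; small and slow, for tiny examples only.
bruteNW <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (A[i] == B[j]) match else mismatch,
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; ra <- rb <- character()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] +
          (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1
    }
  }
  c(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

randomAa <- function(n) paste(sample(c("A","R","N","D","C","Q","E","G",
                                       "H","I","L","K","M","F","P","S",
                                       "T","W","Y","V"), n, replace = TRUE),
                              collapse = "")
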