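# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and must stay independent of the
# package's vectorized code paths.

# direct double-loop Gaussian smoothing of the histidine indicator
oracle_profile <- function(sequence, fwhm = 5, span = 20,
                           residues = "H") {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- floor(span / 2)
  chars <- strsplit(toupper(sequence), "")[[1]]
  ind <- as.numeric(chars %in% residues)
  n <- length(chars)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in -half:half) {
      j <- i + k
      if (j >= 1 && j <= n) s <- s + ind[j] * exp(-k^2 / (2 * sigma^2))
    }
    out[i] <- s
  }
  out
}

# naive scan for local maxima above a strict threshold, plateau counted
# once at its first index, greedy merge by decreasing value
oracle_peaks <- function(profile, thr = 1, min_sep = 20) {
  n <- length(profile)
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    v <- profile[i]
    if (v > thr) {
      j <- i
      while (j < n && profile[j + 1] == v) j <- j + 1L
      lv <- if (i == 1L) -Inf else profile[i - 1]
      rv <- if (j == n) -Inf else profile[j + 1]
      if (v > lv && v > rv) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  acc <- integer(0)
  for (idx in cand[order(-profile[cand], cand)])
    if (!length(acc) || all(abs(acc - idx) >= min_sep))
      acc <- c(acc, idx)
  sort(acc)
}

# max histidine count over all length-`window` windows containing position i
oracle_window_his <- function(sequence, i, window = 20) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  best <- 0L
  for (s in max(1L, i - window + 1L):min(i, n - window + 1L)) {
    if (s < 1L) next
    e <- min(n, s + window - 1L)
    best <- max(best, sum(chars[s:e] == "H"))
  }
  best
}

# normal-equations OLS used as an oracle against the QR path of fit_gene
oracle_ols <- function(Y, X) {
  xtx <- t(X) %*% X
  beta <- solve(xtx) %*% t(X) %*% Y
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(beta = as.numeric(beta),
       se = sqrt(sigma2 * diag(solve(xtx))),
       sigma2 = sigma2)
}

random_protein <- function(len, p_his = 0.025) {
  aa <- c("A", "G", "S", "T", "P", "Q", "L", "V", "K", "E")
  chars <- sample(aa, len, replace = TRUE)
  his <- runif(len) < p_his
  chars[his] <- "H"
  paste(chars, collapse = "")
}
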