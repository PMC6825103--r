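# Independent naive reference implementations used as oracles.
# These deliberately use plain double loops / string-keyed censuses so they
# share no code path with the package's compiled estimators.

chebDistRef <- function(x, i, j, m) max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))

apenRef <- function(x, m, r) {
  phi <- function(k) {
    nt <- length(x) - k + 1
    vals <- vapply(seq_len(nt), function(i) {
      cnt <- sum(vapply(seq_len(nt),
                        function(j) chebDistRef(x, i, j, k) <= r, logical(1)))
      log(cnt / nt)
    }, numeric(1))
    mean(vals)
  }
  phi(m) - phi(m + 1)
}

sampenRef <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (chebDistRef(x, i, j, m) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) NA_real_ else -log(A / B)
}

fuzzyRef <- function(x, m, r, n = 2) {
  phi <- function(k, nt) {
    sims <- numeric(nt * (nt - 1) / 2); s <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        ti <- x[i:(i + k - 1)]; ti <- ti - mean(ti)
        tj <- x[j:(j + k - 1)]; tj <- tj - mean(tj)
        s <- s + 1L
        sims[s] <- exp(-(max(abs(ti - tj)) / r)^n)
      }
    }
    mean(sims)
  }
  nt <- length(x) - m
  log(phi(m, nt)) - log(phi(m + 1, nt))
}

permRef <- function(x, ord, delay = 1, normalized = TRUE) {
  nwin <- length(x) - (ord - 1) * delay
  keys <- vapply(seq_len(nwin), function(t) {
    w <- x[t + (0:(ord - 1)) * delay]
    paste(rank(w, ties.method = "first"), collapse = "-")
  }, character(1))
  p <- table(keys) / nwin
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(ord)) else h
}

# AUC as the fraction of positive-negative score pairs correctly ordered,
# ties counted one half.
aucPairRef <- function(scores, labels, positive = "female") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))
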