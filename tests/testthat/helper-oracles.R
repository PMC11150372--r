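# Independent brute-force oracles used to pin down the fast implementations.

# Haar approximation cascade by literal pairwise replacement (a,b) -> (a+b)/sqrt(2);
# defined for inputs whose length stays even through every level.
oracle_haar_cascade <- function(x, level) {
  for (l in seq_len(level)) {
    stopifnot(length(x) %% 2 == 0)
    out <- numeric(length(x) / 2)
    for (i in seq_along(out)) out[i] <- (x[2 * i - 1] + x[2 * i]) / sqrt(2)
    x <- out
  }
  x
}

# O(n^2) DFT amplitudes from the definition, half-spectrum
oracle_dft_amplitude <- function(x) {
  n <- length(x)
  k_max <- floor(n / 2)
  vapply(0:k_max, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# exhaustive F-max: every distinct score as threshold, plus all-negative
oracle_f_max <- function(labels, scores) {
  y <- labels == "divided"
  best <- 0; best_thr <- Inf
  for (thr in sort(unique(scores))) {
    pred <- scores >= thr
    tp <- sum(pred & y)
    f <- if (tp == 0) 0 else {
      p <- tp / sum(pred); r <- tp / sum(y); 2 * p * r / (p + r)
    }
    if (f > best) { best <- f; best_thr <- thr }
  }
  list(f_max = best, threshold = best_thr)
}

# all-pairs Mann-Whitney AUC with ties counted 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "divided"]
  neg <- scores[labels == "undivided"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}
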