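# Independent brute-force oracles, deliberately written as naive loops so
# they share no code with the package implementations they check.

naive_roll <- function(x, width, fun) {
  out <- rep(NA_real_, length(x))
  for (t in seq_along(x)) {
    if (t >= width) out[t] <- fun(x[(t - width + 1):t])
  }
  out
}

naive_monotony <- function(tl, width = 7) {
  out <- rep(NA_real_, length(tl))
  for (t in seq_along(tl)) {
    if (t >= width) {
      w <- tl[(t - width + 1):t]
      s <- sqrt(sum((w - mean(w))^2) / (width - 1))
      out[t] <- if (s > 0) mean(w) / s else NA_real_
    }
  }
  out
}

naive_strain <- function(tl, width = 7) {
  m <- naive_monotony(tl, width)
  out <- rep(NA_real_, length(tl))
  for (t in seq_along(tl)) {
    if (t >= width) out[t] <- sum(tl[(t - width + 1):t]) * m[t]
  }
  out
}

naive_ewma <- function(x, span = 7) {
  a <- 2 / (span + 1)
  out <- numeric(length(x))
  out[1] <- x[1]
  if (length(x) > 1) {
    for (t in 2:length(x)) out[t] <- a * x[t] + (1 - a) * out[t - 1]
  }
  out
}

naive_consec <- function(tl) {
  out <- integer(length(tl))
  for (t in seq_along(tl)) {
    if (tl[t] > 0) out[t] <- (if (t > 1) out[t - 1] else 0L) + 1L else out[t] <- 0L
  }
  out
}

naive_diff <- function(x) {
  out <- rep(NA_real_, length(x))
  for (t in seq_along(x)) if (t > 1) out[t] <- x[t] - x[t - 1]
  out
}

# iterative correlation pruning re-derived from scratch each round
naive_prune_order <- function(df, threshold = 0.85) {
  removed <- character(0)
  repeat {
    keep <- setdiff(names(df), removed)
    if (length(keep) < 2) break
    C <- abs(cor(as.matrix(df[keep])))
    diag(C) <- 0
    if (max(C) <= threshold) break
    idx <- which(C == max(C), arr.ind = TRUE)[1, ]
    i <- keep[idx[1]]; j <- keep[idx[2]]
    mi <- mean(C[i, setdiff(keep, i)])
    mj <- mean(C[j, setdiff(keep, j)])
    drop <- if (mi > mj) i else if (mj > mi) j else
      c(i, j)[which.max(match(c(i, j), keep))]
    removed <- c(removed, drop)
  }
  removed
}
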