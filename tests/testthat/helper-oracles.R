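# Independent reference implementations, coded directly from the defining
# formulas with explicit loops, against which the package estimators are
# checked. They deliberately share no code with the implementation.

oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  s <- w[o] / sum(w)
  p <- numeric(length(b))
  run <- 0
  for (j in seq_along(b)) {
    p[j] <- run + s[j] / 2
    run <- run + s[j]
  }
  if (p[1] >= 0.5) return(b[1])
  if (p[length(b)] <= 0.5) return(b[length(b)])
  hi <- which(p >= 0.5)[1]
  lo <- hi - 1
  b[lo] + (b[hi] - b[lo]) * (0.5 - p[lo]) / (p[hi] - p[lo])
}

oracle_kde_mode <- function(b, w, h, n_grid = 512) {
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  dens <- numeric(n_grid)
  for (i in seq_len(n_grid))
    dens[i] <- sum(w * dnorm(grid[i], mean = b, sd = h))
  grid[which.max(dens)]
}
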