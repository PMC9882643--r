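# Independently coded brute-force oracles. These deliberately avoid the
# package's code paths (and stats::quantile): landmarks come from explicit
# sort-and-interpolate, statistics from explicit loops.

# linear-interpolation percentile at fractional rank h = (n-1)q/100 + 1
oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

oracle_cv <- function(means) oracle_pop_sd(means) / (sum(means) / length(means))

oracle_md <- function(m1, m2) {
  acc <- 0
  for (i in seq_along(m1))
    acc <- acc + abs(m1[i] - m2[i]) / ((m1[i] + m2[i]) / 2)
  acc / length(m1)
}

# organ mean after mapping [min(I), p_b(body)] -> [0, s_max], one image
oracle_lambda_organ_mean <- function(vox, organ, b, s_max) {
  body_vals <- vox[vox > mean(vox)]
  p_a <- min(vox)
  p_b <- oracle_percentile(body_vals, b)
  mapped <- s_max * (vox[organ] - p_a) / (p_b - p_a)
  sum(mapped) / length(mapped)
}

# cohort CV of the lambda-mapped organ mean (vox_list: plain arrays)
oracle_delta <- function(vox_list, organ_list, b, s_max) {
  mus <- numeric(length(vox_list))
  for (i in seq_along(vox_list))
    mus[i] <- oracle_lambda_organ_mean(vox_list[[i]], organ_list[[i]], b, s_max)
  oracle_cv(mus)
}

oracle_sm <- function(vox_list, beta, s_max) {
  vals <- numeric(length(vox_list))
  for (i in seq_along(vox_list)) {
    vox <- vox_list[[i]]
    body_vals <- vox[vox > mean(vox)]
    p_a <- min(vox)
    p_m <- oracle_percentile(body_vals, 50)
    p_b <- oracle_percentile(body_vals, beta)
    vals[i] <- s_max * (p_m - p_a) / (p_b - p_a)
  }
  sum(vals) / length(vals)
}

# exhaustive grid argmin of oracle_delta with largest-b tie breaking
oracle_beta_grid <- function(vox_list, organ_list, b_low, b_high, step, s_max) {
  grid <- seq(b_low, b_high, by = step)
  delta <- vapply(grid, function(b)
    oracle_delta(vox_list, organ_list, b, s_max), numeric(1))
  dmin <- min(delta)
  ties <- which(delta <= dmin + 1e-12 + 1e-8 * dmin)
  list(beta = grid[ties[length(ties)]], grid = grid, delta = delta)
}
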