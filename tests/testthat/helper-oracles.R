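# Brute-force statistical oracles, deliberately independent of the package's
# implementation paths.

# exact two-sided Mann-Whitney p by enumerating every label assignment
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); N <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs_dev <- abs(u_of(a, b) - n * (N - n) / 2)
  combos <- utils::combn(N, n)
  devs <- apply(combos, 2, function(idx)
    abs(u_of(pooled[idx], pooled[-idx]) - n * (N - n) / 2))
  mean(devs >= obs_dev - 1e-12)
}

# Cliff's delta via the explicit double loop
cliffs_delta_loops <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}
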