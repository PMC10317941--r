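# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Dx by brute force: sort voxel doses descending, take the k-th largest
# with k = ceiling(x * N / 100)
oracle_dx <- function(doses, x) {
  s <- sort(doses, decreasing = TRUE)
  s[ceiling(x * length(s) / 100)]
}

# Vx by direct counting
oracle_vx <- function(doses, x) 100 * sum(doses >= x) / length(doses)

# two-sided Mann-Whitney p by full enumeration of all C(m+n, m) group
# assignments of the pooled (tie-free) values
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  m <- length(x)
  idx <- utils::combn(N, m)
  r <- rank(pooled)
  u_of <- function(ii) sum(r[ii]) - m * (m + 1) / 2
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(m))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Kruskal-Wallis H from the textbook rank formula (no ties)
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  12 / (N * (N + 1)) *
    sum(vapply(splits, function(g) length(g) * (mean(g) - (N + 1) / 2)^2,
               numeric(1)))
}
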