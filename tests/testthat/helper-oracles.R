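# Independent oracles used to cross-check library-backed implementations.
# These deliberately share no code with the package paths they verify.

# Greedy minimal-variance-increase (Ward) agglomeration: at every step merge
# the pair of clusters whose union raises the total within-cluster sum of
# squares least; ties resolved by lowest pair index. Returns the member sets
# merged at each step.
ward_oracle_merges <- function(X) {
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    m <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2L, m)^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  merges <- vector("list", nrow(X) - 1L)
  for (s in seq_len(nrow(X) - 1L)) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[s]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets merged at each step of an hclust tree, for comparison with the
# oracle above.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(members(hc$merge[s, 1L]), members(hc$merge[s, 2L])))
  }
  sets
}

# Exact two-sided rank-sum p by full enumeration of all group assignments.
ranksum_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  sums <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- mean(sums)
  # two-sided: assignments at least as extreme (in |sum - mean|) as observed
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Hand-rolled k-group log-rank chi-squared with aggregated risk sets at each
# distinct event time (hypergeometric expectations and variances).
logrank_oracle_chi2 <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ni <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    di <- vapply(levels(group), function(g)
      sum(event == 1 & time == t & group == g), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        V[i, j] <- V[i, j] +
          d * (n - d) / (n - 1) *
          (ifelse(i == j, ni[i] / n, 0) - ni[i] * ni[j] / n^2)
      }
    }
  }
  z <- (O - E)[-1L]
  drop(t(z) %*% solve(V[-1L, -1L, drop = FALSE]) %*% z)
}

# Closed-form upper-tail hypergeometric probability via exact binomial
# coefficients: P(overlap >= k) for a set of size m, group of size g, in a
# universe of size N.
hyper_tail_oracle <- function(k, m, g, N) {
  ks <- k:min(m, g)
  ks <- ks[ks >= max(0, g - (N - m))]
  if (length(ks) == 0L) return(0)
  sum(choose(m, ks) * choose(N - m, g - ks)) / choose(N, g)
}

# Fine-grid numeric integral of the piecewise-linear dose-response curve on
# the log10 dose axis (independent route to the observed-point trapezoid).
finegrid_auc <- function(doses, viability_mean, n_grid = 200001L) {
  lx <- log10(doses)
  f <- stats::approxfun(lx, viability_mean)
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  vals <- f(grid)
  sum((vals[-1L] + vals[-n_grid]) / 2 * diff(grid))
}
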