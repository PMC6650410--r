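# Independent oracles used across the suite.  These deliberately use
# brute force / exhaustive enumeration and share no code with the
# implementation paths they check.

# All-pairs single-linkage clustering under the tolerance predicate:
# connected components of the graph whose edges are observation pairs
# within both tolerances.  O(n^2), fine for the small instances it is
# used on.
oracle_cluster <- function(mass, time, run_span, params) {
  n <- length(mass)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ms <- min(mass[i], mass[j])
    ppm <- if (ms < params$interp_bounds_kda[1] * 1000) params$ppm_low
      else if (ms > params$interp_bounds_kda[2] * 1000) params$ppm_high
      else params$ppm_low + (params$ppm_high - params$ppm_low) *
        (ms - params$interp_bounds_kda[1] * 1000) /
        (diff(params$interp_bounds_kda) * 1000)
    tol_m <- ppm * 1e-6 * ms
    tm <- (time[i] + time[j]) / 2
    fr <- min(1, max(0, (tm - run_span[1]) / diff(run_span)))
    tol_t <- params$mig_tol_min_low +
      fr * (params$mig_tol_min_high - params$mig_tol_min_low)
    if (abs(mass[i] - mass[j]) <= tol_m && abs(time[i] - time[j]) <= tol_t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# canonical form of a set partition given as a labeling
canonical_partition <- function(labels) {
  groups <- split(seq_along(labels), labels)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, integer(1), 1))])
}

# Exact two-sided rank-sum p by full enumeration of all C(n, n1)
# group-a assignments (doubled smaller tail, capped at 1).
oracle_exact_wilcoxon_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(x), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Exhaustive-permutation Westfall-Young maxT: enumerates every group-a
# assignment, no Monte-Carlo, no smoothing.  Tie-corrected |Z| computed
# from first principles per assignment.
oracle_exact_maxt <- function(X, n1) {
  m <- nrow(X); n <- ncol(X)
  zfun <- function(row, idx) {
    r <- rank(row)
    W <- sum(r[idx])
    E <- n1 * (n + 1) / 2
    tie <- table(row)
    V <- n1 * (n - n1) / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (V <= 0) 0 else abs(W - E) / sqrt(V)
  }
  sets <- utils::combn(n, n1)
  Zall <- apply(sets, 2, function(idx)
    vapply(seq_len(m), function(i) zfun(X[i, ], idx), numeric(1)))
  Zall <- matrix(Zall, nrow = m)
  z_obs <- Zall[, 1]                      # identity assignment is column 1
  ord <- order(-z_obs)
  B <- ncol(Zall)
  q <- matrix(0, m, B)
  run <- rep(-Inf, B)
  for (i in m:1) { run <- pmax(run, Zall[ord[i], ]); q[i, ] <- run }
  p <- vapply(seq_len(m), function(i) mean(q[i, ] >= z_obs[ord[i]] - 1e-12),
              numeric(1))
  p <- cummax(p)
  out <- numeric(m)
  out[ord] <- p
  out
}
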