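# Independent oracles used to validate the statistical machinery.

# Exact two-sided Mann-Whitney p-value by enumeration of all rank
# assignments (tie-free inputs), using the 2*min(lower, upper) convention.
enum_two_sample_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  all_ranks <- seq_len(n + m)
  us <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (tie-free, non-zero differences).
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(1, p)
}

# Distribution of the rank-sum count via dynamic programming: number of
# n-subsets of {1..n+m} with each possible rank sum (exact U distribution
# without enumeration, usable at n = m = 25).
rank_sum_counts <- function(n, m) {
  total <- n + m
  max_sum <- sum((m + 1):total)
  cnt <- matrix(0, n + 1, max_sum + 1)  # cnt[k+1, s+1]
  cnt[1, 1] <- 1
  for (v in seq_len(total)) {
    for (k in min(n, v):1) {
      nonzero <- which(cnt[k, ] > 0)
      for (s in rev(nonzero)) {
        cnt[k + 1, s + v] <- cnt[k + 1, s + v] + cnt[k, s]
      }
    }
  }
  cnt[n + 1, ]  # index s+1 = count of subsets with rank sum s
}

# Exact two-sided p for the largest possible U (all x above all y) at n = m.
exact_p_max_u <- function(n, m) {
  min(1, 2 / choose(n + m, n))
}

# Brute-force maximum-margin separator: enumerate candidate support-vector
# subsets, solve the equality-constrained KKT system, keep feasible
# solutions, and return the minimum-norm (maximum-margin) one.
qp_max_margin <- function(X, y01) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  best <- NULL
  for (size in 2:min(n, ncol(X) + 1)) {
    for (subset in utils::combn(n, size, simplify = FALSE)) {
      S <- X[subset, , drop = FALSE]
      ys <- y[subset]
      # w = sum lambda_i y_i x_i; constraints y_j (w.x_j + b) = 1 for j in S
      K <- S %*% t(S)
      A <- rbind(cbind(K * outer(ys, ys), ys), c(ys, 0))
      rhs <- c(rep(1, size), 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      lambda <- sol[seq_len(size)]
      b <- sol[size + 1]
      if (any(lambda < -1e-9)) next
      w <- drop(t(S) %*% (lambda * ys))
      margins <- y * (drop(X %*% w) + b)
      if (all(margins >= 1 - 1e-7)) {
        nrm <- sum(w^2)
        if (is.null(best) || nrm < best$norm - 1e-12) {
          best <- list(w = w, b = b, norm = nrm)
        }
      }
    }
  }
  best
}

# Primal objective of the soft-margin linear SVM, for optimality comparisons.
svc_primal_objective <- function(w, b, X, y01, cost = 1) {
  y <- ifelse(y01 == 1, 1, -1)
  0.5 * sum(w^2) + cost * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
}
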