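# Shared fixtures and independent oracles used across test files.

# Quick burst_stats row(s) without trial data.
make_stats <- function(label, X, Y, sX, sY, rho = 0, n = 30L) {
  out <- data.frame(label = label, X = X, Y = Y, sX = sX, sY = sY,
                    rho = rho, n = n, stringsAsFactors = FALSE)
  class(out) <- c("burst_stats", "data.frame")
  out
}

# Brute-force adjacency criterion: enumerate all 16 sign combinations of the
# two SD vertex vectors projected on the unit inter-centroid axis.
brute_force_q <- function(a, b) {
  d <- c(a$X - b$X, a$Y - b$Y)
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(Inf)
  dh <- d / nd
  best <- -Inf
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) for (s4 in c(-1, 1)) {
    val <- sum(c(s1 * a$sX, s2 * a$sY) * dh) + sum(c(s3 * b$sX, s4 * b$sY) * dh) - nd
    if (val > best) best <- val
  }
  best
}

random_stats_pair <- function() {
  list(
    a = list(X = stats::runif(1, -0.5, 1), Y = stats::runif(1, -0.5, 1.5),
             sX = stats::runif(1, 0, 0.2), sY = stats::runif(1, 0, 0.2)),
    b = list(X = stats::runif(1, -0.5, 1), Y = stats::runif(1, -0.5, 1.5),
             sX = stats::runif(1, 0, 0.2), sY = stats::runif(1, 0, 0.2))
  )
}

# Graph-traversal connected components (breadth-first), independent of the
# union-find implementation under test.
bfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which((adj[v, ] | adj[, v]) & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  names(comp) <- rownames(adj)
  comp
}

# Hand-coded Welch two-sample t (oracle for pairwise_t).
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Hand-coded one-way fixed-effects ANOVA from sums of squares.
anova_oracle <- function(groups) {
  x <- unlist(groups)
  k <- length(groups)
  N <- length(x)
  between <- sum(vapply(groups, function(g) length(g) * (mean(g) - mean(x))^2, numeric(1)))
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (between / (k - 1)) / (within / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}
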