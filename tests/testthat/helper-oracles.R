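# Brute-force oracles, written independently of the package internals (and
# of igraph): plain-R BFS, path counting, and fixed-point iteration. Used to
# freeze expected values for the graph and equilibrium machinery.

# BFS shortest-path lengths from every source on a 0/1 adjacency matrix.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(A[v, ] > 0)) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Mean local clustering: neighbor-pair counting, degree < 2 contributes 0.
oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (u in nb) for (v in nb) if (u < v && A[u, v] > 0) links <- links + 1
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

# Characteristic path length over reachable ordered pairs.
oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_global_efficiency <- function(A) {
  D <- oracle_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(A)
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# Shortest-path counts from source s by dynamic programming over BFS layers.
oracle_sigma_from <- function(A, s, D) {
  n <- nrow(A)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(D[s, ])
  for (v in ord) {
    if (v == s || !is.finite(D[s, v])) next
    pred <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

# Pair-normalized betweenness via sigma(s,v) * sigma(v,t) / sigma(s,t).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- t(vapply(seq_len(n), function(s) oracle_sigma_from(A, s, D),
                    numeric(n)))
  b <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t <= s || t == v) next
        if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
        if (D[s, v] + D[v, t] == D[s, t])
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    b[v] <- acc / ((n - 1) * (n - 2) / 2)
  }
  b
}

# Two-sided Fisher p by direct enumeration with log-binomial arithmetic.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Free testosterone by fixed-point iteration on the mass balance:
# TT = FT * (1 + ka*Alb) + kt * FT * SHBG / (1 + kt * FT).
oracle_free_t <- function(tt_nmol, shbg_nmol, kt = 1e9, ka = 3.6e4,
                          albumin = 43, mw = 66500) {
  tt <- tt_nmol * 1e-9; sh <- shbg_nmol * 1e-9
  N <- 1 + ka * albumin / mw
  ft <- 0
  for (i in 1:200) {
    ft_new <- tt / (N + kt * sh / (1 + kt * ft))
    if (abs(ft_new - ft) < 1e-18) break
    ft <- ft_new
  }
  ft * 1e9
}

# Piecewise-linear integral by fine midpoint sum (independent of the
# trapezoid implementation under test).
oracle_auc <- function(values, grid, m = 20000) {
  f <- stats::approxfun(grid, values)
  x <- seq(min(grid), max(grid), length.out = m + 1)
  mid <- (x[-1] + x[-length(x)]) / 2
  100 * sum(f(mid) * diff(x))
}

# Erdos-Renyi style random 0/1 adjacency matrix (connected not enforced).
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A + t(A)
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Small cohort config used across tests (cheap but non-degenerate).
tiny_config <- function(seed = 11, ...) {
  cohort_config(n_patients = 12, n_controls = 10, seed = seed, ...)
}
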