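# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: plain double loops and
# exhaustive enumeration only.

# Direct double-loop evaluation of the shifted cross-correlation
# C(k) = (1/n_k) * sum_t si(t) sj(t+k) on globally standardized inputs.
oracle_ccf <- function(s_i, s_j, tr, tau_max) {
  std <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  si <- std(s_i); sj <- std(s_j)
  T_ <- length(si)
  k_max <- floor(tau_max / tr + 1e-9)
  shifts <- (-k_max):k_max
  vals <- numeric(length(shifts))
  for (s in seq_along(shifts)) {
    k <- shifts[s]
    acc <- 0; n <- 0
    for (t in seq_len(T_)) {
      if (t + k >= 1 && t + k <= T_) {
        acc <- acc + si[t] * sj[t + k]
        n <- n + 1
      }
    }
    vals[s] <- acc / n
  }
  list(shifts_seconds = shifts * tr, values = vals)
}

# Exhaustive simple-path search for shortest path lengths. Positive edge
# lengths allow pruning paths already no shorter than the incumbent without
# missing any optimum.
oracle_shortest_paths <- function(L) {
  n <- nrow(L)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  adj <- lapply(seq_len(n), function(u)
    which(is.finite(L[u, ]) & seq_len(n) != u))
  for (s in seq_len(n)) {
    visited <- logical(n)
    walk <- function(u, len) {
      if (len < best[s, u]) best[s, u] <<- len
      for (v in adj[[u]]) {
        # positive lengths: extending a path that is already >= the
        # incumbent for v cannot produce a shorter simple path through v
        if (!visited[v] && len + L[u, v] < best[s, v]) {
          visited[v] <<- TRUE
          walk(v, len + L[u, v])
          visited[v] <<- FALSE
        }
      }
    }
    visited[s] <- TRUE
    walk(s, 0)
  }
  best
}

# Step-by-step greedy navigation walk for one ordered pair, choosing at
# each step the neighbour of the current node closest (Euclidean) to the
# target; lower index wins ties; fails on revisit or dead end.
oracle_navigate_pair <- function(L, coords, i, j) {
  n <- nrow(L)
  euc <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))
  cur <- i
  visited <- i
  lam <- 0; dd <- 0; hops <- 0
  repeat {
    nbrs <- which(is.finite(L[cur, ]) & seq_len(n) != cur)
    if (length(nbrs) == 0) return(list(lambda = Inf, d = Inf, hops = Inf))
    dists <- vapply(nbrs, euc, numeric(1), b = j)
    nxt <- nbrs[order(dists, nbrs)][1]
    if (nxt %in% visited) return(list(lambda = Inf, d = Inf, hops = Inf))
    lam <- lam + L[cur, nxt]
    dd <- dd + euc(cur, nxt)
    hops <- hops + 1
    cur <- nxt
    visited <- c(visited, cur)
    if (cur == j) return(list(lambda = lam, d = dd, hops = hops))
  }
}

# Benjamini-Hochberg step-up computed from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Random spatially embedded weighted graph for routing oracles.
random_length_graph <- function(n, p_edge = 0.6) {
  coords <- matrix(runif(3 * n, 0, 100), ncol = 3)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- sample(1:20, sum(ut), replace = TRUE) * (runif(sum(ut)) < p_edge)
  w[ut] <- vals
  w <- w + t(w)
  if (max(w) == 0) w[1, 2] <- w[2, 1] <- 5
  list(conn = connectome(w, coords), L = weight_to_length(connectome(w, coords)))
}

# Small cohort used by several suites; generated once per test run.
small_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- gen_cohort(cohort_config(n_stroke = 4, n_control = 4,
                                         n_pairs = 10, n_timepoints = 160,
                                         seed = 42))
    }
    value
  }
})
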