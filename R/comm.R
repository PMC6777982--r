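#' Euclidean distance matrix of node coordinates
#'
#' @param coords N x 3 matrix of coordinates in mm.
#' @return symmetric N x N matrix of straight-line distances, zero diagonal.
#' @export
euclidean_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop_invalid("coords must be finite")
  as.matrix(stats::dist(coords))
}

#' Proportional density thresholding
#'
#' Retains the `ceiling(density * N * (N - 1) / 2)` largest-weight
#' undirected edges of a connectome; ties at the cut-off are broken toward
#' the smaller `(i, j)` pair in lexicographic order, so nested densities
#' yield nested edge sets. If the graph has fewer edges than requested, all
#' are kept.
#'
#' @param conn a [connectome()].
#' @param density fraction of possible undirected edges in `(0, 1]`.
#' @return the thresholded [connectome()].
#' @export
threshold_density <- function(conn, density) {
  stopifnot(inherits(conn, "connectome"))
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    stop_invalid("`density` must lie in (0, 1]")
  }
  w <- conn$weights
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  pos <- wt > 0
  idx <- idx[pos, , drop = FALSE]
  wt <- wt[pos]
  k <- min(ceiling(density * n * (n - 1) / 2), length(wt))
  ord <- order(-wt, idx[, 1], idx[, 2])
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n)
  out[idx[keep, , drop = FALSE]] <- wt[keep]
  out <- out + t(out)
  connectome(out, conn$coords, conn$region_ids)
}

#' Remap connection weights into connection lengths
#'
#' Converts a streamline-count matrix \eqn{W} into a length matrix
#' \deqn{L_{ij} = -\log_{10}\!\frac{W_{ij}}{\max(W) + 1},}
#' a monotonically decreasing remapping that is strictly positive on every
#' edge; absent edges become `Inf` and the diagonal 0. `form = "printed"`
#' exposes the variant \eqn{-\log_{10}(W/\max(W) + 1)} for auditability;
#' note that variant yields non-positive lengths and is not used anywhere in
#' the pipeline.
#'
#' @param conn a [connectome()] or a plain weight matrix.
#' @param form `"standard"` (default) or `"printed"`.
#' @return N x N length matrix.
#' @export
weight_to_length <- function(conn, form = c("standard", "printed")) {
  form <- match.arg(form)
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  mx <- max(w)
  if (mx <= 0) stop_invalid("connectome has no positive weight")
  L <- matrix(Inf, nrow(w), ncol(w))
  edge <- w > 0
  L[edge] <- if (form == "standard") {
    -log10(w[edge] / (mx + 1))
  } else {
    -log10(w[edge] / mx + 1)
  }
  diag(L) <- 0
  dimnames(L) <- dimnames(w)
  L
}

#' Shortest-path length matrix
#'
#' Globally minimal sums of connection lengths between all node pairs
#' (Dijkstra via igraph); `Inf` between disconnected components.
#'
#' @param L length matrix from [weight_to_length()] (`Inf` = no edge).
#' @return N x N matrix of shortest-path lengths.
#' @export
shortest_paths <- function(L) {
  L <- as.matrix(L)
  adj <- L
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(L)
  d
}

#' Greedy spatial navigation routing
#'
#' Routes every ordered node pair `(i, j)` by repeatedly moving to the
#' current node's neighbour that is closest in Euclidean distance to the
#' target `j` (ties broken toward the lower node index). Navigation succeeds
#' when `j` is reached; it fails -- all three outputs `Inf` -- when a node
#' is revisited or the current node has no neighbours.
#'
#' @param L length matrix (`Inf` = no edge, 0 diagonal).
#' @param coords N x 3 node coordinates in mm.
#' @return list with N x N matrices `lambda_nav` (summed connection
#'   lengths), `d_nav` (summed Euclidean hop distances), `hops_nav`
#'   (path length in edges); zero diagonals.
#' @export
navigate <- function(L, coords) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (nrow(coords) != n) stop_invalid("coords not aligned with length matrix")
  d <- euclidean_matrix(coords)

  # next_hop[u, j]: the neighbour of u closest to target j (NA if u has no
  # neighbours). Greedy progression depends only on (current, target), so
  # the hop table is precomputed once.
  next_hop <- matrix(NA_integer_, n, n)
  for (u in seq_len(n)) {
    nb <- which(is.finite(L[u, ]) & seq_len(n) != u)
    if (length(nb) == 0L) next
    sub <- d[nb, , drop = FALSE]                     # |nb| x n
    next_hop[u, ] <- nb[max.col(-t(sub), ties.method = "first")]
  }

  lambda <- matrix(Inf, n, n)
  dnav <- matrix(Inf, n, n)
  hops <- matrix(Inf, n, n)
  diag(lambda) <- diag(dnav) <- diag(hops) <- 0

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cur <- i
      visited <- logical(n)
      visited[i] <- TRUE
      lam <- 0; dd <- 0; h <- 0L
      repeat {
        nxt <- next_hop[cur, j]
        if (is.na(nxt) || visited[nxt]) break  # dead end or revisit: fail
        lam <- lam + L[cur, nxt]
        dd <- dd + d[cur, nxt]
        h <- h + 1L
        cur <- nxt
        if (cur == j) {
          lambda[i, j] <- lam
          dnav[i, j] <- dd
          hops[i, j] <- h
          break
        }
        visited[cur] <- TRUE
      }
    }
  }
  dimnames(lambda) <- dimnames(dnav) <- dimnames(hops) <- dimnames(L)
  list(lambda_nav = lambda, d_nav = dnav, hops_nav = hops)
}

#' Communication efficiency of a path-length matrix
#'
#' Mean inverse path length over ordered node pairs,
#' \deqn{E = \frac{\sum_{i \ne j} \Lambda_{ij}^{-1}}{N (N - 1)},}
#' with failed or disconnected pairs contributing zero (\eqn{1/\infty = 0}).
#'
#' @param path_lengths N x N matrix (`Inf` allowed).
#' @return scalar efficiency.
#' @export
efficiency <- function(path_lengths) {
  m <- as.matrix(path_lengths)
  n <- nrow(m)
  if (n < 2) stop_invalid("need at least 2 nodes")
  off <- m[row(m) != col(m)]
  inv <- ifelse(is.finite(off), 1 / off, 0)
  sum(inv) / (n * (n - 1))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Communication profile across a density grid
#'
#' For each connection density, thresholds the raw weighted connectome,
#' remaps weights to lengths, routes under both schemes (shortest paths and
#' navigation), and records whole-brain efficiencies; these are summarized
#' by the trapezoidal area under the curve (AUC) over the grid. When
#' homotopic `pairs` are supplied, per-pair efficiencies (mean of the two
#' routing directions, \eqn{1/\infty = 0}) and navigation distances (mean
#' over densities of successful navigations, both directions) are also
#' returned.
#'
#' @param conn a [connectome()] (raw streamline counts).
#' @param densities increasing density grid, default `seq(0.10, 0.50, 0.05)`.
#' @param pairs optional two-column matrix of region ids
#'   `(left, right)` per homotopic pair.
#' @return list of class `comm_profile`: `per_density` (`density`, `e_sp`,
#'   `e_nav`), `auc_e_sp`, `auc_e_nav`, and (with `pairs`) `pair`
#'   (`pair_id`, `auc_nav_eff`, `auc_sp_eff`, `mean_dnav`).
#' @export
comm_profile <- function(conn, densities = seq(0.10, 0.50, by = 0.05),
                         pairs = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (length(densities) < 2 || any(diff(densities) <= 0)) {
    stop_invalid("`densities` must be a strictly increasing grid (>= 2 points)")
  }
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    li <- match(pairs[, 1], conn$region_ids)
    ri <- match(pairs[, 2], conn$region_ids)
    if (any(is.na(li)) || any(is.na(ri))) {
      stop_invalid("pair region ids not found in connectome")
    }
  }

  nd <- length(densities)
  e_sp <- e_nav <- numeric(nd)
  if (!is.null(pairs)) {
    np <- nrow(pairs)
    p_nav <- p_sp <- p_dnav <- matrix(NA_real_, nd, np)
  }

  for (k in seq_len(nd)) {
    thr <- threshold_density(conn, densities[k])
    L <- weight_to_length(thr)
    sp <- shortest_paths(L)
    nav <- navigate(L, thr$coords)
    e_sp[k] <- efficiency(sp)
    e_nav[k] <- efficiency(nav$lambda_nav)
    if (!is.null(pairs)) {
      inv <- function(x) ifelse(is.finite(x), 1 / x, 0)
      for (p in seq_len(np)) {
        i <- li[p]; j <- ri[p]
        p_nav[k, p] <- (inv(nav$lambda_nav[i, j]) + inv(nav$lambda_nav[j, i])) / 2
        p_sp[k, p] <- inv(sp[i, j])
        dns <- c(nav$d_nav[i, j], nav$d_nav[j, i])
        dns <- dns[is.finite(dns)]
        p_dnav[k, p] <- if (length(dns)) mean(dns) else NA_real_
      }
    }
  }

  out <- list(
    per_density = data.frame(density = densities, e_sp = e_sp, e_nav = e_nav),
    auc_e_sp = trapz(densities, e_sp),
    auc_e_nav = trapz(densities, e_nav)
  )
  if (!is.null(pairs)) {
    out$pair <- data.frame(
      pair_id = seq_len(np),
      auc_nav_eff = vapply(seq_len(np), function(p) trapz(densities, p_nav[, p]), numeric(1)),
      auc_sp_eff = vapply(seq_len(np), function(p) trapz(densities, p_sp[, p]), numeric(1)),
      mean_dnav = colMeans(p_dnav, na.rm = TRUE)
    )
    out$pair$mean_dnav[is.nan(out$pair$mean_dnav)] <- NA_real_
  }
  structure(out, class = "comm_profile")
}

#' @export
print.comm_profile <- function(x, ...) {
  cat(sprintf("<comm_profile> %d densities; AUC e_sp = %.4f, AUC e_nav = %.4f\n",
              nrow(x$per_density), x$auc_e_sp, x$auc_e_nav))
  invisible(x)
}

#' Area under the efficiency curve over a density grid
#'
#' @param conn a [connectome()].
#' @param densities increasing density grid, default `seq(0.10, 0.50, 0.05)`.
#' @param measure `"e_nav"` or `"e_sp"`.
#' @return scalar trapezoidal AUC.
#' @export
auc_over_densities <- function(conn, densities = seq(0.10, 0.50, by = 0.05),
                               measure = c("e_nav", "e_sp")) {
  measure <- match.arg(measure)
  prof <- comm_profile(conn, densities)
  if (measure == "e_nav") prof$auc_e_nav else prof$auc_e_sp
}

#' Region-to-lesion Euclidean distance per homotopic pair
#'
#' For every homotopic pair, the distance from the centre of mass of the
#' pair's *ipsilesional* region (the region in the lesioned hemisphere) to
#' the nearest lesion centroid. Contralesional coordinates are never used.
#'
#' @param regions region table.
#' @param centroids lesion centroid(s): length-3 vector or k x 3 matrix.
#' @param side lesion hemisphere, `"left"` or `"right"`.
#' @return `data.frame` with `pair_id`, `distance_mm`.
#' @export
region_to_lesion_distance <- function(regions, centroids, side) {
  check_regions(regions)
  if (is.null(centroids) || length(centroids) == 0) {
    stop_invalid("subject has no lesion centroid")
  }
  centroids <- matrix(as.numeric(centroids), ncol = 3)
  if (any(!is.finite(centroids))) stop_invalid("lesion centroid must be finite")
  if (!side %in% c("left", "right")) {
    stop_invalid("`side` must be \"left\" or \"right\"")
  }
  ipsi <- regions[regions$hemisphere == side, ]
  ipsi <- ipsi[order(ipsi$pair_id), ]
  cc <- region_coords(ipsi)
  dist_mm <- vapply(seq_len(nrow(cc)), function(r) {
    min(sqrt(rowSums((centroids - matrix(cc[r, ], nrow(centroids), 3,
                                         byrow = TRUE))^2)))
  }, numeric(1))
  data.frame(pair_id = ipsi$pair_id, distance_mm = dist_mm)
}
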