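#' Signed similarity graph of a chart
#'
#' Builds the weighted graph underlying the well-formedness criterion: the
#' edge between chips u and v carries weight `sim(u, v) - 1/2`, positive
#' for similar pairs and negative for dissimilar ones. The diagonal is 0.
#'
#' @param chart a [chip_chart()].
#' @param params a [similarity_params()].
#' @return symmetric n x n numeric matrix of signed edge weights.
#' @export
build_similarity_graph <- function(chart, params = similarity_params()) {
  w <- similarity_matrix(chart, params) - 0.5
  diag(w) <- 0
  w
}

check_weight_matrix <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-9)
    stop("weights must be symmetric")
  if (any(diag(weights) != 0))
    stop("weights must have a zero diagonal")
  invisible(weights)
}

#' Maximizing-agreements objective of a clustering
#'
#' Sum of edge weights over unordered intra-cluster pairs.
#'
#' @param weights symmetric signed weight matrix with zero diagonal.
#' @param labels cluster label per node.
#' @return the objective value.
#' @export
cc_objective <- function(weights, labels) {
  check_weight_matrix(weights)
  stopifnot(length(labels) == nrow(weights))
  same <- outer(labels, labels, "==")
  sum(weights[same]) / 2
}

# Greedy best-move local search on a membership vector. Maintains
# S[v, k] = total weight from v into cluster k so each sweep is O(n*K).
# Only strictly improving moves are taken, so starting from all singletons
# a zero-weight graph stays all singletons (deterministic tie policy).
cc_local_search_once <- function(weights, init, max_clusters = NULL,
                                 tol = 1e-10, max_moves = NULL) {
  n <- nrow(weights)
  memb <- match(init, unique(init))       # compact 1..K
  K <- max(memb)
  ind <- matrix(0, n, K)
  ind[cbind(seq_len(n), memb)] <- 1
  S <- weights %*% ind
  sizes <- tabulate(memb, K)
  if (is.null(max_moves)) max_moves <- 200L * n
  no_cap <- is.null(max_clusters)

  for (iter in seq_len(max_moves)) {
    cur <- S[cbind(seq_len(n), memb)]
    delta <- S - cur                       # move v into existing cluster k
    delta[cbind(seq_len(n), memb)] <- 0
    # moving v out of a cluster of size 1 into "its own new cluster" is a
    # no-op; for size > 1 a new singleton cluster has gain -cur[v]
    new_gain <- ifelse(sizes[memb] > 1L, -cur, -Inf)
    if (!no_cap && K >= max_clusters) new_gain[] <- -Inf

    best_existing <- max(delta)
    best_new <- max(new_gain)
    if (max(best_existing, best_new) <= tol) break

    if (best_existing >= best_new) {
      # column-major which.max: ties resolved toward the lowest node id,
      # then the lowest-indexed cluster
      idx <- which(delta == best_existing, arr.ind = TRUE)[1L, ]
      v <- idx[[1L]]; target <- idx[[2L]]
    } else {
      v <- which.max(new_gain)
      # append a new, still-empty cluster; the move update below fills it
      K <- K + 1L
      S <- cbind(S, 0)
      sizes <- c(sizes, 0L)
      target <- K
    }
    src <- memb[v]
    memb[v] <- target
    S[, src] <- S[, src] - weights[, v]
    S[, target] <- S[, target] + weights[, v]
    sizes[src] <- sizes[src] - 1L
    sizes[target] <- sizes[target] + 1L
    if (sizes[src] == 0L) {               # drop the emptied cluster
      keep <- setdiff(seq_len(K), src)
      S <- S[, keep, drop = FALSE]
      sizes <- sizes[keep]
      memb <- match(memb, keep)
      K <- K - 1L
    }
  }
  list(labels = memb, objective = sum(S[cbind(seq_len(n), memb)]) / 2)
}

#' Correlation clustering by seeded local search
#'
#' Maximizing-agreements correlation clustering: find a partition of the
#' nodes maximizing the total signed weight on intra-cluster edges. The
#' problem is NP-hard; this solver runs a greedy best-move local search
#' (repeatedly move the single node whose reassignment — possibly to a new
#' cluster — most increases the objective) to a local optimum, and keeps
#' the best local optimum over `restarts` seeded starting points. The first
#' start is deterministic (all singletons, or a balanced `max_clusters`-way
#' split when a cap is given); the rest are random assignments.
#'
#' Only local optimality is guaranteed; on small instances the solution can
#' be checked against the exact [cc_brute_force()] oracle.
#'
#' @param weights symmetric signed weight matrix (zero diagonal), e.g. from
#'   [build_similarity_graph()].
#' @param restarts number of local-search starts (>= 1).
#' @param max_clusters optional cap: moves that would raise the cluster
#'   count above this are forbidden, and random starts respect it.
#' @param chart_name chart identity recorded on the returned partition.
#' @return a [color_partition()] with attribute `objective` (also exposed
#'   in the returned list element `objective`).
#' @export
cc_local_search <- function(weights, restarts = 20L, max_clusters = NULL,
                            chart_name = "graph") {
  check_weight_matrix(weights)
  restarts <- as.integer(restarts)
  if (is.na(restarts) || restarts < 1L) stop("restarts must be >= 1")
  n <- nrow(weights)
  if (!is.null(max_clusters)) {
    max_clusters <- as.integer(max_clusters)
    if (is.na(max_clusters) || max_clusters < 1L)
      stop("max_clusters must be a positive integer")
    max_clusters <- min(max_clusters, n)
  }
  kcap <- if (is.null(max_clusters)) n else max_clusters
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) {
      if (is.null(max_clusters)) seq_len(n)
      else ((seq_len(n) - 1L) %% max_clusters) + 1L
    } else {
      k0 <- sample.int(min(kcap, max(2L, min(n, 20L))), 1L)
      sample.int(k0, n, replace = TRUE)
    }
    res <- cc_local_search_once(weights, init, max_clusters)
    if (is.null(best) || res$objective > best$objective + 1e-12) best <- res
  }
  p <- color_partition(best$labels, chart_name)
  attr(p, "objective") <- best$objective
  p
}

#' Exact correlation clustering by exhaustive enumeration
#'
#' Enumerates all set partitions of the nodes (restricted-growth order) and
#' returns the one maximizing the agreements objective. Intended as an
#' oracle for small instances; refuses n > 12 (Bell numbers explode).
#'
#' @inheritParams cc_local_search
#' @return list with elements `partition` (a [color_partition()]) and
#'   `objective` (the exact optimum).
#' @export
cc_brute_force <- function(weights, chart_name = "graph") {
  check_weight_matrix(weights)
  n <- nrow(weights)
  if (n > 12L)
    stop("cc_brute_force is limited to n <= 12 nodes")
  best_obj <- -Inf
  best_lab <- rep(1L, n)
  labels <- integer(n)
  recurse <- function(i, kmax, obj) {
    if (i > n) {
      if (obj > best_obj) {
        best_obj <<- obj
        best_lab <<- labels[seq_len(n)]
      }
      return(invisible())
    }
    for (c in seq_len(kmax + 1L)) {
      labels[i] <<- c
      gain <- if (i > 1L) {
        prev <- seq_len(i - 1L)
        sum(weights[i, prev][labels[prev] == c])
      } else 0
      recurse(i + 1L, max(kmax, c), obj + gain)
    }
  }
  recurse(1L, 0L, 0)
  list(partition = color_partition(best_lab, chart_name),
       objective = best_obj)
}

#' Consensus partition of many partitions
#'
#' Aggregates a collection of partitions of the same chart into a single
#' consensus map: each input partition casts a similarity judgment for a
#' chip pair it co-assigns and a dissimilarity judgment otherwise, giving
#' the signed weight `(co-assignment frequency) - 1/2`; the consensus is
#' the correlation clustering of that graph. For a single input partition
#' the weights are +1/2 / -1/2 and the consensus recovers it exactly.
#'
#' @param partitions list of [color_partition()]s on the same chart.
#' @param restarts local-search restarts passed to [cc_local_search()].
#' @param max_clusters optional cluster-count cap.
#' @return a [color_partition()] with an `objective` attribute.
#' @export
consensus_partition <- function(partitions, restarts = 20L,
                                max_clusters = NULL) {
  if (!is.list(partitions) || length(partitions) == 0L ||
      !all(vapply(partitions, inherits, logical(1L), "color_partition")))
    stop("partitions must be a non-empty list of color_partition objects")
  ns <- vapply(partitions, function(p) p$n, integer(1L))
  charts <- vapply(partitions, function(p) p$chart_name, character(1L))
  if (length(unique(ns)) != 1L || length(unique(charts)) != 1L)
    stop("all partitions must be on the same chart")
  n <- ns[[1L]]
  co <- matrix(0, n, n)
  for (p in partitions)
    co <- co + outer(p$labels, p$labels, "==")
  w <- co / length(partitions) - 0.5
  diag(w) <- 0
  cc_local_search(w, restarts = restarts, max_clusters = max_clusters,
                  chart_name = charts[[1L]])
}
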