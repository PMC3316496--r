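#' Weighted miRNA correlation network
#'
#' Container for the undirected, significance-filtered Spearman correlation
#' network over a signature: nodes are features, edges carry the Spearman
#' coefficient `rho` (the weight), its p-value and its sign. Centrality and
#' distance computations use `|rho|` as the edge weight (`raw_abs`, default)
#' or `1/|rho|` (`inverse_abs`); path lengths are always sums of *inverse*
#' weights, so strongly correlated nodes are close.
#'
#' @param nodes Character vector of node ids (isolated nodes allowed).
#' @param edges Data frame with columns `from`, `to`, `rho` and optionally
#'   `p_value`.
#' @param weight_mode `"raw_abs"` or `"inverse_abs"`.
#' @return A `mir_network` object.
#' @export
mir_network <- function(nodes, edges = NULL,
                        weight_mode = c("raw_abs", "inverse_abs")) {
  weight_mode <- match.arg(weight_mode)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node ids")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(
      from = character(), to = character(),
      rho = numeric(), p_value = numeric(), sign = character()
    )
  } else {
    edges <- as.data.frame(edges)
    stopifnot(all(c("from", "to", "rho") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      stop("edge endpoint not among the nodes")
    }
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(edges$rho == 0) || any(abs(edges$rho) > 1)) {
      stop("edge weights must lie in [-1, 1] excluding 0")
    }
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("at most one edge per node pair")
    if (is.null(edges$p_value)) edges$p_value <- NA_real_
    edges$sign <- ifelse(edges$rho > 0, "+", "-")
    edges <- edges[, c("from", "to", "rho", "p_value", "sign")]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, weight_mode = weight_mode),
    class = "mir_network"
  )
}

#' @export
print.mir_network <- function(x, ...) {
  cat(sprintf(
    "mir_network: %d nodes, %d edges (weight mode %s)\n",
    length(x$nodes), nrow(x$edges), x$weight_mode
  ))
  invisible(x)
}

# symmetric weight matrix (0 = no edge) under the network's weight mode
weight_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    w <- switch(net$weight_mode,
      raw_abs = abs(net$edges$rho),
      inverse_abs = 1 / abs(net$edges$rho)
    )
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    W[cbind(i, j)] <- w
    W[cbind(j, i)] <- w
  }
  W
}

node_index <- function(net, v) {
  i <- match(v, net$nodes)
  if (is.na(i)) stop("unknown node: ", v)
  i
}

# Dijkstra with shortest-path counting; edge length = 1 / weight.
# Ties in path length are resolved at relative tolerance `tol`.
dijkstra_count <- function(L, s, tol = 1e-9) {
  n <- nrow(L)
  d <- rep(Inf, n)
  sigma <- numeric(n)
  d[s] <- 0
  sigma[s] <- 1
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(d))
    if (length(cand) == 0) break
    u <- cand[which.min(d[cand])]
    visited[u] <- TRUE
    for (v in which(is.finite(L[u, ]))) {
      if (visited[v]) next
      nd <- d[u] + L[u, v]
      if (!is.finite(d[v]) || nd < d[v] - tol * max(1, d[v])) {
        d[v] <- nd
        sigma[v] <- sigma[u]
      } else if (abs(nd - d[v]) <= tol * max(1, d[v])) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  list(d = d, sigma = sigma)
}

# all-pairs distances and shortest-path counts
all_pairs_shortest <- function(net, tol = 1e-9) {
  W <- weight_matrix(net)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  n <- nrow(L)
  D <- matrix(Inf, n, n, dimnames = dimnames(W))
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (s in seq_len(n)) {
    r <- dijkstra_count(L, s, tol)
    D[s, ] <- r$d
    S[s, ] <- r$sigma
  }
  list(D = D, S = S, tol = tol)
}

#' Shortest-path distance and path count between two nodes
#'
#' The length of a path is the sum of the inverse weights of its edges;
#' the distance is the minimum length over connecting paths. All paths
#' attaining the minimum (at relative tolerance 1e-9) are counted.
#'
#' @param net A [mir_network()].
#' @param u,v Node ids.
#' @return List with `distance` (`Inf` if unreachable) and
#'   `n_shortest_paths` (0 if unreachable).
#' @export
path_distance <- function(net, u, v) {
  iu <- node_index(net, u)
  iv <- node_index(net, v)
  W <- weight_matrix(net)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  r <- dijkstra_count(L, iu)
  if (is.finite(r$d[iv])) {
    list(distance = r$d[iv], n_shortest_paths = r$sigma[iv])
  } else {
    list(distance = Inf, n_shortest_paths = 0)
  }
}

#' Weighted degree (strength) of nodes
#'
#' Sum of the incident edge weights: `sum |rho|` under `raw_abs`,
#' `sum 1/|rho|` under `inverse_abs`. Isolated nodes have degree 0.
#'
#' @param net A [mir_network()].
#' @param v A node id, or `NULL` for all nodes.
#' @return Named numeric vector (or scalar when `v` is given).
#' @export
weighted_degree <- function(net, v = NULL) {
  W <- weight_matrix(net)
  deg <- rowSums(W)
  if (is.null(v)) deg else unname(deg[node_index(net, v)])
}

#' Betweenness centrality on inverse-weight shortest paths
#'
#' Fraction of pairwise shortest paths that pass through the node:
#' `B(v) = sum_{s<t, s,t != v} sigma_st(v)/sigma_st / ((n-1)(n-2)/2)`,
#' with path lengths as in [path_distance()]. Unreachable pairs contribute
#' 0; networks with fewer than 3 nodes have betweenness 0 by convention.
#'
#' @inheritParams weighted_degree
#' @return Named numeric vector in `[0, 1]` (or scalar when `v` is given).
#' @export
betweenness <- function(net, v = NULL) {
  n <- length(net$nodes)
  out <- stats::setNames(numeric(n), net$nodes)
  if (n >= 3) {
    ap <- all_pairs_shortest(net)
    D <- ap$D
    S <- ap$S
    tol <- ap$tol
    norm <- (n - 1) * (n - 2) / 2
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    for (k in seq_len(n)) {
      acc <- 0
      for (p in seq_len(nrow(pairs))) {
        s <- pairs[p, 1]
        t <- pairs[p, 2]
        if (s == k || t == k || S[s, t] == 0) next
        dst <- D[s, t]
        if (!is.finite(D[s, k]) || !is.finite(D[k, t])) next
        if (abs(D[s, k] + D[k, t] - dst) <= tol * max(1, dst)) {
          acc <- acc + (S[s, k] * S[k, t]) / S[s, t]
        }
      }
      out[k] <- acc / norm
    }
  }
  if (is.null(v)) out else unname(out[node_index(net, v)])
}

#' Zhang-Horvath weighted clustering coefficient
#'
#' Triangle-density measure of a node's neighbourhood cohesion:
#' `c_w(v) = sum_{j != k} w_vj w_jk w_kv / ((sum_j w_vj)^2 - sum_j w_vj^2)`,
#' which with unit weights reduces to the unweighted local clustering
#' coefficient. Nodes with fewer than two neighbours (zero denominator)
#' score 0.
#'
#' @inheritParams weighted_degree
#' @return Named nonnegative numeric vector (or scalar when `v` is given).
#' @export
zhang_clustering <- function(net, v = NULL) {
  W <- weight_matrix(net)
  num <- diag(W %*% W %*% W)
  den <- rowSums(W)^2 - rowSums(W^2)
  cw <- ifelse(den > 1e-12, num / den, 0)
  names(cw) <- net$nodes
  if (is.null(v)) cw else unname(cw[node_index(net, v)])
}

#' Schank-Wagner average weighted clustering coefficient
#'
#' Network-level summary `C = sum_v c_w(v) w(v) / sum_v w(v)` for a node
#' weight function `w(v)`. With the default unit weights this is the plain
#' mean of the Zhang-Horvath coefficients over all nodes (isolated nodes
#' included); `"degree"` weights each node by its weighted degree, which
#' emphasises hubs but lets a node's own low-clustering pendant edges mask
#' its contribution to cohesion. A network whose total node weight is 0
#' scores 0 by convention.
#'
#' @param net A nonempty [mir_network()].
#' @param node_weight `"unit"` (default) or `"degree"`.
#' @return Scalar average weighted clustering coefficient.
#' @export
average_weighted_clustering <- function(net, node_weight = c("unit", "degree")) {
  node_weight <- match.arg(node_weight)
  if (length(net$nodes) == 0) stop("network has no nodes")
  cw <- zhang_clustering(net)
  w <- switch(node_weight,
    unit = rep(1, length(net$nodes)),
    degree = rowSums(weight_matrix(net))
  )
  tot <- sum(w)
  if (tot == 0) 0 else sum(cw * w) / tot
}

# induced subnetwork after deleting one node
drop_node <- function(net, v) {
  keep <- setdiff(net$nodes, v)
  e <- net$edges[net$edges$from != v & net$edges$to != v, , drop = FALSE]
  mir_network(keep, e, net$weight_mode)
}

#' Node-removal robustness ranking
#'
#' Removes each node (with its edges) in turn and recomputes the average
#' weighted clustering coefficient of the remainder. Nodes whose removal
#' drops the coefficient the most — the smallest `awcc_without` — are the
#' most important for network cohesion and are listed first.
#'
#' @param net A [mir_network()] with at least 2 nodes.
#' @param node_weight Node weight function of the average, see
#'   [average_weighted_clustering()].
#' @return Data frame `(feature_id, awcc_without)` sorted ascending;
#'   entries undefined because removal empties the network are `NA`, last.
#' @export
robustness_ranking <- function(net, node_weight = c("unit", "degree")) {
  node_weight <- match.arg(node_weight)
  if (length(net$nodes) < 2) stop("robustness ranking needs at least 2 nodes")
  awcc <- vapply(net$nodes, function(v) {
    sub <- drop_node(net, v)
    if (length(sub$nodes) == 0) {
      NA_real_
    } else {
      average_weighted_clustering(sub, node_weight)
    }
  }, numeric(1))
  out <- data.frame(feature_id = net$nodes, awcc_without = unname(awcc))
  out <- out[order(out$awcc_without, out$feature_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Convert to an igraph graph
#' @param net A [mir_network()].
#' @return An undirected `igraph` object; edge attributes `rho`, `p_value`,
#'   `sign`, `weight` (the mode-dependent metric weight).
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- switch(net$weight_mode,
      raw_abs = abs(igraph::E(g)$rho),
      inverse_abs = 1 / abs(igraph::E(g)$rho)
    )
  }
  g
}

#' Maximal cliques of the network
#'
#' Enumerates all maximal sets of pairwise-adjacent nodes of at least
#' `min_size` members; edge weights are ignored, only adjacency counts.
#'
#' @param net A [mir_network()].
#' @param min_size Smallest clique size reported.
#' @return List of character vectors (sorted node ids), largest cliques
#'   first.
#' @export
find_cliques <- function(net, min_size = 3) {
  g <- as_igraph(net)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(x) sort(igraph::V(g)$name[x]))
  cl[order(-lengths(cl), vapply(cl, paste, "", collapse = ","))]
}

#' Build the significance-filtered Spearman correlation network
#'
#' Computes all pairwise Spearman correlations among signature features in
#' the chosen tissue's samples and keeps an edge wherever the correlation
#' is significant at `alpha` (two-sided, unadjusted; exact p-values for 10
#' or fewer untied samples, t-approximation otherwise). Constant features
#' keep their node but contribute no edges (warning).
#'
#' @param study A [paired_study()].
#' @param signature A `mir_signature` or character vector of feature ids.
#' @param alpha Edge significance threshold.
#' @param tissue Samples used for the correlations: `"tumor"` (default),
#'   `"normal"` or `"all"`.
#' @param weight_mode Passed to [mir_network()].
#' @return A [mir_network()] whose edges store `rho`, `p_value`, `sign`.
#' @export
build_network <- function(study, signature, alpha = 0.05,
                          tissue = c("tumor", "normal", "all"),
                          weight_mode = c("raw_abs", "inverse_abs")) {
  tissue <- match.arg(tissue)
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(study, "paired_study"), alpha >= 0, alpha <= 1)
  feats <- if (is.character(signature)) signature else signature$feature_id
  missing <- setdiff(feats, study$feature_ids)
  if (length(missing) > 0) {
    stop("signature features absent from study: ", paste(missing, collapse = ", "))
  }
  cols <- switch(tissue,
    tumor = names(study$pairing),
    normal = unname(study$pairing),
    all = study$sample_ids
  )
  if (length(cols) < 4) stop("need at least 4 samples in the chosen tissue set")
  X <- study$matrix[feats, cols, drop = FALSE]
  n <- ncol(X)
  constant <- apply(X, 1, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warning(
      "constant features kept as isolated nodes: ",
      paste(feats[constant], collapse = ", ")
    )
  }
  edges <- list()
  if (length(feats) >= 2) {
    idx <- which(!constant)
    combs <- if (length(idx) >= 2) utils::combn(idx, 2) else matrix(integer(0), 2, 0)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]
      j <- combs[2, k]
      ct <- suppressWarnings(stats::cor.test(
        X[i, ], X[j, ],
        method = "spearman", exact = n <= 10
      ))
      rho <- unname(ct$estimate)
      if (!is.na(ct$p.value) && ct$p.value < alpha && rho != 0) {
        edges[[length(edges) + 1]] <- data.frame(
          from = feats[i], to = feats[j],
          rho = rho, p_value = ct$p.value
        )
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else NULL
  net <- mir_network(feats, edges, weight_mode)
  net$alpha <- alpha
  net$tissue <- tissue
  net
}

#' Per-node centrality report
#'
#' Assembles weighted degree, betweenness, Zhang-Horvath clustering and the
#' node-removal AWCC of every node, with ranks (rank 1 = most central:
#' largest degree/betweenness/clustering, *smallest* `awcc_without`).
#'
#' @param net A [mir_network()].
#' @param node_weight Node weight function of the AWCC, see
#'   [average_weighted_clustering()].
#' @return Data frame with one row per node.
#' @export
centrality_report <- function(net, node_weight = c("unit", "degree")) {
  node_weight <- match.arg(node_weight)
  deg <- weighted_degree(net)
  btw <- betweenness(net)
  cw <- zhang_clustering(net)
  awcc <- if (length(net$nodes) >= 2) {
    rr <- robustness_ranking(net, node_weight)
    rr$awcc_without[match(net$nodes, rr$feature_id)]
  } else {
    rep(NA_real_, length(net$nodes))
  }
  data.frame(
    feature_id = net$nodes,
    degree = unname(deg),
    betweenness = unname(btw),
    clustering = unname(cw),
    awcc_without = awcc,
    degree_rank = rank(-deg, ties.method = "min"),
    betweenness_rank = rank(-btw, ties.method = "min"),
    clustering_rank = rank(-cw, ties.method = "min"),
    robustness_rank = rank(awcc, ties.method = "min", na.last = "keep")
  )
}

#' Write the network as GraphML / edge list TSV
#'
#' GraphML nodes carry all centrality measures, edges carry `rho`,
#' `p_value` and `sign`.
#'
#' @param net A [mir_network()].
#' @param path Output file.
#' @name network_io
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  rep <- centrality_report(net)
  ord <- match(igraph::V(g)$name, rep$feature_id)
  igraph::V(g)$degree <- rep$degree[ord]
  igraph::V(g)$betweenness <- rep$betweenness[ord]
  igraph::V(g)$clustering <- rep$clustering[ord]
  awcc <- rep$awcc_without[ord]
  igraph::V(g)$awcc_without <- ifelse(is.na(awcc), -1, awcc)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network_io
#' @param nodes Node universe to restore (edge lists do not list isolated
#'   nodes).
#' @param weight_mode Passed to [mir_network()].
#' @export
read_edge_list <- function(path, nodes = NULL,
                           weight_mode = c("raw_abs", "inverse_abs")) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(e$from, e$to)))
  mir_network(nodes, e, match.arg(weight_mode))
}
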