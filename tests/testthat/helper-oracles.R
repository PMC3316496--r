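# Independent brute-force oracles and fixture builders used across tests.
# The oracles deliberately avoid the package's own code paths.

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j>=i} m p_(j)/j
bf_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, m * ranked[i:m] / (i:m))
  out <- numeric(m)
  out[o] <- q
  out
}

# weight matrix of a mir_network rebuilt from its edge list (raw |rho|)
net_weights <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    W[cbind(i, j)] <- abs(net$edges$rho)
    W[cbind(j, i)] <- abs(net$edges$rho)
  }
  W
}

# all simple paths s -> t by depth-first search; returns list of
# list(len = sum of inverse weights, nodes = interior node indices)
bf_all_paths <- function(W, s, t) {
  n <- nrow(W)
  paths <- list()
  visited <- rep(FALSE, n)
  path_nodes <- integer(0)
  rec <- function(v, len) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- list(len = len, nodes = path_nodes)
      return(invisible())
    }
    for (u in which(W[v, ] > 0)) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        if (u != t) path_nodes <<- c(path_nodes, u)
        rec(u, len + 1 / W[v, u])
        if (u != t) path_nodes <<- path_nodes[-length(path_nodes)]
        visited[u] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  rec(s, 0)
  paths
}

bf_path_distance <- function(W, s, t, tol = 1e-9) {
  paths <- bf_all_paths(W, s, t)
  if (length(paths) == 0) {
    return(list(distance = Inf, n_shortest_paths = 0))
  }
  lens <- vapply(paths, `[[`, numeric(1), "len")
  d <- min(lens)
  list(
    distance = d,
    n_shortest_paths = sum(abs(lens - d) <= tol * max(1, d))
  )
}

bf_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  B <- numeric(n)
  if (n < 3) return(B)
  norm <- (n - 1) * (n - 2) / 2
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_paths(W, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      d <- min(lens)
      sp <- paths[abs(lens - d) <= tol * max(1, d)]
      sigma <- length(sp)
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(sp, function(p) v %in% p$nodes, logical(1)))
        B[v] <- B[v] + through / sigma / norm
      }
    }
  }
  B
}

# maximal cliques of size >= min_size by exhaustive subset enumeration
bf_max_cliques <- function(A, min_size = 3) {
  n <- nrow(A)
  res <- list()
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) < min_size) next
    sub <- A[S, S, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    outside <- setdiff(seq_len(n), S)
    if (length(outside) > 0 &&
      any(vapply(outside, function(u) all(A[u, S] > 0), logical(1)))) {
      next
    }
    res[[length(res) + 1]] <- S
  }
  res
}

# unweighted local clustering coefficient from a 0/1 adjacency matrix
bf_unweighted_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(k, 2)
  }, numeric(1))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
bf_wilcoxon_exact <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n <= 12, !any(duplicated(abs(x))))
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# random weighted graph as a mir_network (weights |rho| in [0.1, 1])
random_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  if (nrow(e) == 0) return(mir_network(nodes))
  rho <- stats::runif(nrow(e), 0.1, 1) *
    sample(c(-1, 1), nrow(e), replace = TRUE)
  mir_network(nodes, data.frame(
    from = nodes[e[, 1]], to = nodes[e[, 2]], rho = rho
  ))
}

# tiny paired study built directly from a matrix of tumour and normal columns
make_study <- function(tumor, normal, feature_ids = NULL) {
  stopifnot(ncol(tumor) == ncol(normal), nrow(tumor) == nrow(normal))
  n <- ncol(tumor)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%02d", seq_len(nrow(tumor)))
  mat <- cbind(tumor, normal)
  rownames(mat) <- feature_ids
  colnames(mat) <- c(sprintf("P%02d_T", 1:n), sprintf("P%02d_N", 1:n))
  paired_study(mat, stats::setNames(sprintf("P%02d_N", 1:n), sprintf("P%02d_T", 1:n)))
}

# one end-to-end discovery run on a synthetic cohort with a planted
# 10-feature DE signal whose first four members form a rho = 0.8 module
recovery_run <- function(seed, n_pairs = 50, n_trees = 1000) {
  planted <- data.frame(
    feature = 1:10,
    fold_change = c(3, 3.5, 4, 3, -3, 3.5, -4, 3, -3.5, 4)
  )
  cfg <- generator_config(
    n_pairs = n_pairs, n_features = 60,
    de_plan = planted,
    module_plan = list(list(features = 1:4, rho = 0.8)),
    seed = seed
  )
  st <- generate_paired_cohort(cfg)
  de <- differential_table(st)
  fm <- fit_forest(st, forest_config(n_trees = n_trees, seed = seed))
  imp <- conditional_mda(fm)
  sig <- merge_rankings(de, imp, p_threshold = 0.001, mda_threshold = 0)
  net <- if (nrow(sig) >= 2) build_network(st, sig, alpha = 0.05) else NULL
  list(
    planted_ids = sprintf("miR-%03d", planted$feature),
    module_ids = sprintf("miR-%03d", 1:4),
    study = st, de = de, imp = imp, sig = sig, net = net
  )
}
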