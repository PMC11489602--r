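# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities from first principles (brute
# force / literal definitions) so they stay independent of the package's
# implementation paths.

# Four-term plug-in MI computed straight from the 2x2 empirical table.
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x == a & y == b) / n
    pa <- sum(x == a) / n
    pb <- sum(y == b) / n
    if (pab > 0) total <- total + pab * log2(pab / (pa * pb))
  }
  total
}

# Literal Benjamini-Hochberg step-up rule: largest k with p_(k) <= k q / m.
oracle_bh_select <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= seq_len(m) * q / m)))
  sel <- rep(FALSE, m)
  if (k > 0) sel[ord[seq_len(k)]] <- TRUE
  sel
}

# Brute-force betweenness (unweighted, unnormalized, unordered pairs
# counted once, equal split over equally short paths) by exhaustive
# simple-path enumeration. adj: symmetric logical/0-1 matrix.
oracle_betweenness <- function(adj) {
  k <- nrow(adj)
  bc <- numeric(k)
  all_paths <- function(s, t, visited) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[s, ] > 0)) {
      if (!visited[v]) {
        vis <- visited; vis[v] <- TRUE
        for (p in all_paths(v, t, vis)) out <- c(out, list(c(s, p)))
      }
    }
    out
  }
  for (s in seq_len(k - 1)) for (t in (s + 1):k) {
    vis <- rep(FALSE, k); vis[s] <- TRUE
    paths <- all_paths(s, t, vis)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  bc
}

# Exhaustive Borgatti-Everett optimum over all non-degenerate two-block
# assignments (1 <= #core <= k-1). Returns the best quality.
oracle_core_quality <- function(W) {
  k <- nrow(W)
  ut <- upper.tri(W)
  w <- W[ut]
  best <- -Inf
  for (code in 1:(2^k - 2)) {
    is_core <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    pattern <- outer(is_core, is_core, `|`)[ut]
    if (sd(pattern) == 0 || sd(w) == 0) next
    q <- cor(w, pattern)
    if (q > best) best <- q
  }
  best
}

# Build a symptom_network directly from a symmetric weight matrix; every
# positive weight is a significant edge. Bypasses inference so the graph
# stages can be tested on hand-crafted topologies.
make_network <- function(W, names = NULL) {
  k <- nrow(W)
  if (is.null(names)) names <- sprintf("v%02d", seq_len(k))
  dimnames(W) <- list(names, names)
  diag(W) <- 0
  sig <- W > 0
  pv <- matrix(1, k, k, dimnames = dimnames(W))
  pv[sig] <- 1e-4
  structure(list(variable_names = names,
                 weights = W,
                 pvalues = pv,
                 significant = sig,
                 cohort_label = "fixture",
                 config = surrogate_config(n_surrogates = 100, seed = 1)),
            class = "symptom_network")
}

# Adjacency (0/1) of an undirected path / star / complete graph.
graph_path <- function(k) {
  A <- matrix(0, k, k)
  for (i in seq_len(k - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}
graph_star <- function(k) {
  A <- matrix(0, k, k)
  A[1, 2:k] <- A[2:k, 1] <- 1
  A
}
graph_complete <- function(k) {
  A <- matrix(1, k, k); diag(A) <- 0; A
}

# Random Bernoulli symptom matrix (every column ~ Bernoulli(p)).
random_binary_matrix <- function(n, k, p = 0.5) {
  symptom_matrix(matrix(as.integer(runif(n * k) < p), n, k,
                        dimnames = list(NULL, sprintf("s%02d", seq_len(k)))))
}
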