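#' Node degree of the significant-edge network
#'
#' Number of FDR-surviving edges incident to each symptom.
#'
#' @param net a `symptom_network`.
#' @return named integer vector.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  stats::setNames(as.integer(rowSums(net$significant)), net$variable_names)
}

#' Node strength of the significant-edge network
#'
#' Sum of MI weights (bits) over each symptom's significant edges.
#'
#' @param net a `symptom_network`.
#' @return named numeric vector (bits).
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  stats::setNames(rowSums(net$weights * net$significant), net$variable_names)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through
#' each node, as an unnormalized count (each unordered pair contributes 1,
#' split equally across equally short paths; nodes in different components
#' contribute nothing). The default `"unweighted"` mode measures path
#' length as the number of links; `"inverse-weight"` uses 1/MI as the
#' length of an edge so that strong edges are short.
#'
#' @param net a `symptom_network`.
#' @param mode `"unweighted"` (default) or `"inverse-weight"`.
#' @param normalized divide by (k-1)(k-2)/2.
#' @return named numeric vector.
#' @export
node_betweenness <- function(net, mode = c("unweighted", "inverse-weight"),
                             normalized = FALSE) {
  stopifnot(inherits(net, "symptom_network"))
  mode <- match.arg(mode)
  g <- as_igraph(net)
  w <- if (mode == "inverse-weight") 1 / igraph::E(g)$weight else NA
  bc <- igraph::betweenness(g, directed = FALSE, weights = w,
                            normalized = normalized)
  stats::setNames(as.numeric(bc), net$variable_names)
}

# Borgatti-Everett quality of a two-block assignment: Pearson correlation
# between the off-diagonal weights and the ideal core-periphery pattern
# (1 unless both endpoints are periphery). NA when either vector is
# constant (e.g. all-core / all-periphery assignments, or an empty net).
core_quality <- function(W, is_core) {
  ut <- upper.tri(W)
  pattern <- (outer(is_core, is_core, `|`))[ut]
  w <- W[ut]
  if (stats::sd(pattern) == 0 || stats::sd(w) == 0) return(NA_real_)
  stats::cor(w, pattern)
}

#' Core-periphery decomposition
#'
#' Discrete two-block decomposition of the significant-edge network into a
#' densely interconnected core and a loosely attached periphery,
#' maximizing the Borgatti-Everett quality: the correlation of the MI
#' weight matrix with the ideal pattern (core-core and core-periphery
#' cells 1, periphery-periphery cells 0). Optimized by single-node
#' label-switching local search from random initial assignments, keeping
#' the best of `restarts` runs; deterministic for a fixed seed. A network
#' with no significant edges has no core: all nodes are periphery and the
#' quality is `NA`.
#'
#' @param net a `symptom_network` with >= 3 nodes.
#' @param restarts number of random restarts (default 100).
#' @param seed integer seed.
#' @return list with `is_core` (named logical), `quality`, `restarts`,
#'   `seed`.
#' @export
core_periphery <- function(net, restarts = 100, seed = 1) {
  stopifnot(inherits(net, "symptom_network"))
  k <- length(net$variable_names)
  if (k < 3) stop("core-periphery decomposition needs >= 3 nodes")
  W <- net$weights * net$significant
  empty <- all(W == 0)
  best <- list(is_core = rep(FALSE, k), quality = NA_real_)
  if (!empty) {
    best <- with_local_seed(seed, {
      bq <- -Inf; ba <- NULL
      for (r in seq_len(restarts)) {
        a <- stats::runif(k) < 0.5
        # keep assignments non-degenerate so the pattern has variance
        if (all(a)) a[sample.int(k, 1)] <- FALSE
        if (!any(a)) a[sample.int(k, 1)] <- TRUE
        q <- core_quality(W, a)
        if (is.na(q)) q <- -Inf
        repeat {
          improved <- FALSE
          for (v in seq_len(k)) {
            cand <- a; cand[v] <- !cand[v]
            if (!any(cand) || all(cand)) next
            qc <- core_quality(W, cand)
            if (!is.na(qc) && qc > q + 1e-12) {
              a <- cand; q <- qc; improved <- TRUE
            }
          }
          if (!improved) break
        }
        better <- q > bq + 1e-12 ||
          (abs(q - bq) <= 1e-12 && !is.null(ba) &&
             paste(as.integer(a), collapse = "") <
             paste(as.integer(ba), collapse = ""))
        if (is.null(ba) || better) { bq <- q; ba <- a }
      }
      list(is_core = ba, quality = bq)
    })
  }
  list(is_core = stats::setNames(best$is_core, net$variable_names),
       quality = best$quality, restarts = restarts, seed = seed)
}

# Weighted Newman modularity at resolution gamma, recomputed from scratch
# (independent of igraph's implementation; used for the reported quality).
modularity_value <- function(W, labels, gamma = 1) {
  two_m <- sum(W)
  if (two_m == 0) return(0)
  strength <- rowSums(W)
  same <- outer(labels, labels, `==`)
  expected <- outer(strength, strength) / two_m
  sum(((W - gamma * expected) * same)) / two_m
}

# Renumber community labels 1..M by descending module size; ties broken by
# first node appearance, giving a canonical deterministic labeling.
canonical_labels <- function(labels) {
  sizes <- table(labels)
  first <- vapply(names(sizes), function(l) match(l, as.character(labels)),
                  integer(1))
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  as.integer(factor(as.character(labels), levels = ord))
}

#' Modularity community detection
#'
#' Partitions the significant-edge network into modules by maximizing
#' weighted Newman modularity at resolution `gamma`, using multi-level
#' (Louvain) optimization with `restarts` random node-order restarts;
#' the best partition is kept (ties broken by the lexicographically
#' smallest canonical label vector, for determinism). Isolated nodes form
#' singleton modules. Labels are renumbered 1..M by descending module
#' size. The reported quality is recomputed from the returned labels.
#'
#' @param net a `symptom_network` with >= 2 nodes.
#' @param gamma resolution parameter (default 1).
#' @param restarts number of restarts (default 100).
#' @param seed integer seed.
#' @return list of class `partition_result` with `labels` (named integer),
#'   `quality`, `gamma`, `n_restarts_used`, `seed`.
#' @export
modularity_partition <- function(net, gamma = 1, restarts = 100, seed = 1) {
  stopifnot(inherits(net, "symptom_network"))
  k <- length(net$variable_names)
  if (k < 2) stop("modularity partition needs >= 2 nodes")
  W <- net$weights * net$significant
  g <- as_igraph(net)
  best <- with_local_seed(seed, {
    bq <- -Inf; bl <- NULL
    for (r in seq_len(restarts)) {
      perm <- sample.int(k)
      gp <- igraph::permute(g, perm)
      comm <- igraph::cluster_louvain(gp, resolution = gamma)
      mem <- igraph::membership(comm)  # named by vertex; map to input order
      labels <- as.integer(mem[match(net$variable_names, names(mem))])
      labels <- canonical_labels(labels)
      q <- modularity_value(W, labels, gamma)
      better <- q > bq + 1e-12 ||
        (!is.null(bl) && abs(q - bq) <= 1e-12 &&
           paste(labels, collapse = ",") < paste(bl, collapse = ","))
      if (is.null(bl) || better) { bq <- q; bl <- labels }
    }
    list(labels = bl, quality = bq)
  })
  structure(list(labels = stats::setNames(best$labels, net$variable_names),
                 quality = best$quality, gamma = gamma,
                 n_restarts_used = restarts, seed = seed),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition: %d modules, modularity = %.4f (gamma = %g)\n",
              max(x$labels), x$quality, x$gamma))
  invisible(x)
}

#' Per-symptom network metrics table
#'
#' Assembles the canonical report row per symptom — prevalence count and
#' percent, degree, strength, betweenness centrality, module label and
#' core/periphery flag — for every variable of the original (pre-filter)
#' matrix, in input order. Variables excluded before network inference are
#' rendered with dashes in the formatted view.
#'
#' @param net a `symptom_network`.
#' @param prevalence data.frame from [prevalence_summary()] on the
#'   original matrix (may include excluded variables).
#' @param betweenness_mode passed to [node_betweenness()].
#' @param gamma,restarts,seed passed to the partition and core-periphery
#'   routines.
#' @return data.frame of class `node_metric_table` with columns
#'   `variable`, `n`, `percent`, `degree`, `strength`, `bc`, `module`,
#'   `is_core` (NA for excluded variables).
#' @export
node_metric_table <- function(net, prevalence,
                              betweenness_mode = "unweighted",
                              gamma = 1, restarts = 100, seed = 1) {
  stopifnot(inherits(net, "symptom_network"), is.data.frame(prevalence))
  if (!all(net$variable_names %in% prevalence$variable)) {
    stop("network variables missing from the prevalence table")
  }
  deg <- node_degree(net)
  str_ <- node_strength(net)
  bc <- node_betweenness(net, mode = betweenness_mode)
  part <- modularity_partition(net, gamma = gamma, restarts = restarts,
                               seed = seed)
  cp <- core_periphery(net, restarts = restarts, seed = seed)
  idx <- match(prevalence$variable, net$variable_names)
  out <- data.frame(
    variable = prevalence$variable,
    n = prevalence$n,
    percent = prevalence$percent,
    degree = as.integer(deg[idx]),
    strength = as.numeric(str_[idx]),
    bc = as.numeric(bc[idx]),
    module = as.integer(part$labels[idx]),
    is_core = as.logical(cp$is_core[idx]),
    stringsAsFactors = FALSE
  )
  attr(out, "betweenness_mode") <- betweenness_mode
  attr(out, "modularity_quality") <- part$quality
  attr(out, "core_quality") <- cp$quality
  class(out) <- c("node_metric_table", class(out))
  out
}

#' Format a node-metric table for reporting
#'
#' Renders the 7-column report layout: variable, "n (percent)", degree,
#' strength (one decimal), BC (rounded to integer), module, Core/Periphery.
#' Excluded variables keep their prevalence and get dashes elsewhere.
#'
#' @param tbl a [node_metric_table()] result.
#' @param dash string used for excluded variables' metric cells.
#' @return character data.frame with 7 columns.
#' @export
format_node_metric_table <- function(tbl, dash = "-") {
  stopifnot(inherits(tbl, "node_metric_table"))
  excl <- is.na(tbl$degree)
  fmt <- function(x, f) ifelse(excl, dash, f(x))
  data.frame(
    variable = tbl$variable,
    no_pct = sprintf("%d (%.1f)", tbl$n, tbl$percent),
    degree = fmt(tbl$degree, function(x) sprintf("%d", x)),
    strength = fmt(tbl$strength, function(x)
      sprintf("%.1f", round_half_up(x, 1))),
    bc = fmt(tbl$bc, function(x) sprintf("%d", as.integer(round_half_up(x, 0)))),
    module = fmt(tbl$module, function(x) sprintf("%d", x)),
    core_periphery = fmt(tbl$is_core,
                         function(x) ifelse(x, "Core", "Periphery")),
    stringsAsFactors = FALSE
  )
}
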