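#' Configuration for surrogate-null edge inference
#'
#' @param n_surrogates number of surrogate randomizations per pair
#'   (default 5000; >= 100). Scaled-down runs (e.g. 500) are supported and
#'   flagged as such in pipeline outputs.
#' @param fdr_q false-discovery-rate level in (0, 1) (default 0.05).
#' @param fdr_method `"BH"` (Benjamini-Hochberg, default) or `"BY"`
#'   (Benjamini-Yekutieli).
#' @param seed master integer seed; per-pair random substreams are derived
#'   deterministically from it and the pair's sorted variable names, so
#'   results are invariant to column order.
#' @param null_method `"hypergeometric"` (default) draws the surrogate
#'   n11 cell directly from its exact permutation distribution;
#'   `"permutation"` explicitly permutes one series per surrogate. The two
#'   are the same null distribution (see the methods vignette); the first
#'   is vectorized.
#' @return a list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 5000, fdr_q = 0.05,
                             fdr_method = c("BH", "BY"), seed = 1,
                             null_method = c("hypergeometric", "permutation")) {
  if (n_surrogates < 100) stop("`n_surrogates` must be >= 100")
  if (fdr_q <= 0 || fdr_q >= 1) stop("`fdr_q` must lie in (0, 1)")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 fdr_q = fdr_q,
                 fdr_method = match.arg(fdr_method),
                 seed = as.integer(seed),
                 null_method = match.arg(null_method)),
            class = "surrogate_config")
}

# Draw `n_surrogates` values of MI under the permutation null for a pair
# with margins (s_x ones of n, s_y ones of n). Permuting one series
# uniformly leaves n11 = #\{i : x_i = y_perm_i = 1\} hypergeometric with
# both margins fixed; all four cells, hence MI, are functions of n11.
surrogate_null_mi <- function(x, y, n_surrogates,
                              method = c("hypergeometric", "permutation")) {
  method <- match.arg(method)
  n <- length(x)
  s_x <- sum(x); s_y <- sum(y)
  if (method == "hypergeometric") {
    n11 <- stats::rhyper(n_surrogates, m = s_x, n = n - s_x, k = s_y)
  } else {
    n11 <- vapply(seq_len(n_surrogates),
                  function(i) sum(x[sample.int(n)] * y), numeric(1))
  }
  n10 <- s_x - n11
  n01 <- s_y - n11
  n00 <- n - s_x - s_y + n11
  mi_from_counts(n00, n01, n10, n11, n)
}

#' Surrogate-permutation p-value for one pair of binary series
#'
#' Tests the observed plug-in MI against a null model in which one series
#' is independently permuted (marginal ones-counts preserved exactly) and
#' MI recomputed, `n_surrogates` times. The p-value is the add-one
#' estimate p = (1 + #\{MI_surr >= MI_obs\}) / (n_surrogates + 1), so it is
#' never zero and ties count toward the null. Constant series give p = 1
#' (every surrogate MI equals the observed 0).
#'
#' @param x,y equal-length binary series.
#' @param n_surrogates number of surrogates (>= 100).
#' @param seed integer seed for the surrogate stream.
#' @param method null sampler, see [surrogate_config()].
#' @return list with `p` (in (0, 1\]), `mi_obs` (bits) and `null_sample`
#'   (the surrogate MI values, bits).
#' @export
surrogate_pvalue <- function(x, y, n_surrogates = 5000, seed = 1,
                             method = c("hypergeometric", "permutation")) {
  if (length(x) != length(y)) stop("series length mismatch")
  if (n_surrogates < 100) stop("`n_surrogates` must be >= 100")
  method <- match.arg(method)
  mi_obs <- mutual_information(x, y)$mi_bits
  null_sample <- with_local_seed(
    seed, surrogate_null_mi(x, y, n_surrogates, method))
  p <- (1 + sum(null_sample >= mi_obs)) / (n_surrogates + 1)
  list(p = p, mi_obs = mi_obs, null_sample = null_sample)
}

#' Benjamini-Hochberg edge selection over a p-value matrix
#'
#' Applies a step-up FDR procedure to the upper-triangle p-values of a
#' symmetric pairwise p-value matrix and returns the symmetric selection
#' mask (false diagonal). Selection is monotone: any pair with a p-value
#' no larger than that of a selected pair is itself selected.
#'
#' @param pvalues symmetric matrix of p-values in (0, 1\].
#' @param q FDR level in (0, 1).
#' @param method `"BH"` or `"BY"` (passed to [stats::p.adjust()]).
#' @return symmetric logical matrix.
#' @export
fdr_select <- function(pvalues, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(is.matrix(pvalues), nrow(pvalues) == ncol(pvalues))
  ut <- upper.tri(pvalues)
  p <- pvalues[ut]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  sel <- stats::p.adjust(p, method = method) <= q
  mask <- matrix(FALSE, nrow(pvalues), ncol(pvalues),
                 dimnames = dimnames(pvalues))
  mask[ut] <- sel
  mask | t(mask)
}

#' Infer the significant-edge symptom network
#'
#' Runs the full edge-inference stage on a (already degeneracy-filtered)
#' symptom matrix: pairwise plug-in MI, per-pair surrogate-permutation
#' p-values, and FDR selection of significant edges. Each pair's surrogate
#' stream is seeded from `cfg$seed` and the pair's sorted variable names,
#' so the result is deterministic for a fixed seed and invariant to the
#' order of columns in `m`.
#'
#' @param m a [symptom_matrix] (pass it through [exclude_degenerate()]
#'   first; near-constant variables produce no significant edges but waste
#'   surrogates).
#' @param cfg a [surrogate_config()].
#' @return an object of class `symptom_network`: list with
#'   `variable_names`, `weights` (symmetric MI matrix, bits, zero
#'   diagonal), `pvalues` (symmetric, unit diagonal), `significant`
#'   (symmetric logical mask, false diagonal), `cohort_label`, `config`.
#' @export
build_network <- function(m, cfg = surrogate_config()) {
  stopifnot(inherits(m, "symptom_matrix"), inherits(cfg, "surrogate_config"))
  k <- ncol(m)
  nm <- colnames(m)
  weights <- matrix(0, k, k, dimnames = list(nm, nm))
  pvalues <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pair_key <- paste(sort(c(nm[i], nm[j])), collapse = "\x1f")
      res <- surrogate_pvalue(m[, i], m[, j],
                              n_surrogates = cfg$n_surrogates,
                              seed = substream_seed(cfg$seed, pair_key),
                              method = cfg$null_method)
      weights[i, j] <- weights[j, i] <- res$mi_obs
      pvalues[i, j] <- pvalues[j, i] <- res$p
    }
  }
  significant <- fdr_select(pvalues, q = cfg$fdr_q, method = cfg$fdr_method)
  structure(list(variable_names = nm,
                 weights = weights,
                 pvalues = pvalues,
                 significant = significant,
                 cohort_label = attr(m, "cohort_label"),
                 config = cfg),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  k <- length(x$variable_names)
  ne <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf("symptom_network: %d nodes, %d significant edges (q = %g, %s, %d surrogates)\n",
              k, ne, x$config$fdr_q, x$config$fdr_method,
              x$config$n_surrogates))
  invisible(x)
}

#' Edge list of a symptom network
#'
#' @param net a `symptom_network`.
#' @param significant_only keep only FDR-surviving edges (default TRUE).
#' @return data.frame with columns `source`, `target`, `mi_bits`,
#'   `p_value`, `significant`, ordered by decreasing MI.
#' @export
edge_list <- function(net, significant_only = TRUE) {
  stopifnot(inherits(net, "symptom_network"))
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  df <- data.frame(
    source = net$variable_names[ut[, 1]],
    target = net$variable_names[ut[, 2]],
    mi_bits = net$weights[ut],
    p_value = net$pvalues[ut],
    significant = net$significant[ut],
    stringsAsFactors = FALSE
  )
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  df <- df[order(-df$mi_bits, df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# igraph view of the significant-edge network; weight attribute = MI bits.
as_igraph <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  adj <- net$weights * net$significant
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write the significant-edge network as GraphML
#'
#' Exports only FDR-surviving edges, with `weight` = MI in bits, plus any
#' node attributes supplied (e.g. module and core labels).
#'
#' @param net a `symptom_network`.
#' @param path output file.
#' @param node_attrs optional data.frame of per-node attributes whose
#'   first column is the variable name.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, node_attrs = NULL) {
  g <- as_igraph(net)
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(g)$name, node_attrs[[1]])
    for (col in names(node_attrs)[-1]) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
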