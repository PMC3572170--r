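# out-degree-preserving rewiring on adjacency lists of vertex indices:
# node i keeps its out-degree d_i but redraws its d_i targets uniformly
# without replacement from the other n-1 nodes. sample.int over n-1 slots
# then shifting indices >= i guarantees no self-loop and no duplicates.
.rewire_targets <- function(targets, n) {
  lapply(seq_len(n), function(i) {
    d <- length(targets[[i]])
    if (d == 0L) return(integer(0))
    if (d == n - 1L) return(setdiff(seq_len(n), i))
    if (d > n - 1L) stop("out-degree exceeds n - 1 for node ", i)
    s <- sample.int(n - 1L, d)
    s + (s >= i)
  })
}

#' Randomize a network preserving each node's out-degree
#'
#' Builds a null-model network in which every student keeps the *number*
#' of outgoing ties they reported but their targets are redrawn uniformly
#' at random (without replacement) from the other n - 1 students. This
#' simulates a scenario where each student named the same number of
#' friends but chose them at random, destroying real social structure
#' while preserving reporting propensity. In-degrees are unconstrained;
#' the node set is unchanged; no self-loops or duplicate edges can arise.
#'
#' Randomness comes from R's global RNG: call `set.seed()` (or use the
#' `seed` arguments of the higher-level functions) for reproducibility.
#'
#' @param net Directed igraph with at least 2 nodes.
#' @return A rewired igraph with the same vertices and graph attributes,
#'   plus `rewired = TRUE`.
#' @export
randomize_out_degree_preserving <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("need at least 2 nodes to rewire")
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net), mode = "out"),
                as.integer)
  if (any(vapply(adj, length, integer(1)) == n - 1L)) {
    message("node(s) with out-degree n-1: neighbourhood forced, unchanged up to order")
  }
  new_adj <- .rewire_targets(adj, n)
  src <- rep(seq_len(n), lengths(new_adj))
  dst <- unlist(new_adj, use.names = FALSE)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (length(src)) g <- igraph::add_edges(g, rbind(src, dst))
  igraph::V(g)$name <- igraph::V(net)$name
  for (at in igraph::graph_attr_names(net)) {
    igraph::graph_attr(g, at) <- igraph::graph_attr(net, at)
  }
  igraph::graph_attr(g, "rewired") <- TRUE
  g
}

#' Permutation null distribution of the environment-progress correlation
#'
#' The observed correlation between the friend-environment score x and
#' progress y is inherently positive even without social influence,
#' because both contain the student's own ranking. This test asks whether
#' the observed r exceeds what random friendship structure alone produces:
#' the network is rewired [randomize_out_degree_preserving()] `n_reps`
#' times, x is recomputed on each rewired network with the same mode and
#' policy as the observed analysis, and r(x, y) is collected. y, g and
#' GPAs are never permuted.
#'
#' @param net Directed tier network the observed x is computed on
#'   (typically the friend tier).
#' @param rank_t0 `ranking_table` for the first timepoint (covering the
#'   network's nodes).
#' @param y Named numeric progress vector (fixed per student).
#' @param n_reps Number of rewired replicates (default 500).
#' @param gpas_t0,mode,undefined_policy As in [environment_scores()]; used
#'   both for the observed x and for every replicate.
#' @param alternative `"greater"` (default) or `"two_sided"`, passed to
#'   [empirical_p()].
#' @param seed Optional integer seed, recorded in the result.
#' @return Object of class `permutation_result`: list with `observed_r`,
#'   `null_rs` (length `n_reps`; a replicate whose x series is constant is
#'   recorded as `NA`), `n_reps`, `empirical_p`, `summary` (min, q1,
#'   median, q3, max of the non-missing null r's), `alternative`, `seed`,
#'   `mode`, `undefined_policy`.
#' @export
null_distribution <- function(net, rank_t0, y, n_reps = 500, gpas_t0 = NULL,
                              mode = c("mean_neighbor_rank", "rank_of_mean_gpa"),
                              undefined_policy = c("exclude", "zero"),
                              alternative = c("greater", "two_sided"),
                              seed = NULL) {
  mode <- match.arg(mode)
  undefined_policy <- match.arg(undefined_policy)
  alternative <- match.arg(alternative)
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(y))) stop("progress y missing for some nodes")
  x_obs <- environment_scores(net, gpas_t0, rank_t0, mode = mode,
                              undefined_policy = undefined_policy)
  yv <- as.numeric(y[nodes])
  observed_r <- pearson_r(as.numeric(x_obs), yv)$r

  n <- length(nodes)
  g <- as.numeric(rank_t0$rank[nodes])
  gpa <- if (is.null(gpas_t0)) NULL else as.numeric(gpas_t0[nodes])
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net), mode = "out"),
                as.integer)
  rep_x <- function(a) {
    x <- vapply(seq_len(n), function(i) .x_from_targets(a[[i]], i, g, gpa, mode),
                numeric(1))
    if (undefined_policy == "zero") x[is.na(x)] <- 0
    x
  }
  null_rs <- vapply(seq_len(n_reps), function(k) {
    x <- rep_x(.rewire_targets(adj, n))
    keep <- !is.na(x)
    if (sum(keep) < 3L || stats::sd(x[keep]) == 0 || stats::sd(yv[keep]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[keep], yv[keep])
  }, numeric(1))
  n_missing <- sum(is.na(null_rs))
  if (n_missing > 0) {
    message(n_missing, " replicate(s) with a degenerate x series recorded as missing")
    if (n_missing > 0.1 * n_reps) {
      stop("more than 10% of replicates degenerate (", n_missing, "/", n_reps, ")")
    }
  }
  structure(list(observed_r = observed_r,
                 null_rs = null_rs,
                 n_reps = n_reps,
                 empirical_p = empirical_p(observed_r, null_rs, alternative),
                 summary = summarize_null(null_rs[!is.na(null_rs)]),
                 alternative = alternative,
                 seed = seed,
                 mode = mode,
                 undefined_policy = undefined_policy),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d rewired networks, alternative = %s)\n",
              x$n_reps, x$alternative))
  cat(sprintf("  observed r = %.4f, empirical p = %.4g\n",
              x$observed_r, x$empirical_p))
  cat(sprintf("  null r: min %.4f, q1 %.4f, median %.4f, q3 %.4f, max %.4f\n",
              x$summary["min"], x$summary["q1"], x$summary["median"],
              x$summary["q3"], x$summary["max"]))
  invisible(x)
}

#' Add-one empirical p-value against a permutation null
#'
#' `greater`: p = (1 + #\{null r >= observed\}) / (m + 1), where m is the
#' number of non-missing null values — the add-one rule counts the
#' observed statistic as one more draw from the null, so p is never 0 and
#' never below 1/(m+1). `two_sided` doubles the smaller one-sided p,
#' capped at 1.
#'
#' @param observed_r Observed statistic.
#' @param null_rs Numeric vector of null statistics (`NA`s dropped).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return A single probability.
#' @export
empirical_p <- function(observed_r, null_rs,
                        alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  null_rs <- null_rs[!is.na(null_rs)]
  if (!length(null_rs)) stop("empty null distribution")
  m <- length(null_rs)
  p_greater <- (1 + sum(null_rs >= observed_r)) / (m + 1)
  if (alternative == "greater") return(p_greater)
  p_less <- (1 + sum(null_rs <= observed_r)) / (m + 1)
  min(1, 2 * min(p_greater, p_less))
}

#' Box-whisker summary of a null distribution
#'
#' Five-number summary (min, lower quartile, median, upper quartile, max)
#' with quartiles by linear interpolation of the order statistics.
#'
#' @param null_rs Non-empty numeric vector.
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_null <- function(null_rs) {
  stopifnot(length(null_rs) >= 1, !anyNA(null_rs))
  setNames(quantile(null_rs, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE),
           c("min", "q1", "median", "q3", "max"))
}
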