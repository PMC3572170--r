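# Independent brute-force oracles used to check the implementation, plus
# small fixture builders. Everything here is deliberately naive: explicit
# loops and closed-form sums, no shared code with the package internals.

# --- fixture builders -------------------------------------------------------

# Build survey responses through the real CSV reader. `ratings` is a named
# list: ratings$u is a named character vector of u's non-"unknown" ratings;
# every unspecified (respondent, target) pair is filled with "unknown" so
# all responses are complete unless `drop` removes rows.
toy_survey <- function(ratings, roster = names(ratings), drop = NULL) {
  rows <- do.call(rbind, lapply(roster, function(u) {
    tgts <- setdiff(roster, u)
    rel <- rep("unknown", length(tgts))
    names(rel) <- tgts
    given <- ratings[[u]]
    rel[names(given)] <- given
    data.frame(respondent_id = u, target_id = tgts, relation = unname(rel),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(drop)) rows <- rows[-drop, , drop = FALSE]
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE, quote = FALSE)
  on.exit(unlink(f))
  read_survey(f, roster = roster)
}

# cohort config with tier degrees scaled down for small test cohorts
small_cfg <- function(n_students, ...) {
  cohort_config(n_students = n_students,
                out_degree_means = c(acquaintance = max(3, round(0.6 * (n_students - 1))),
                                     friend = 4, best = 2),
                ...)
}

# random exclusive-tier ratings over n students (used for property tests)
random_toy_ratings <- function(n, p = c(0.15, 0.2, 0.25)) {
  ids <- sprintf("T%02d", seq_len(n))
  ratings <- lapply(ids, function(u) {
    tgts <- setdiff(ids, u)
    lv <- sample(c("best_friend", "friend", "acquaintance", "unknown"),
                 length(tgts), replace = TRUE, prob = c(p, 1 - sum(p)))
    setNames(lv, tgts)[lv != "unknown"]
  })
  names(ratings) <- ids
  ratings
}

# a small score table with smooth random predictors (no NAs, full rank)
random_scores <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(student_id = sprintf("R%02d", seq_len(n)),
             g = rnorm(n, 10, 4),
             x_acquaintance = rnorm(n),
             x_friend = rnorm(n),
             x_best_friend = rnorm(n),
             y = rnorm(n, 0, 2),
             stringsAsFactors = FALSE)
}

# --- graph metric oracles (explicit triple loops) ---------------------------

graph_to_adjacency <- function(net) {
  n <- igraph::vcount(net)
  a <- matrix(0L, n, n)
  el <- igraph::as_edgelist(net, names = FALSE)
  a[el] <- 1L
  a
}

bf_density <- function(a) sum(a) / (nrow(a) * (nrow(a) - 1))

bf_directed_transitivity <- function(a) {
  n <- nrow(a)
  paths <- 0; closed <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && a[i, j] == 1 && a[j, k] == 1) {
      paths <- paths + 1
      if (a[i, k] == 1) closed <- closed + 1
    }
  }
  if (paths == 0) NaN else closed / paths
}

bf_avg_clustering <- function(a) {
  u <- (a + t(a)) > 0
  n <- nrow(u)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(u[i, ])
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- 0
    for (v in nb) for (w in nb) if (v < w && u[v, w]) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

bf_components <- function(a) {
  u <- (a + t(a)) > 0
  n <- nrow(u)
  comp <- rep(0L, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    nc <- nc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- nc
      queue <- c(queue, which(u[v, ] & comp == 0L))
    }
  }
  nc
}

# --- regression / statistics oracles ----------------------------------------

# normal-equations least squares: beta = (X'X)^{-1} X'y
oracle_ols <- function(d, terms) {
  X <- as.matrix(cbind(1, d[, terms, drop = FALSE]))
  beta <- solve(crossprod(X), crossprod(X, d$y))
  rss <- sum((d$y - X %*% beta)^2)
  list(beta = as.numeric(beta), rss = rss)
}

# sequential sums of squares by refitting every nested model from scratch
oracle_sequential_ss <- function(d, terms) {
  rss <- numeric(length(terms) + 1)
  rss[1] <- sum((d$y - mean(d$y))^2)  # intercept-only
  for (k in seq_along(terms)) {
    rss[k + 1] <- oracle_ols(d, terms[seq_len(k)])$rss
  }
  list(ss = -diff(rss), rss_full = rss[length(rss)])
}

# direct product-moment formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# linear-interpolation quantile on sorted order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo + 1 >= n) return(s[n])
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }, numeric(1))
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
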