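#' Transform a GPA table into class rankings
#'
#' GPA distributions in school records are typically highly negatively
#' skewed, so the pipeline works with academic rankings instead of raw
#' scores. A student's ranking is the number of classmates ranked below
#' them: the class size minus the student's position, with position 1 held
#' by the highest GPA. Greater ranking values therefore mean higher
#' academic standing, and with no ties the rankings are exactly
#' 0, 1, ..., N-1.
#'
#' @param gpas Named numeric vector, student id -> GPA (finite,
#'   non-negative).
#' @param tie_policy How tied GPAs share rankings: `"average"` (default;
#'   tied students share the mean of the rankings they span), `"dense"`
#'   (tied students share the next distinct ranking value), or `"random"`
#'   (ties broken at random; uses the RNG).
#' @param timepoint Optional label (e.g. `"t0"`) stored with the table.
#' @return An object of class `ranking_table`: list with `rank` (named
#'   numeric), `n`, `timepoint`, `tie_policy`.
#' @examples
#' gpa_to_ranking(c(A = 95, B = 90, C = 80))$rank  # A=2 B=1 C=0
#' @export
gpa_to_ranking <- function(gpas, tie_policy = c("average", "dense", "random"),
                           timepoint = NA_character_) {
  tie_policy <- match.arg(tie_policy)
  if (length(gpas) == 0L) stop("empty GPA table")
  if (length(gpas) < 2L) stop("ranking needs at least 2 students")
  if (is.null(names(gpas)) || anyNA(names(gpas)) || anyDuplicated(names(gpas))) {
    stop("gpas must be named by unique student ids")
  }
  if (!all(is.finite(gpas))) stop("GPA values must be finite")
  g <- switch(tie_policy,
    average = rank(gpas, ties.method = "average") - 1,
    random  = rank(gpas, ties.method = "random") - 1,
    dense   = match(gpas, sort(unique(gpas))) - 1
  )
  structure(list(rank = setNames(as.numeric(g), names(gpas)),
                 n = length(gpas),
                 timepoint = timepoint,
                 tie_policy = tie_policy),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table n=%d tie_policy=%s timepoint=%s>\n",
              x$n, x$tie_policy, x$timepoint))
  invisible(x)
}

#' Academic progress between two ranking tables
#'
#' Progress y is the increase or decrease of a student's academic ranking
#' between the two measurement timepoints: y = rank_t1 - rank_t0. Over a
#' tie-free cohort the rankings at both timepoints are permutations of the
#' same values, so the progresses sum to zero.
#'
#' @param rank_t0,rank_t1 `ranking_table` objects over the same cohort.
#' @return Named numeric vector of y values, ordered as `rank_t0`.
#' @export
academic_progress <- function(rank_t0, rank_t1) {
  stopifnot(inherits(rank_t0, "ranking_table"), inherits(rank_t1, "ranking_table"))
  ids0 <- names(rank_t0$rank)
  ids1 <- names(rank_t1$rank)
  if (!setequal(ids0, ids1)) {
    diff <- c(setdiff(ids0, ids1), setdiff(ids1, ids0))
    stop("cohort mismatch between timepoints: ", paste(diff, collapse = ", "))
  }
  rank_t1$rank[ids0] - rank_t0$rank
}

# shared core: x for one node given its out-neighbour target indices.
# g is the ranking vector in node order; gpa only needed for the
# rank_of_mean_gpa reading.
.x_from_targets <- function(targets, i, g, gpa, mode) {
  if (!length(targets)) return(NA_real_)
  if (mode == "mean_neighbor_rank") {
    mean(g[targets]) - g[i]
  } else {
    m <- mean(gpa[targets])
    others <- gpa[-i]
    (sum(others < m) + 0.5 * sum(others == m)) - g[i]
  }
}

#' Social-environment score per student at one tier
#'
#' For each student u, the environment score x_u measures, in rank units,
#' how u's self-reported neighbours' average GPA standing compares with
#' u's own: positive x means u's neighbours outrank u. Neighbours are the
#' targets of u's *outgoing* edges (self-reported ties).
#'
#' Two readings of "difference in ranking between the neighbours' average
#' GPA and one's own" are supported. The default, `"mean_neighbor_rank"`,
#' averages the neighbours' rankings and subtracts u's ranking, staying
#' entirely in rank units. `"rank_of_mean_gpa"` averages the neighbours'
#' raw GPAs, places that mean on the class ranking scale by counting
#' classmates (excluding u) with a lower GPA (ties counted half), and then
#' subtracts u's ranking.
#'
#' @param net Directed igraph whose nodes are a subset of the ranking
#'   cohort.
#' @param gpas_t0 Named numeric GPA vector at the first timepoint (needed
#'   for `mode = "rank_of_mean_gpa"`; may be `NULL` otherwise).
#' @param rank_t0 `ranking_table` at the first timepoint.
#' @param mode `"mean_neighbor_rank"` (default) or `"rank_of_mean_gpa"`.
#' @param undefined_policy What to do for students with no out-neighbours
#'   at this tier: `"exclude"` (default; x is `NA` and the student is
#'   dropped from correlations) or `"zero"` (x = 0, with a warning).
#' @return Named numeric vector of x values over the network's nodes, with
#'   attributes `mode`, `undefined_policy` and `tier`.
#' @export
environment_scores <- function(net, gpas_t0 = NULL, rank_t0,
                               mode = c("mean_neighbor_rank", "rank_of_mean_gpa"),
                               undefined_policy = c("exclude", "zero")) {
  mode <- match.arg(mode)
  undefined_policy <- match.arg(undefined_policy)
  stopifnot(inherits(rank_t0, "ranking_table"))
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(rank_t0$rank))) {
    stop("network nodes missing from the ranking cohort: ",
         paste(utils::head(setdiff(nodes, names(rank_t0$rank)), 5), collapse = ", "))
  }
  g <- rank_t0$rank[nodes]
  gpa <- NULL
  if (mode == "rank_of_mean_gpa") {
    if (is.null(gpas_t0) || !all(nodes %in% names(gpas_t0))) {
      stop("rank_of_mean_gpa mode needs GPA values for every node")
    }
    gpa <- gpas_t0[nodes]
  }
  adj <- igraph::adjacent_vertices(net, igraph::V(net), mode = "out")
  x <- vapply(seq_along(nodes), function(i) {
    .x_from_targets(as.integer(adj[[i]]), i, g, gpa, mode)
  }, numeric(1))
  names(x) <- nodes
  if (anyNA(x)) {
    if (undefined_policy == "zero") {
      warning(sum(is.na(x)), " student(s) with no out-neighbours assigned x = 0")
      x[is.na(x)] <- 0
    } else {
      message(sum(is.na(x)), " student(s) with no out-neighbours excluded (x = NA)")
    }
  }
  structure(x, mode = mode, undefined_policy = undefined_policy,
            tier = igraph::graph_attr(net, "tier"))
}

#' Assemble the per-student score table
#'
#' Runs the whole scoring stage: ranks both GPA tables, computes progress
#' y, builds the three tier networks from the retained survey responses and
#' computes x at each tier. The resulting table is the input to
#' [fit_progress_model()] and [sequential_anova()] (and its `x_friend`/`y`
#' columns are the data behind the environment-vs-progress scatter).
#'
#' @param responses Complete survey responses (see [filter_complete()]).
#' @param gpas_t0,gpas_t1 Named numeric GPA vectors; entries for students
#'   outside the retained cohort are ignored.
#' @param tier_mode `"exclusive"` (default) builds the x predictors from
#'   disjoint neighbour sets; `"cumulative"` nests them.
#' @param x_mode,undefined_policy Passed to [environment_scores()].
#' @param tie_policy Passed to [gpa_to_ranking()].
#' @return A `data.frame` with columns `student_id`, `g`,
#'   `x_acquaintance`, `x_friend`, `x_best_friend`, `y`; attributes record
#'   the policies used and the tier networks (`attr(, "networks")`).
#' @export
score_table <- function(responses, gpas_t0, gpas_t1,
                        tier_mode = c("exclusive", "cumulative"),
                        x_mode = c("mean_neighbor_rank", "rank_of_mean_gpa"),
                        undefined_policy = c("exclude", "zero"),
                        tie_policy = "average") {
  tier_mode <- match.arg(tier_mode)
  x_mode <- match.arg(x_mode)
  undefined_policy <- match.arg(undefined_policy)
  ids <- vapply(responses, `[[`, character(1), "respondent_id")
  missing_gpa <- setdiff(ids, intersect(names(gpas_t0), names(gpas_t1)))
  if (length(missing_gpa)) {
    stop("retained students missing GPA records: ",
         paste(utils::head(missing_gpa, 5), collapse = ", "))
  }
  r0 <- gpa_to_ranking(gpas_t0[ids], tie_policy = tie_policy, timepoint = "t0")
  r1 <- gpa_to_ranking(gpas_t1[ids], tie_policy = tie_policy, timepoint = "t1")
  y <- academic_progress(r0, r1)
  nets <- lapply(c(acquaintance = "acquaintance", friend = "friend", best = "best"),
                 function(t) build_tier_network(responses, t, mode = tier_mode))
  xs <- lapply(nets, function(net) {
    environment_scores(net, gpas_t0[ids], r0, mode = x_mode,
                       undefined_policy = undefined_policy)[ids]
  })
  out <- data.frame(student_id = ids,
                    g = as.numeric(r0$rank[ids]),
                    x_acquaintance = as.numeric(xs$acquaintance),
                    x_friend = as.numeric(xs$friend),
                    x_best_friend = as.numeric(xs$best),
                    y = as.numeric(y[ids]),
                    stringsAsFactors = FALSE)
  attr(out, "tier_mode") <- tier_mode
  attr(out, "x_mode") <- x_mode
  attr(out, "undefined_policy") <- undefined_policy
  attr(out, "tie_policy") <- tie_policy
  attr(out, "networks") <- nets
  attr(out, "rank_t0") <- r0
  out
}
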