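#' Configuration for a synthetic student cohort
#'
#' Bundles the generative conditions for a simulated junior-class cohort:
#' a negatively skewed GPA distribution that drifts upward over the year,
#' three nested tiers of self-reported directed ties, and an optional
#' planted contagion effect coupling a student's GPA change to their
#' friends' mean GPA. Defaults describe a single high-school class of 158
#' students whose acquaintance network is very dense (students know almost
#' everybody) while friendship and best-friendship networks are sparse.
#'
#' @param n_students Cohort size (default 158).
#' @param out_degree_means Named numeric: mean out-degree of the
#'   *exclusive* tiers `acquaintance`, `friend`, `best`. Sizes are drawn
#'   Poisson around these means; the friend tier is clipped to at least 1
#'   so no student lacks friends.
#' @param gpa_shape Two positive Beta shape parameters for GPA_t0 on a
#'   0-100 scale. The default `c(8, 2)` gives a long left tail with mass
#'   near the top (sample skewness around -0.8), as school GPA
#'   distributions typically show.
#' @param drift Mean upward GPA shift from t0 to t1, in GPA units
#'   (default 2).
#' @param contagion_delta Dimensionless coefficient coupling
#'   (mean friend GPA_t0 - own GPA_t0) to the student's GPA change
#'   (default 0.15, a moderate planted effect; 0 = no contagion).
#' @param noise_sd Standard deviation of the Gaussian GPA-change noise, in
#'   GPA units (default 5).
#' @param homophily Weight in `[0, 1]` biasing *best-friend* choices
#'   toward classmates with similar GPA_t0 (kernel `exp(-|dGPA| / 5)`;
#'   0 = uniform choice).
#' @param related_frac Fraction of otherwise-unknown classmates marked
#'   `related` (default 0.02).
#' @param incomplete_count Number of responses rendered incomplete by
#'   deleting a single rating row (default 0).
#' @param seed Optional integer RNG seed recorded with the cohort.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_students = 158,
                          out_degree_means = c(acquaintance = 105, friend = 7, best = 3),
                          gpa_shape = c(8, 2),
                          drift = 2,
                          contagion_delta = 0.15,
                          noise_sd = 5,
                          homophily = 0.3,
                          related_frac = 0.02,
                          incomplete_count = 0,
                          seed = NULL) {
  stopifnot(n_students >= 3,
            all(c("acquaintance", "friend", "best") %in% names(out_degree_means)),
            all(out_degree_means >= 0),
            length(gpa_shape) == 2, all(gpa_shape > 0),
            noise_sd >= 0, homophily >= 0, homophily <= 1,
            related_frac >= 0, related_frac <= 1,
            incomplete_count >= 0, incomplete_count <= n_students)
  if (any(out_degree_means > n_students - 1)) {
    stop("infeasible degree config: mean out-degree exceeds n - 1")
  }
  structure(list(n_students = as.integer(n_students),
                 out_degree_means = out_degree_means[c("acquaintance", "friend", "best")],
                 gpa_shape = as.numeric(gpa_shape),
                 drift = drift,
                 contagion_delta = contagion_delta,
                 noise_sd = noise_sd,
                 homophily = homophily,
                 related_frac = related_frac,
                 incomplete_count = as.integer(incomplete_count),
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Produces a full simulated data set in the same shape the pipeline
#' consumes from real records: one survey response per student (ratings of
#' every classmate at one of the five relation levels) and GPA tables at
#' the two timepoints.
#'
#' Generation steps: (1) GPA_t0 is 100 x Beta(`gpa_shape`); (2) each
#' student's exclusive-tier out-neighbour sets are drawn with Poisson
#' sizes around the tier means (friend tier clipped to at least 1), best
#' friends sampled with homophily-weighted probabilities, friends and
#' acquaintances uniformly from the remaining classmates; remaining
#' classmates are rated `unknown` except a small `related` fraction; (3)
#' GPA_t1 = GPA_t0 + drift + contagion_delta x (mean friend GPA_t0 - own
#' GPA_t0) + Gaussian noise, clipped to the 0-100 scale; (4)
#' `incomplete_count` responses have one randomly chosen rating row
#' deleted.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort`: list with `responses` (list of
#'   `survey_response`), `gpa_t0`, `gpa_t1` (named numeric vectors over
#'   the roster) and `config` (with the seed actually recorded).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_students
  ids <- sprintf("S%04d", seq_len(n))
  gpa_t0 <- setNames(100 * rbeta(n, config$gpa_shape[1], config$gpa_shape[2]), ids)

  mu <- config$out_degree_means
  h <- config$homophily
  tiers <- vector("list", n)
  for (i in seq_len(n)) {
    k_best <- min(rpois(1, mu["best"]), n - 2L)
    k_friend <- min(max(1L, rpois(1, mu["friend"])), n - 1L - k_best)
    k_acq <- min(rpois(1, mu["acquaintance"]), n - 1L - k_best - k_friend)
    others <- setdiff(seq_len(n), i)
    w <- (1 - h) + h * exp(-abs(gpa_t0[i] - gpa_t0[others]) / 5)
    best <- if (k_best > 0) sample(others, k_best, prob = w) else integer(0)
    pool <- setdiff(others, best)
    friend <- sample(pool, k_friend)
    pool <- setdiff(pool, friend)
    acq <- if (k_acq > 0) sample(pool, k_acq) else integer(0)
    pool <- setdiff(pool, acq)
    related <- if (length(pool) && config$related_frac > 0) {
      pool[runif(length(pool)) < config$related_frac]
    } else integer(0)
    tiers[[i]] <- list(best = best, friend = friend, acq = acq, related = related)
  }

  friend_mean <- vapply(tiers, function(t) mean(gpa_t0[t$friend]), numeric(1))
  gpa_t1 <- gpa_t0 + config$drift +
    config$contagion_delta * (friend_mean - gpa_t0) +
    rnorm(n, sd = config$noise_sd)
  gpa_t1 <- setNames(pmin(100, pmax(0, gpa_t1)), ids)

  responses <- lapply(seq_len(n), function(i) {
    t <- tiers[[i]]
    others <- setdiff(seq_len(n), i)
    ratings <- setNames(rep("unknown", length(others)), ids[others])
    ratings[ids[t$best]] <- "best_friend"
    ratings[ids[t$friend]] <- "friend"
    ratings[ids[t$acq]] <- "acquaintance"
    ratings[ids[t$related]] <- "related"
    new_survey_response(ids[i], ratings, complete = TRUE)
  })

  if (config$incomplete_count > 0) {
    marks <- sample.int(n, config$incomplete_count)
    for (i in marks) {
      drop <- sample.int(length(responses[[i]]$ratings), 1)
      responses[[i]]$ratings <- responses[[i]]$ratings[-drop]
      responses[[i]]$complete <- FALSE
    }
  }

  structure(list(responses = responses, gpa_t0 = gpa_t0, gpa_t1 = gpa_t1,
                 config = config),
            class = "cohort")
}

#' Generate a null cohort (no contagion)
#'
#' Identical to [generate_cohort()] with `contagion_delta` forced to 0;
#' used for type-I-error experiments, where any x-y association must come
#' from the rank mechanics alone.
#'
#' @param config A [cohort_config()]; its `contagion_delta` is overridden.
#' @return A `cohort` whose `config$contagion_delta` is 0.
#' @export
generate_null_cohort <- function(config = cohort_config()) {
  config$contagion_delta <- 0
  generate_cohort(config)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d students, contagion_delta = %s, seed = %s>\n",
              x$config$n_students, format(x$config$contagion_delta),
              if (is.null(x$config$seed)) "none" else format(x$config$seed)))
  invisible(x)
}

#' Write a cohort to survey and roster CSV files
#'
#' Emits the same CSV dialects the pipeline reads back: `survey.csv` with
#' header `respondent_id,target_id,relation` and `roster.csv` with header
#' `student_id,gpa_t0,gpa_t1`.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey_path <- file.path(dir, "survey.csv")
  roster_path <- file.path(dir, "roster.csv")
  rows <- do.call(rbind, lapply(cohort$responses, function(r) {
    data.frame(respondent_id = r$respondent_id,
               target_id = names(r$ratings),
               relation = unname(r$ratings),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, survey_path, row.names = FALSE, quote = FALSE)
  roster <- data.frame(student_id = names(cohort$gpa_t0),
                       gpa_t0 = unname(cohort$gpa_t0),
                       gpa_t1 = unname(cohort$gpa_t1),
                       stringsAsFactors = FALSE)
  write.csv(roster, roster_path, row.names = FALSE, quote = FALSE)
  invisible(c(survey = survey_path, roster = roster_path))
}
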