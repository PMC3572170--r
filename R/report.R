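#' Read a roster CSV with two-timepoint GPAs
#'
#' @param file CSV with header `student_id,gpa_t0,gpa_t1`.
#' @return A list with named numeric vectors `gpa_t0` and `gpa_t1`.
#' @export
read_roster <- function(file) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("student_id", "gpa_t0", "gpa_t1")
  if (!all(need %in% names(raw))) {
    stop("roster CSV must have header student_id,gpa_t0,gpa_t1")
  }
  if (anyDuplicated(raw$student_id)) stop("duplicate student ids in roster")
  g0 <- setNames(as.numeric(raw$gpa_t0), raw$student_id)
  g1 <- setNames(as.numeric(raw$gpa_t1), raw$student_id)
  if (!all(is.finite(g0)) || !all(is.finite(g1))) {
    stop("non-finite GPA values in roster")
  }
  list(gpa_t0 = g0, gpa_t1 = g1)
}

# round every numeric leaf to 6 significant digits for serialized reports
.signif6 <- function(x) {
  if (is.list(x)) return(lapply(x, .signif6))
  if (is.numeric(x)) return(signif(x, 6))
  x
}

.write_json <- function(x, file) {
  jsonlite::write_json(.signif6(x), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

#' Run the end-to-end observational analysis
#'
#' Ties the stages together: read (or take) survey responses and GPA
#' records, drop incomplete responses, build the three cumulative tier
#' networks and their metrics, compute rankings, progress and environment
#' scores, fit the progress regression and its sequential ANOVA, and
#' write machine-readable reports plus a run manifest recording every
#' policy choice.
#'
#' Output files in `out_dir`: `metrics_<tier>.json` (one per cumulative
#' tier), `edges_<tier>.tsv`, `scores.tsv`, `anova.tsv`, `manifest.json`.
#' Floating-point values in reports carry 6 significant digits.
#'
#' @param survey,roster Paths to the survey and roster CSVs; alternatively
#'   pass a `cohort` object.
#' @param cohort Optional `cohort` from [generate_cohort()] used instead
#'   of input files.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param tier_mode,x_mode,undefined_policy,tie_policy Analysis policies,
#'   see [score_table()].
#' @param seed Optional integer seed (recorded in the manifest; the
#'   analysis itself is deterministic unless `tie_policy = "random"`).
#' @return Invisibly, a list with `scores`, `fit`, `anova`, `metrics`,
#'   `n_retained`, `manifest`.
#' @export
run_analyze <- function(survey = NULL, roster = NULL, cohort = NULL,
                        out_dir = NULL,
                        tier_mode = "exclusive",
                        x_mode = "mean_neighbor_rank",
                        undefined_policy = "exclude",
                        tie_policy = "average",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cohort)) {
    if (is.null(survey) || is.null(roster)) {
      stop("provide either a cohort or both survey and roster paths")
    }
    gpas <- read_roster(roster)
    responses <- read_survey(survey, roster = names(gpas$gpa_t0))
  } else {
    stopifnot(inherits(cohort, "cohort"))
    gpas <- list(gpa_t0 = cohort$gpa_t0, gpa_t1 = cohort$gpa_t1)
    responses <- cohort$responses
  }
  n_responses <- length(responses)
  retained <- filter_complete(responses)
  scores <- score_table(retained, gpas$gpa_t0, gpas$gpa_t1,
                        tier_mode = tier_mode, x_mode = x_mode,
                        undefined_policy = undefined_policy,
                        tie_policy = tie_policy)
  fit <- fit_progress_model(scores)
  anova_tab <- sequential_anova(scores)
  cum_nets <- lapply(c(acquaintance = "acquaintance", friend = "friend",
                       best = "best"),
                     function(t) build_tier_network(retained, t, "cumulative"))
  metrics <- lapply(cum_nets, network_metrics)
  manifest <- list(
    n_responses = n_responses,
    n_retained = length(retained),
    tier_mode = tier_mode, x_mode = x_mode,
    undefined_policy = undefined_policy, tie_policy = tie_policy,
    seed = seed,
    equation = fit$equation
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(cum_nets)) {
      tier_lab <- igraph::graph_attr(cum_nets[[nm]], "tier")
      .write_json(metrics[[nm]], file.path(out_dir, paste0("metrics_", tier_lab, ".json")))
      write_edge_list(cum_nets[[nm]], file.path(out_dir, paste0("edges_", tier_lab, ".tsv")))
    }
    sc <- scores
    num <- vapply(sc, is.numeric, logical(1))
    sc[num] <- lapply(sc[num], signif, 6)
    utils::write.table(sc, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    at <- as.data.frame(anova_tab)
    at[c("SS", "MS", "F", "p")] <- lapply(at[c("SS", "MS", "F", "p")], signif, 6)
    at$sig <- .p_stars(anova_tab$p)
    utils::write.table(at, file.path(out_dir, "anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(list(scores = scores, fit = fit, anova = anova_tab,
                 metrics = metrics, n_retained = length(retained),
                 manifest = manifest))
}

#' Run the network-randomization permutation test
#'
#' Computes the observed Pearson correlation between the friend-tier
#' environment score and progress, then compares it against `n_reps`
#' out-degree-preserving rewirings of the friend network
#' (see [null_distribution()]), writing a JSON report with the full null
#' distribution for re-plotting.
#'
#' @inheritParams run_analyze
#' @param n_reps Number of rewired replicates (default 500).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param seed Integer seed for the rewirings.
#' @return Invisibly, the `permutation_result` (with an added
#'   `observed_exceeds_null_max` flag).
#' @export
run_permtest <- function(survey = NULL, roster = NULL, cohort = NULL,
                         out_dir = NULL, n_reps = 500,
                         tier_mode = "exclusive",
                         x_mode = "mean_neighbor_rank",
                         undefined_policy = "exclude",
                         tie_policy = "average",
                         alternative = "greater",
                         seed = NULL) {
  if (is.null(cohort)) {
    if (is.null(survey) || is.null(roster)) {
      stop("provide either a cohort or both survey and roster paths")
    }
    gpas <- read_roster(roster)
    responses <- read_survey(survey, roster = names(gpas$gpa_t0))
  } else {
    stopifnot(inherits(cohort, "cohort"))
    gpas <- list(gpa_t0 = cohort$gpa_t0, gpa_t1 = cohort$gpa_t1)
    responses <- cohort$responses
  }
  retained <- filter_complete(responses)
  ids <- vapply(retained, `[[`, character(1), "respondent_id")
  r0 <- gpa_to_ranking(gpas$gpa_t0[ids], tie_policy = tie_policy, timepoint = "t0")
  r1 <- gpa_to_ranking(gpas$gpa_t1[ids], tie_policy = tie_policy, timepoint = "t1")
  y <- academic_progress(r0, r1)
  net <- build_tier_network(retained, "friend", mode = tier_mode)
  res <- null_distribution(net, r0, y, n_reps = n_reps,
                           gpas_t0 = gpas$gpa_t0[ids],
                           mode = x_mode, undefined_policy = undefined_policy,
                           alternative = alternative, seed = seed)
  res$observed_exceeds_null_max <-
    res$observed_r > max(res$null_rs, na.rm = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_json(list(observed_r = res$observed_r,
                     n_reps = res$n_reps,
                     empirical_p = res$empirical_p,
                     summary = as.list(res$summary),
                     alternative = res$alternative,
                     observed_exceeds_null_max = res$observed_exceeds_null_max,
                     seed = res$seed,
                     mode = res$mode,
                     undefined_policy = res$undefined_policy,
                     null_rs = res$null_rs),
                file.path(out_dir, "permutation.json"))
  }
  invisible(res)
}

#' Quick direction test from one student's self-reported friends
#'
#' A screening heuristic requiring no network survey: compare a student's
#' own GPA with the average GPA of the friends they name. Friends' average
#' above the student's own suggests upward pressure on the student's
#' future ranking; below suggests downward.
#'
#' @param own_gpa The student's GPA.
#' @param friend_gpas Numeric vector of the named friends' GPAs (at least
#'   one).
#' @return `"up"`, `"down"` or `"flat"`.
#' @examples
#' quick_test(80, c(90, 85))  # "up"
#' @export
quick_test <- function(own_gpa, friend_gpas) {
  stopifnot(is.numeric(own_gpa), length(own_gpa) == 1, is.finite(own_gpa))
  if (!is.numeric(friend_gpas) || length(friend_gpas) < 1) {
    stop("need at least one friend GPA")
  }
  m <- mean(friend_gpas)
  if (m > own_gpa) "up" else if (m < own_gpa) "down" else "flat"
}
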