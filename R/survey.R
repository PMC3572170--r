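#' @importFrom stats cor pf quantile rbeta rbinom rnorm rpois runif setNames
#' @importFrom utils read.csv write.csv
NULL

#' Relation levels recognised in survey data
#'
#' The five relationship categories a respondent can assign to a classmate.
#' Only the first three (`best_friend`, `friend`, `acquaintance`) ever
#' produce network edges; `unknown` and `related` are retained in the data
#' model for round-trip fidelity but are never used for network
#' reconstruction.
#'
#' @format Character vector of length 5.
#' @export
RELATION_LEVELS <- c("best_friend", "friend", "acquaintance", "unknown", "related")

# relation sets per tier under each construction mode
.tier_relations <- function(tier, mode) {
  tier <- match.arg(tier, c("acquaintance", "friend", "best"))
  mode <- match.arg(mode, c("cumulative", "exclusive"))
  if (mode == "cumulative") {
    switch(tier,
      best         = "best_friend",
      friend       = c("best_friend", "friend"),
      acquaintance = c("best_friend", "friend", "acquaintance"))
  } else {
    switch(tier,
      best         = "best_friend",
      friend       = "friend",
      acquaintance = "acquaintance")
  }
}

.tier_label <- function(tier, mode) {
  if (tier == "best") return("best_only")
  if (mode == "cumulative") paste0(tier, "_plus") else paste0(tier, "_only")
}

#' Read a sociometric survey from CSV
#'
#' Parses a survey edge list in which each row records one respondent's
#' rating of one classmate, validates it against the class roster, and
#' returns one response object per respondent. A response is *complete*
#' when the respondent rated every roster member other than themself
#' exactly once; duplicated ratings of the same target are a validation
#' error rather than a silent overwrite, since the survey form enforces one
#' answer per pair.
#'
#' @param file Path to (or connection for) a CSV with header
#'   `respondent_id,target_id,relation`. Relation strings are matched
#'   case-insensitively against [RELATION_LEVELS].
#' @param roster Character vector of student ids on the class roster.
#' @return A list of `survey_response` objects, each with fields
#'   `respondent_id`, `ratings` (named character vector, target id ->
#'   relation level) and `complete`.
#' @export
read_survey <- function(file, roster) {
  stopifnot(is.character(roster), length(roster) >= 2, !anyDuplicated(roster))
  raw <- read.csv(file, colClasses = "character", strip.white = TRUE)
  need <- c("respondent_id", "target_id", "relation")
  if (!all(need %in% names(raw))) {
    stop("survey CSV must have header respondent_id,target_id,relation")
  }
  rel <- tolower(trimws(raw$relation))
  bad <- which(!rel %in% RELATION_LEVELS)
  if (length(bad)) {
    stop(sprintf("parse error: unknown relation %s at line %d",
                 sQuote(raw$relation[bad[1]]), bad[1] + 1L))
  }
  self <- which(raw$respondent_id == raw$target_id)
  if (length(self)) {
    stop(sprintf("validation error: respondent %s rates self at line %d",
                 raw$respondent_id[self[1]], self[1] + 1L))
  }
  off_roster <- which(!raw$target_id %in% roster)
  if (length(off_roster)) {
    stop(sprintf("validation error: target %s at line %d is not on the roster",
                 raw$target_id[off_roster[1]], off_roster[1] + 1L))
  }
  off_resp <- which(!raw$respondent_id %in% roster)
  if (length(off_resp)) {
    stop(sprintf("validation error: respondent %s at line %d is not on the roster",
                 raw$respondent_id[off_resp[1]], off_resp[1] + 1L))
  }
  dup <- which(duplicated(paste(raw$respondent_id, raw$target_id, sep = "\r")))
  if (length(dup)) {
    stop(sprintf("validation error: duplicate rating of %s by %s at line %d",
                 raw$target_id[dup[1]], raw$respondent_id[dup[1]], dup[1] + 1L))
  }
  split_idx <- split(seq_len(nrow(raw)), factor(raw$respondent_id,
                                                levels = unique(raw$respondent_id)))
  lapply(names(split_idx), function(id) {
    i <- split_idx[[id]]
    ratings <- setNames(rel[i], raw$target_id[i])
    new_survey_response(id, ratings,
                        complete = length(ratings) == length(roster) - 1L)
  })
}

new_survey_response <- function(respondent_id, ratings, complete) {
  structure(list(respondent_id = respondent_id,
                 ratings = ratings,
                 complete = isTRUE(complete)),
            class = "survey_response")
}

#' @export
print.survey_response <- function(x, ...) {
  cat(sprintf("<survey_response %s: %d ratings, %s>\n", x$respondent_id,
              length(x$ratings), if (x$complete) "complete" else "INCOMPLETE"))
  invisible(x)
}

#' Keep only complete survey responses
#'
#' Incomplete responses are excluded from all statistical analysis. The
#' retained responses keep their original order; ratings that point at
#' excluded respondents are *not* removed here — network construction
#' restricts edges to retained nodes.
#'
#' @param responses List of `survey_response` objects.
#' @return The subset with `complete = TRUE`.
#' @export
filter_complete <- function(responses) {
  Filter(function(r) isTRUE(r$complete), responses)
}

#' Build a directed tier network from survey responses
#'
#' Nodes are the respondents; a directed edge (u, v) means u reported a
#' relationship of the requested strength about v. Under `mode =
#' "cumulative"` an edge is present when the rating is at the tier or any
#' stronger tier (the nested networks of the friendship survey: all
#' acquaintances and above, friends and above, best friends only); under
#' `mode = "exclusive"` only ratings exactly at the tier count. Ratings of
#' students who are not retained respondents are dropped (with a message),
#' and `unknown`/`related` ratings never produce edges.
#'
#' @param responses List of complete `survey_response` objects (run
#'   [filter_complete()] first).
#' @param tier One of `"acquaintance"`, `"friend"`, `"best"`.
#' @param mode `"cumulative"` (default) or `"exclusive"`.
#' @return A directed [igraph::igraph] with graph attributes `tier` (e.g.
#'   `"friend_plus"`, `"friend_only"`) and `mode`.
#' @export
build_tier_network <- function(responses, tier = c("acquaintance", "friend", "best"),
                               mode = c("cumulative", "exclusive")) {
  if (is.character(tier) && length(tier) == 1L && tier %in% c("unknown", "related")) {
    stop("tier must be a reconstruction level (acquaintance/friend/best); ",
         sQuote(tier), " ratings never form edges")
  }
  tier <- match.arg(tier)
  mode <- match.arg(mode)
  if (!length(responses)) stop("no responses")
  if (!all(vapply(responses, function(r) isTRUE(r$complete), logical(1)))) {
    stop("all responses must be complete; run filter_complete() first")
  }
  nodes <- vapply(responses, `[[`, character(1), "respondent_id")
  keep_rel <- .tier_relations(tier, mode)
  src <- rep(nodes, vapply(responses, function(r) length(r$ratings), integer(1)))
  tgt <- unlist(lapply(responses, function(r) names(r$ratings)), use.names = FALSE)
  rel <- unlist(lapply(responses, `[[`, "ratings"), use.names = FALSE)
  sel <- rel %in% keep_rel
  src <- src[sel]; tgt <- tgt[sel]
  dropped <- !tgt %in% nodes
  if (any(dropped)) {
    message(sum(dropped), " rating(s) of non-retained students dropped")
    src <- src[!dropped]; tgt <- tgt[!dropped]
  }
  g <- igraph::graph_from_data_frame(data.frame(from = src, to = tgt,
                                                stringsAsFactors = FALSE),
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::graph_attr(g, "tier") <- .tier_label(tier, mode)
  igraph::graph_attr(g, "mode") <- mode
  g
}

# directed global transitivity: fraction of directed 2-paths i->j->k (i != k)
# that are closed by an edge i->k
.directed_transitivity <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  p <- a %*% a
  paths <- sum(p) - sum(Matrix::diag(p))
  if (paths == 0) return(NaN)
  sum(p * a) / paths
}

#' Network metrics for a tier network
#'
#' Computes the summary metrics used to characterise each survey tier:
#' density and global transitivity on the directed links, average local
#' clustering after replacing each directed edge by an undirected one,
#' complementary cumulative out-/in-degree distributions, and the
#' component/isolate counts of the undirected view.
#'
#' Directed transitivity is the fraction of directed two-paths
#' u -> v -> w (u != w) closed by an edge u -> w. The CCDFs report
#' P(degree >= k) at every integer k from 0 to the maximum degree, so they
#' start at 1 and are non-increasing.
#'
#' @param net A directed igraph, e.g. from [build_tier_network()].
#' @return An object of class `network_metrics`: a list with `n_nodes`,
#'   `n_edges`, `density`, `transitivity`, `avg_clustering`, `out_ccdf`,
#'   `in_ccdf`, `n_components`, `n_isolated`.
#' @export
network_metrics <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("density undefined for a network with fewer than 2 nodes")
  und <- igraph::as_undirected(net, mode = "collapse")
  ccdf <- function(deg) {
    ks <- 0:max(deg)
    setNames(vapply(ks, function(k) mean(deg >= k), numeric(1)), ks)
  }
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    density = igraph::ecount(net) / (n * (n - 1)),
    transitivity = .directed_transitivity(net),
    avg_clustering = igraph::transitivity(und, type = "localaverage",
                                          isolates = "zero"),
    out_ccdf = ccdf(igraph::degree(net, mode = "out")),
    in_ccdf = ccdf(igraph::degree(net, mode = "in")),
    n_components = igraph::components(und)$no,
    n_isolated = sum(igraph::degree(und) == 0)
  ), class = "network_metrics", tier = igraph::graph_attr(net, "tier"))
}

#' @export
print.network_metrics <- function(x, ...) {
  tier <- attr(x, "tier")
  cat(sprintf("Network metrics%s: %d nodes, %d edges\n",
              if (is.null(tier)) "" else paste0(" (", tier, ")"),
              x$n_nodes, x$n_edges))
  cat(sprintf("  density %.4f, transitivity %.4f, avg clustering %.4f\n",
              x$density, x$transitivity, x$avg_clustering))
  cat(sprintf("  components %d, isolated nodes %d\n", x$n_components, x$n_isolated))
  invisible(x)
}

#' Write a tier network as an edge-list TSV
#'
#' @param net Directed igraph with a `tier` graph attribute.
#' @param file Output path; columns `source`, `target`, `tier`.
#' @export
write_edge_list <- function(net, file) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   tier = igraph::graph_attr(net, "tier") %||% NA_character_)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
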