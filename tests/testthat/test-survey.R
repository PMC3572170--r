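test_that("a full 3-student survey parses into complete responses", {
  resp <- toy_survey(list(
    A = c(B = "best_friend", C = "friend"),
    B = c(A = "friend", C = "acquaintance"),
    C = c(A = "unknown", B = "related")
  ))
  expect_length(resp, 3)
  expect_true(all(vapply(resp, `[[`, logical(1), "complete")))
  expect_identical(resp[[1]]$ratings[["B"]], "best_friend")
  expect_false("A" %in% names(resp[[1]]$ratings))
})

test_that("invalid survey rows are rejected with line-level diagnostics", {
  roster <- c("A", "B", "C")
  write_rows <- function(df) {
    f <- tempfile(fileext = ".csv")
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    f
  }
  base <- data.frame(respondent_id = c("A", "A"), target_id = c("B", "C"),
                     relation = c("friend", "friend"))
  bad_rel <- base; bad_rel$relation[2] <- "enemy"
  expect_error(read_survey(write_rows(bad_rel), roster), "unknown relation.*line 3")
  self <- base; self$target_id[1] <- "A"
  expect_error(read_survey(write_rows(self), roster), "rates self")
  off <- base; off$target_id[2] <- "Z"
  expect_error(read_survey(write_rows(off), roster), "not on the roster")
  dup <- rbind(base, data.frame(respondent_id = "A", target_id = "B",
                                relation = "acquaintance"))
  expect_error(read_survey(write_rows(dup), roster), "duplicate rating")
  # case-insensitive relation strings are fine
  cased <- base; cased$relation <- c("Friend", "BEST_FRIEND")
  resp <- read_survey(write_rows(cased), roster)
  expect_identical(unname(resp[[1]]$ratings), c("friend", "best_friend"))
})

test_that("a 160-response cohort with 2 incomplete responses retains 158", {
  co <- generate_cohort(cohort_config(n_students = 160, incomplete_count = 2,
                                      seed = 11))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  resp <- read_survey(paths["survey"], roster = names(co$gpa_t0))
  expect_length(resp, 160)
  expect_identical(sum(!vapply(resp, `[[`, logical(1), "complete")), 2L)
  kept <- filter_complete(resp)
  expect_length(kept, 158)
  # idempotence and trivial cases
  expect_identical(filter_complete(kept), kept)
  expect_length(filter_complete(list()), 0)
  none <- lapply(resp, function(r) { r$complete <- FALSE; r })
  expect_length(filter_complete(none), 0)
})

test_that("tier networks follow the cumulative/exclusive edge rules", {
  resp <- toy_survey(list(
    A = c(B = "best_friend", C = "friend", D = "acquaintance", E = "related"),
    B = c(A = "friend", C = "best_friend"),
    C = c(A = "acquaintance"),
    D = c(A = "friend", B = "friend", C = "unknown"),
    E = c(A = "best_friend")
  ))
  edges <- function(net) {
    el <- igraph::as_edgelist(net)
    sort(paste(el[, 1], el[, 2]))
  }
  # hand enumeration of the 5-node toy survey
  expect_identical(edges(build_tier_network(resp, "best", "cumulative")),
                   sort(c("A B", "B C", "E A")))
  expect_identical(edges(build_tier_network(resp, "friend", "cumulative")),
                   sort(c("A B", "A C", "B C", "B A", "D A", "D B", "E A")))
  expect_identical(edges(build_tier_network(resp, "acquaintance", "cumulative")),
                   sort(c("A B", "A C", "A D", "B C", "B A", "C A",
                          "D A", "D B", "E A")))
  # exclusive tiers: a best_friend rating does not appear at the friend tier
  expect_identical(edges(build_tier_network(resp, "friend", "exclusive")),
                   sort(c("A C", "B A", "D A", "D B")))
  expect_identical(edges(build_tier_network(resp, "acquaintance", "exclusive")),
                   sort(c("A D", "C A")))
  # related/unknown never form edges and are not valid tiers
  expect_error(build_tier_network(resp, "related"), "never form edges")
  expect_error(build_tier_network(resp, "unknown"), "never form edges")
  # incomplete responses must be filtered first
  resp[[1]]$complete <- FALSE
  expect_error(build_tier_network(resp, "friend"), "filter_complete")
})

test_that("tier construction is monotone and exclusive tiers partition", {
  set.seed(401)
  for (rep in 1:5) {
    resp <- toy_survey(random_toy_ratings(8))
    e <- function(net) {
      el <- igraph::as_edgelist(net)
      paste(el[, 1], el[, 2])
    }
    best <- e(build_tier_network(resp, "best", "cumulative"))
    fr <- e(build_tier_network(resp, "friend", "cumulative"))
    acq <- e(build_tier_network(resp, "acquaintance", "cumulative"))
    expect_true(all(best %in% fr))
    expect_true(all(fr %in% acq))
    ex <- c(e(build_tier_network(resp, "best", "exclusive")),
            e(build_tier_network(resp, "friend", "exclusive")),
            e(build_tier_network(resp, "acquaintance", "exclusive")))
    expect_identical(sort(ex), sort(acq))
    expect_identical(anyDuplicated(ex), 0L)
  }
})

test_that("ratings of non-retained students are dropped from networks", {
  resp <- toy_survey(list(
    A = c(B = "friend", C = "friend"),
    B = c(A = "friend", C = "best_friend"),
    C = c(A = "unknown", B = "unknown")
  ))
  # C never responded completely in this scenario: drop C's response and
  # expect edges naming C to disappear with a message
  kept <- resp[1:2]
  expect_message(net <- build_tier_network(kept, "friend"), "non-retained")
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  el <- igraph::as_edgelist(net)
  expect_setequal(paste(el[, 1], el[, 2]), c("A B", "B A"))
})

test_that("network metrics match hand computations on canonical graphs", {
  # complete directed graph on 4 nodes
  k4 <- igraph::make_full_graph(4, directed = TRUE)
  igraph::V(k4)$name <- letters[1:4]
  m <- network_metrics(k4)
  expect_equal(m$density, 1)
  expect_equal(m$n_components, 1)
  expect_equal(m$transitivity, 1)
  # directed 3-cycle: density 1/2; undirected view is a triangle
  cyc <- igraph::graph_from_literal(a -+ b, b -+ c, c -+ a)
  m <- network_metrics(cyc)
  expect_equal(m$density, 0.5)
  expect_equal(m$avg_clustering, 1)
  # a directed 3-cycle has 3 two-paths, none closed in the directed sense
  expect_equal(m$transitivity, 0)
  # out-star on 5 nodes: hub out-degree 4
  star <- igraph::make_star(5, mode = "out")
  igraph::V(star)$name <- paste0("s", 1:5)
  m <- network_metrics(star)
  expect_equal(unname(m$out_ccdf[["4"]]), 0.2)
  expect_equal(unname(m$out_ccdf[["0"]]), 1)
  expect_equal(m$n_isolated, 0)
  expect_equal(m$n_components, 1)
  # single-node network: density undefined
  one <- igraph::make_empty_graph(1)
  expect_error(network_metrics(one), "fewer than 2 nodes")
})

test_that("metrics agree with brute-force oracles on random digraphs", {
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7), directed = TRUE)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    a <- graph_to_adjacency(g)
    m <- network_metrics(g)
    expect_equal(m$density, bf_density(a))
    expect_equal(m$transitivity, bf_directed_transitivity(a))
    expect_equal(m$avg_clustering, bf_avg_clustering(a))
    expect_equal(m$n_components, bf_components(a))
    expect_equal(m$n_isolated, sum(rowSums((a + t(a)) > 0) == 0))
    # CCDF starts at 1, is non-increasing, and matches per-degree counts
    for (ccdf in list(m$out_ccdf, m$in_ccdf)) {
      expect_equal(unname(ccdf[["0"]]), 1)
      expect_true(all(diff(ccdf) <= 1e-12))
    }
    outdeg <- rowSums(a)
    expect_equal(unname(m$out_ccdf[[as.character(max(outdeg))]]),
                 mean(outdeg == max(outdeg)) + mean(outdeg > max(outdeg)))
  }
})
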