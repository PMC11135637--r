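tree <- toy_tree()

test_that("tally_votes matches hand tallies for both strategies", {
  w <- c(A = 2, B = 1, C = 1.5)
  # A->5, B->6, C->6 at species
  t1 <- tally_votes(c(A = 5L, B = 6L, C = 6L), w, "recall", "species", tree)
  expect_equal(t1[["5"]], 2.0)
  expect_equal(t1[["6"]], 2.5)
  # abstentions vanish under recall ...
  t2 <- tally_votes(c(A = 5L, B = 0L, C = 0L), w, "recall", "species", tree)
  expect_equal(t2, c("5" = 2.0))
  # ... and pool under UNKNOWN under precision
  t3 <- tally_votes(c(A = 5L, B = 0L, C = 0L), w, "precision", "species", tree)
  expect_equal(t3[["5"]], 2.0)
  expect_equal(t3[["UNKNOWN"]], 2.5)
  # projection: strain 9 votes as its species 5; genus 3 is above species
  t4 <- tally_votes(c(A = 9L, B = 3L, C = 5L), w, "recall", "species", tree)
  expect_equal(t4, c("5" = 3.5))
  # a tool without a weight is a config error
  expect_error(tally_votes(c(A = 5L, D = 6L), w, "recall", "species", tree),
               class = "taxvote_config_error")
})

test_that("decide applies argmax, strict-max UNKNOWN, and the LCA tie rule", {
  d1 <- decide(c("5" = 2.0, "6" = 2.5), "recall", tree)
  expect_identical(d1$verdict, 6L)
  expect_equal(d1$winning_weight, 2.5)
  expect_false(d1$tie_resolved)

  # UNKNOWN needs a strict win under precision
  d2 <- decide(c("5" = 2.0, UNKNOWN = 2.5), "precision", tree)
  expect_identical(d2$verdict, UNKNOWN)
  d3 <- decide(c("5" = 2.5, UNKNOWN = 2.5), "precision", tree)
  expect_identical(d3$verdict, 5L)   # tie resolves to the taxon

  # tied taxa collapse to their LCA
  d4 <- decide(c("5" = 1.0, "6" = 1.0), "recall", tree)
  expect_identical(d4$verdict, 3L)   # lca(5,6) = genus 3
  expect_true(d4$tie_resolved)
  # cross-superkingdom tie would collapse to the root -> UNCLASSIFIED
  tree2 <- taxonomy_tree(c(1, 2, 3, 4, 5), c(1, 1, 1, 2, 3),
                         c("no rank", "superkingdom", "superkingdom",
                           "species", "species"))
  d5 <- decide(c("4" = 1.0, "5" = 1.0), "recall", tree2)
  expect_identical(d5$verdict, UNCLASSIFIED)
  expect_true(d5$tie_resolved)

  d6 <- decide(setNames(numeric(0), character(0)), "recall", tree)
  expect_identical(d6$verdict, UNCLASSIFIED)
  expect_equal(d6$winning_weight, 0)
})

test_that("merge_all: single-tool identity and unanimity", {
  s <- assignment_set("solo", c("r1", "r2", "r3"), c(9L, 3L, 0L))
  res <- merge_all(list(s), weights = c(solo = 0.7), tree = tree)
  # equals the tool's own output projected to species
  expect_identical(res$consensus$assignments,
                   c(r1 = 5L, r2 = UNCLASSIFIED, r3 = UNCLASSIFIED))
  sets <- lapply(paste0("t", 1:4), function(nm)
    assignment_set(nm, c("r1", "r2"), c(5L, 6L)))
  w <- c(t1 = 1, t2 = 2, t3 = 0.5, t4 = 1.5)
  res2 <- merge_all(sets, weights = w, tree = tree)
  expect_identical(unname(res2$consensus$assignments), c(5L, 6L))
  expect_equal(res2$details$winning_weight, rep(sum(w), 2))  # unanimity
  expect_error(merge_all(list(), tree = tree), class = "taxvote_config_error")
})

test_that("merge_all agrees with the brute-force oracle, per strategy", {
  set.seed(101)
  instances <- replicate(300, random_instance(), simplify = FALSE)
  weights <- instances[[1L]]$weights
  sets <- make_sets(lapply(instances, `[[`, "votes"))
  for (strategy in c("recall", "precision")) {
    res <- merge_all(sets, weights = weights, strategy = strategy,
                     target_rank = "species", tree = tree)
    expected <- vapply(instances, function(inst)
      o_merge_read(tree, inst$votes, weights, strategy, "species")$verdict,
      integer(1))
    expect_identical(unname(res$consensus$assignments), expected)
    # scalar API agrees with the vectorised path
    for (i in sample.int(length(instances), 20)) {
      tl <- tally_votes(instances[[i]]$votes, weights, strategy, "species", tree)
      d <- decide(tl, strategy, tree)
      expect_identical(d$verdict, expected[i])
    }
  }
})

test_that("verdict weight is the argmax certificate", {
  set.seed(202)
  instances <- replicate(100, random_instance(), simplify = FALSE)
  weights <- instances[[1L]]$weights
  sets <- make_sets(lapply(instances, `[[`, "votes"))
  res <- merge_all(sets, weights = weights, strategy = "precision",
                   tree = tree)
  tal <- res$tallies
  for (r in unique(tal$read_id)) {
    w <- tal$weight[tal$read_id == r]
    i <- match(r, res$details$read_id)
    expect_true(all(res$details$winning_weight[i] >= w - 1e-12))
    expect_equal(res$details$winning_weight[i], max(w))
  }
})

test_that("weight-scale and tool-order invariance hold exactly", {
  set.seed(303)
  instances <- replicate(200, random_instance(), simplify = FALSE)
  weights <- instances[[1L]]$weights
  sets <- make_sets(lapply(instances, `[[`, "votes"))
  for (strategy in c("recall", "precision")) {
    base <- merge_all(sets, weights = weights, strategy = strategy, tree = tree)
    for (c0 in c(0.01, 3, 1e6)) {
      scaled <- merge_all(sets, weights = weights * c0, strategy = strategy,
                          tree = tree)
      expect_identical(scaled$consensus$assignments, base$consensus$assignments)
    }
    perm <- merge_all(sets[sample(length(sets))], weights = weights,
                      strategy = strategy, tree = tree)
    expect_identical(perm$consensus$assignments, base$consensus$assignments)
    expect_identical(perm$details$verdict, base$details$verdict)
    expect_identical(perm$details$tie_resolved, base$details$tie_resolved)
    expect_equal(perm$details$winning_weight, base$details$winning_weight)
  }
})

test_that("precision verdicts are contained in recall verdicts", {
  set.seed(404)
  for (rep in 1:20) {
    instances <- replicate(100, random_instance(), simplify = FALSE)
    weights <- instances[[1L]]$weights
    sets <- make_sets(lapply(instances, `[[`, "votes"))
    rc <- merge_all(sets, weights = weights, strategy = "recall", tree = tree)
    pr <- merge_all(sets, weights = weights, strategy = "precision", tree = tree)
    a_rc <- rc$consensus$assignments
    a_pr <- pr$consensus$assignments
    assigned <- a_pr > 0L
    expect_true(all(a_rc[assigned] == a_pr[assigned]))
    expect_true(all(a_rc[assigned] > 0L))
  }
})

test_that("missing reads count as unclassified votes for that tool", {
  s1 <- assignment_set("a", c("r1", "r2"), c(5L, 6L))
  s2 <- assignment_set("b", "r1", 5L)          # r2 absent
  res <- merge_all(list(s1, s2), strategy = "precision", tree = tree)
  tal <- res$tallies
  r2 <- tal[tal$read_id == "r2", ]
  expect_equal(r2$weight[r2$label == UNKNOWN], 1)   # b's absence votes UNKNOWN
  expect_equal(r2$weight[r2$label == 6L], 1)
})

test_that("require_unanimity blanks disagreeing reads under recall", {
  sets <- list(assignment_set("a", c("r1", "r2"), c(5L, 5L)),
               assignment_set("b", c("r1", "r2"), c(5L, 6L)))
  res <- merge_all(sets, strategy = "recall", tree = tree,
                   require_unanimity = TRUE)
  expect_identical(res$consensus$assignments,
                   c(r1 = 5L, r2 = UNCLASSIFIED))
})

test_that("raw-taxid voting is available behind the project flag", {
  sets <- list(assignment_set("a", "r1", 9L),
               assignment_set("b", "r1", 9L))
  res <- merge_all(sets, tree = tree, project = FALSE)
  expect_identical(res$consensus$assignments[["r1"]], 9L)  # strain kept raw
})

test_that("fit_weights is accuracy-proportional, normalised to max 1", {
  truth <- truth_set(sprintf("r%02d", 1:20), rep(c(5L, 6L, 7L, 8L), 5))
  correct <- truth$taxid
  mk <- function(nm, n_ok) {
    lab <- correct
    if (n_ok < 20) lab[(n_ok + 1):20] <- 0L
    assignment_set(nm, truth$read_id, lab)
  }
  w <- fit_weights(list(mk("good", 18), mk("half", 9)), truth, "species", tree)
  expect_equal(unname(w[c("good", "half")]), c(1.0, 0.5))
  expect_equal(unname(fit_weights(list(mk("solo", 13)), truth, "species", tree)), 1.0)
  w0 <- fit_weights(list(mk("good", 18), mk("dead", 0)), truth, "species", tree)
  expect_equal(unname(w0[["dead"]]), 0.0)
  expect_warning(
    we <- fit_weights(list(mk("d1", 0), mk("d2", 0)), truth, "species", tree),
    "equal weights")
  expect_equal(unname(we), c(1, 1))
  expect_error(fit_weights(list(), truth, "species", tree),
               class = "taxvote_config_error")
  expect_error(fit_weights(list(mk("a", 5)), truth_set(character(0), integer(0)),
                           "species", tree),
               class = "taxvote_config_error")
})

test_that("merge config files round-trip and validate", {
  p <- withr::local_tempfile()
  w <- c(kraken2 = 1, kaiju = 0.5)
  write_merge_config(p, w, strategy = "merge_p", target_rank = "genus")
  cfg <- read_merge_config(p)
  expect_equal(cfg$weights, w)
  expect_identical(cfg$strategy, "precision")
  expect_identical(cfg$target_rank, "genus")
  writeLines(c("a\t-1"), p)
  expect_error(read_merge_config(p), class = "taxvote_config_error")
  expect_error(weight_config(c(a = 0, b = 0)), class = "taxvote_config_error")
  expect_error(weight_config(c(a = Inf)), class = "taxvote_config_error")
  expect_error(weight_config(setNames(1, "")), class = "taxvote_config_error")
})
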