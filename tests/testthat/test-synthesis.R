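test_that("global priorities multiply down the tree and conserve mass", {
  # two equal top objectives, each with two equal children -> (50, 25 x4)
  h <- decision_hierarchy("g", list(
    list(name = "A", children = c("A1", "A2")),
    list(name = "B", children = c("B1", "B2"))
  ), c("x", "y"))
  loc <- list(g = c(A = 0.5, B = 0.5), A = c(A1 = 0.5, A2 = 0.5),
              B = c(B1 = 0.5, B2 = 0.5))
  g <- global_priorities(h, loc)
  expect_equal(unname(g[c("A", "A1", "A2", "B", "B1", "B2")]),
               c(50, 25, 25, 50, 25, 25))

  # single-child chain inherits the parent weight unchanged
  h2 <- decision_hierarchy("g", list(
    list(name = "benefits", children = list("only outcome")), "harms"
  ), c("x", "y"))
  g2 <- global_priorities(h2, list(g = c(benefits = 0.5483, harms = 0.4517)))
  expect_equal(unname(g2["only outcome"]), unname(g2["benefits"]))

  expect_error(global_priorities(h, loc[-1]), "missing local priorities")
})

test_that("sibling partitions conserve the parent's global to machine precision", {
  set.seed(31)
  h <- decision_hierarchy("g", list(
    list(name = "A", children = c("A1", "A2", "A3")),
    list(name = "B", children = list(
      list(name = "B1", children = c("B1a", "B1b")), "B2"))
  ), c("x", "y"))
  for (rep in 1:10) {
    loc <- list(g = random_simplex(2), A = random_simplex(3),
                B = random_simplex(2), B1 = random_simplex(2))
    loc <- lapply(loc, function(w) w)
    names(loc) <- c("g", "A", "B", "B1")
    loc$g <- stats::setNames(loc$g, c("A", "B"))
    loc$A <- stats::setNames(loc$A, c("A1", "A2", "A3"))
    loc$B <- stats::setNames(loc$B, c("B1", "B2"))
    loc$B1 <- stats::setNames(loc$B1, c("B1a", "B1b"))
    g <- global_priorities(h, loc)
    expect_equal(sum(g[c("A", "B")]), 100, tolerance = 1e-12)
    expect_equal(sum(g[c("A1", "A2", "A3")]), unname(g["A"]), tolerance = 1e-12)
    expect_equal(sum(g[c("B1a", "B1b")]), unname(g["B1"]), tolerance = 1e-12)
  }
})

test_that("the two synthesis modes reproduce the hand-computed example", {
  # 2 equal criteria; local alternative priorities A(.7,.4), B(.2,.35), C(.1,.25)
  h <- flat_model(2, alternatives = c("A", "B", "C"))
  loc <- flat_locals(h, c(0.5, 0.5),
                     rbind(c(0.7, 0.2, 0.1), c(0.4, 0.35, 0.25)))
  d <- score_alternatives(h, loc, "distributive")
  expect_equal(unname(d$alternative_scores), c(0.55, 0.275, 0.175),
               tolerance = 1e-12)
  i <- score_alternatives(h, loc, "ideal")
  expect_equal(unname(i$raw_scores), c(1, 0.580357142857143, 0.383928571428571),
               tolerance = 1e-12)
  expect_equal(round(unname(i$alternative_scores), 3), c(0.509, 0.295, 0.195))
  expect_identical(d$ranking$alternative, c("A", "B", "C"))
  expect_identical(i$ranking$rank, c(1L, 2L, 3L))
})

test_that("a single leaf objective makes scores equal its local priorities", {
  h <- flat_model(1, alternatives = c("A", "B", "C"))
  loc <- flat_locals(h, 1, rbind(c(0.5, 0.3, 0.2)))
  for (mode in c("ideal", "distributive")) {
    s <- score_alternatives(h, loc, mode)
    expect_equal(unname(s$alternative_scores), c(0.5, 0.3, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("an everywhere-maximal alternative ranks first in both modes", {
  set.seed(77)
  for (rep in 1:20) {
    n_leaf <- sample(2:4, 1)
    n_alt <- sample(3:5, 1)
    P <- t(replicate(n_leaf, {
      w <- random_simplex(n_alt)
      # force alternative 1 to be the strict leaf maximum
      w[1] <- max(w) * 1.05
      w / sum(w)
    }))
    h <- flat_model(n_leaf, alternatives = paste0("alt", seq_len(n_alt)))
    loc <- flat_locals(h, random_simplex(n_leaf), P)
    for (mode in c("ideal", "distributive")) {
      s <- score_alternatives(h, loc, mode)
      expect_identical(s$ranking$alternative[1], "alt1")
    }
  }
})

test_that("both modes rank identically under chain dominance across leaves", {
  set.seed(78)
  for (rep in 1:20) {
    n_leaf <- sample(2:4, 1)
    P <- t(replicate(n_leaf, sort(random_simplex(4), decreasing = TRUE)))
    h <- flat_model(n_leaf, alternatives = paste0("alt", 1:4))
    loc <- flat_locals(h, random_simplex(n_leaf), P)
    cmp <- compare_modes(h, loc)
    expect_true(cmp$agreement)
    expect_identical(cmp$ranks$rank_ideal, 1:4)
  }
})

test_that("ideal mode preserves ranks when a nowhere-best alternative is added", {
  set.seed(202)
  for (rep in 1:100) {
    n_leaf <- sample(2:4, 1)
    n_alt <- sample(3:5, 1)
    P <- t(replicate(n_leaf, random_simplex(n_alt)))
    # entrant strictly below the current leaf maximum everywhere
    entrant <- apply(P, 1, function(p) max(p) * runif(1, 0.1, 0.95))
    lw <- random_simplex(n_leaf)

    alts0 <- paste0("alt", seq_len(n_alt))
    h0 <- flat_model(n_leaf, alternatives = alts0)
    s0 <- score_alternatives(h0, flat_locals(h0, lw, P), "ideal")

    P1 <- cbind(P, entrant) / rowSums(cbind(P, entrant))
    h1 <- flat_model(n_leaf, alternatives = c(alts0, "entrant"))
    s1 <- score_alternatives(h1, flat_locals(h1, lw, P1), "ideal")

    r0 <- rank(-s0$alternative_scores[alts0], ties.method = "min")
    r1 <- rank(-s1$alternative_scores[alts0], ties.method = "min")
    expect_identical(unname(r0), unname(r1))
  }
})

test_that("distributive mode can reverse ranks when an alternative is added", {
  # equal-weight criteria; performances A=(8,1), B=(3,3); entrant C=(1,6).
  # Found by small grid search over integer performance tables.
  perf2 <- rbind(c(8, 3), c(1, 3))              # rows = criteria
  perf3 <- rbind(c(8, 3, 1), c(1, 3, 6))
  h2 <- flat_model(2, alternatives = c("A", "B"))
  h3 <- flat_model(2, alternatives = c("A", "B", "C"))
  loc2 <- flat_locals(h2, c(0.5, 0.5), perf2 / rowSums(perf2))
  loc3 <- flat_locals(h3, c(0.5, 0.5), perf3 / rowSums(perf3))
  s2 <- score_alternatives(h2, loc2, "distributive")$alternative_scores
  s3 <- score_alternatives(h3, loc3, "distributive")$alternative_scores
  expect_gt(s2["B"], s2["A"])  # B wins head-to-head
  expect_gt(s3["A"], s3["B"])  # adding C flips the order
})

test_that("relative differences reproduce ratio arithmetic and significance", {
  rd <- relative_differences(c(hypo = 14.01, fracture = 2.57))
  expect_equal(ratio_between(rd, "hypo", "fracture"), 14.01 / 2.57)
  expect_equal(round(ratio_between(rd, "hypo", "fracture"), 2), 5.45)
  expect_true(rd$significant["hypo", "fracture"])
  expect_identical(rd$display["fracture", "hypo"], "")  # shown in larger row
  expect_identical(rd$display["hypo", "hypo"], "1.00")

  rd2 <- relative_differences(c(a = 3, b = 3))
  expect_equal(ratio_between(rd2, "a", "b"), 1)
  expect_false(rd2$significant["a", "b"])

  expect_error(relative_differences(c(a = 1, b = 0)), "positive")
})
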