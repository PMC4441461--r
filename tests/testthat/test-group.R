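test_that("geometric-mean aggregation matches direct arithmetic", {
  # idempotence
  v <- c(a = 0.3, b = 0.7)
  expect_equal(as.numeric(aggregate_priorities(list(v, v, v))), c(0.3, 0.7),
               tolerance = 1e-12)
  # symmetry
  expect_equal(as.numeric(aggregate_priorities(list(c(a = 0.8, b = 0.2),
                                                    c(a = 0.2, b = 0.8)))),
               c(0.5, 0.5), tolerance = 1e-12)
  # three experts, hand-computed geometric means then renormalization
  agg <- aggregate_priorities(list(c(a = 0.5, b = 0.5),
                                   c(a = 0.25, b = 0.75),
                                   c(a = 0.4, b = 0.6)))
  gm <- c((0.5 * 0.25 * 0.4)^(1 / 3), (0.5 * 0.75 * 0.6)^(1 / 3))
  expect_equal(unname(attr(agg, "unnormalized")), gm, tolerance = 1e-12)
  expect_equal(as.numeric(agg), gm / sum(gm), tolerance = 1e-12)
  expect_equal(as.numeric(agg), c(0.3772, 0.6228), tolerance = 1e-4)
})

test_that("aggregation rejects zero weights and mismatched items", {
  expect_error(aggregate_priorities(list(c(a = 1, b = 0), c(a = .5, b = .5))),
               "positive")
  expect_error(aggregate_priorities(list(c(a = .5, b = .5), c(a = .5, q = .5))),
               "identical items")
})

test_that("log-domain mean property and rescaling invariance hold", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    k <- sample(2:9, 1)
    vecs <- replicate(k, stats::setNames(random_simplex(n), paste0("i", 1:n)),
                      simplify = FALSE)
    agg <- aggregate_priorities(vecs)
    # pre-normalization log group weight = mean of log individual weights
    W <- do.call(rbind, vecs)
    expect_equal(log(unname(attr(agg, "unnormalized"))),
                 unname(colMeans(log(W))), tolerance = 1e-12)
    # per-expert positive rescaling before normalization changes nothing
    scaled <- lapply(vecs, function(v) v * runif(1, 0.1, 10))
    expect_equal(as.numeric(aggregate_priorities(scaled)), as.numeric(agg),
                 tolerance = 1e-9)
  }
})

test_that("dispersion is the per-item sample SD in percentage points", {
  v <- list(c(a = 0.2, b = 0.8), c(a = 0.4, b = 0.6))
  expect_equal(unname(priority_dispersion(v)), c(sd(c(20, 40)), sd(c(80, 60))))
  expect_equal(unname(priority_dispersion(v))[1], 14.14, tolerance = 1e-3)

  # identical vectors -> zero spread; expert order is irrelevant
  same <- list(c(a = .5, b = .5), c(a = .5, b = .5))
  expect_equal(unname(priority_dispersion(same)), c(0, 0))
  expect_equal(priority_dispersion(rev(v)), priority_dispersion(v))

  expect_error(priority_dispersion(list(c(a = .5, b = .5))), "at least two")
})

test_that("group synthesis of one expert equals that expert's synthesis", {
  h <- diabetes_model()
  coh <- generate_cohort(cohort_config(h, n_experts = 1, noise_sigma = 0.3,
                                       seed = 21))
  der <- derive_all(coh$judgments[[1]], h)
  solo <- score_alternatives(h, der, "ideal")
  grp <- group_synthesize(h, list(der), "ideal")
  expect_equal(grp$synthesis$alternative_scores, solo$alternative_scores,
               tolerance = 1e-12)
  expect_null(grp$dispersion)
  expect_identical(grp$n_experts, 1L)
})

test_that("a noise-free panel reproduces the ground truth exactly", {
  h <- diabetes_model()
  coh <- generate_cohort(cohort_config(h, n_experts = 9, noise_sigma = 0,
                                       seed = 8))
  ders <- lapply(coh$judgments, derive_all, h = h)
  grp <- group_synthesize(h, ders, "ideal")
  for (p in names(coh$truth$locals)) {
    expect_equal(as.numeric(grp$group_locals[[p]]),
                 as.numeric(coh$truth$locals[[p]]), tolerance = 1e-8)
  }
  expect_equal(grp$synthesis$alternative_scores,
               coh$truth$alternative_scores$ideal, tolerance = 1e-8)
  for (d in grp$dispersion) expect_true(all(abs(d) < 1e-6))
})

test_that("group locals beat the median individual expert on recovery", {
  # Monte-Carlo: geometric-mean pooling across 9 noisy experts should be
  # closer to truth (lower MAE) than the median expert, on average.
  h <- minimal_model()
  n_rep <- 50
  wins <- 0
  group_mae <- med_mae <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(cohort_config(h, n_experts = 9, noise_sigma = 0.3,
                                         seed = 1000 + r))
    ders <- lapply(coh$judgments, derive_all, h = h)
    locs <- lapply(ders, local_priorities)
    maes_by_expert <- vapply(locs, function(l) {
      mean(vapply(names(coh$truth$locals), function(p) {
        recovery_error(l[[p]], coh$truth$locals[[p]])$mae
      }, numeric(1)))
    }, numeric(1))
    grp <- group_synthesize(h, ders, "ideal")
    group_mae[r] <- mean(vapply(names(coh$truth$locals), function(p) {
      recovery_error(grp$group_locals[[p]], coh$truth$locals[[p]])$mae
    }, numeric(1)))
    med_mae[r] <- median(maes_by_expert)
  }
  expect_lt(mean(group_mae), mean(med_mae))
})

test_that("score-level aggregation is available and differs only in scores", {
  h <- diabetes_model()
  coh <- generate_cohort(cohort_config(h, n_experts = 3, noise_sigma = 0.4,
                                       seed = 13))
  ders <- lapply(coh$judgments, derive_all, h = h)
  a <- group_synthesize(h, ders, "ideal", aggregate = "locals")
  b <- group_synthesize(h, ders, "ideal", aggregate = "scores")
  expect_equal(sum(b$synthesis$alternative_scores), 1, tolerance = 1e-9)
  expect_identical(a$group_locals, b$group_locals)
})
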