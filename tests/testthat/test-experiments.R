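fake_summaries <- function(n_per, shift_cs = 0, seed = 1) {
  set.seed(seed)
  mk <- function(cond, n, cs_mu) {
    data.frame(condition = cond, subject_id = seq_len(n),
               OBS = rnorm(n, 50, 5), SW = rnorm(n, 0.1, 0.02),
               VIS = rnorm(n, 0.2, 0.05), ABS = rnorm(n, 0.05, 0.01),
               AS = rnorm(n, 5, 1), MS = rnorm(n, 10, 2),
               HOM = rnorm(n, 0.8, 0.05), GS = rnorm(n, 20, 3),
               TS = rnorm(n, 30, 5), CS = rnorm(n, cs_mu, 3))
  }
  rbind(mk("young", n_per, 30 + shift_cs), mk("aged", n_per, 30))
}

test_that("rank-sum comparisons with Holm correction flag only real shifts", {
  # identical groups: nothing significant
  d0 <- fake_summaries(10, shift_cs = 0, seed = 2)
  d0[d0$condition == "aged", -(1:2)] <- d0[d0$condition == "young", -(1:2)]
  r0 <- compare_groups(d0)
  expect_true(all(!r0$significant))
  # a large planted CS shift is flagged, and mostly only CS
  hits_cs <- 0; hits_other <- 0
  for (s in 1:50) {
    d <- fake_summaries(12, shift_cs = 15, seed = s)
    r <- compare_groups(d)
    if (r$significant[r$metric == "CS"]) hits_cs <- hits_cs + 1
    hits_other <- hits_other + sum(r$significant[r$metric != "CS"])
  }
  expect_gte(hits_cs / 50, 0.9)
  expect_lte(hits_other / (50 * 9), 0.05)
  # Holm's most extreme comparison is p_min against alpha / m
  d <- fake_summaries(12, shift_cs = 15, seed = 3)
  r <- compare_groups(d)
  pmin_ <- min(r$p)
  expect_equal(min(r$p_holm), min(1, pmin_ * 10))
  expect_error(compare_groups(d[c(1, 13), ]), "at least 2")
})

test_that("the dose classifier is deterministic and aces separable classes", {
  # five classes with disjoint feature ranges: leave-one-out accuracy 1
  set.seed(4)
  d <- do.call(rbind, lapply(1:5, function(k) {
    n <- 8
    data.frame(condition = paste0("dose", k), subject_id = 1:n,
               OBS = rnorm(n, 100 * k, 1), SW = rnorm(n, k, 0.01),
               VIS = rnorm(n, k, 0.01), ABS = rnorm(n, k, 0.01),
               AS = rnorm(n, 10 * k, 0.1), MS = rnorm(n, 20 * k, 0.1),
               HOM = rnorm(n, k / 10, 0.001), GS = rnorm(n, 5 * k, 0.05),
               TS = rnorm(n, 8 * k, 0.1), CS = rnorm(n, 6 * k, 0.05))
  }))
  fit <- dose_classifier(d, n_trees = 50, seed = 1)
  expect_equal(fit$accuracy, 1.0)
  # confusion-matrix accounting is exact
  expect_equal(sum(diag(fit$confusion)) / sum(fit$confusion), fit$accuracy)
  expect_equal(as.vector(rowSums(fit$confusion)),
               as.vector(table(d$condition)))
  # determinism: identical seed, identical confusion matrix
  fit2 <- dose_classifier(d, n_trees = 50, seed = 1)
  expect_identical(fit$confusion, fit2$confusion)
  # five equiprobable classes put chance accuracy at 0.2
  expect_equal(1 / nlevels(factor(d$condition)), 0.2)
})

test_that("shuffled labels drive accuracy down to the permutation null", {
  set.seed(5)
  d <- fake_summaries(10, shift_cs = 0, seed = 6)
  d$condition <- sample(d$condition)
  fit <- dose_classifier(d, n_trees = 25, seed = 2)
  # two balanced classes: null accuracy is near 0.5; binomial 95% bounds
  expect_gte(fit$accuracy, qbinom(0.025, 20, 0.5) / 20 - 0.15)
  expect_lte(fit$accuracy, qbinom(0.975, 20, 0.5) / 20 + 0.15)
})

test_that("transfer scoring counts category-consistent predictions", {
  expect_equal(consistency_fraction(c(30, 22), c(40, 30)), 52 / 70)
  expect_equal(round(100 * consistency_fraction(c(30, 22), c(40, 30))), 74)
  expect_equal(consistency_fraction(c(40, 30), c(40, 30)), 1.0)
  expect_error(consistency_fraction(31, 30), "range")
  # model transfer: aged-like (low coupling analogue) features score into
  # degraded categories under a classifier trained on graded doses
  set.seed(7)
  mk <- function(cond, mu, n = 10) data.frame(
    condition = cond, subject_id = 1:n, OBS = rnorm(n, 50, 2),
    SW = rnorm(n, 0.1, 0.01), VIS = rnorm(n, 0.2, 0.02),
    ABS = rnorm(n, 0.05, 0.01), AS = rnorm(n, 5, 0.5),
    MS = rnorm(n, 10, 1), HOM = rnorm(n, 0.8, 0.02),
    GS = rnorm(n, mu, 1), TS = rnorm(n, 30, 2), CS = rnorm(n, mu, 1))
  train <- rbind(mk("baseline", 30), mk("apv15", 24), mk("apv30", 18),
                 mk("apv60", 12), mk("apv120", 6))
  fit <- dose_classifier(train, n_trees = 50, seed = 3)
  test <- rbind(mk("young", 30, n = 12), mk("aged", 14, n = 12))
  mapping <- list(young = "baseline",
                  aged = c("apv15", "apv30", "apv60", "apv120"))
  tr <- transfer_classify(fit, test, mapping)
  expect_gt(tr$fraction_consistent, 0.7)
  expect_equal(sum(tr$per_condition$n), 24)
  expect_error(transfer_classify(fit, mk("unknown", 20), mapping),
               "no mapping")
})

test_that("edge dropping reaches the target degree without touching weights' distribution", {
  sp <- synth_spec(height = 6, width = 6, n_frames = 120, n_communities = 2,
                   coupling = 0.9, noise_sd = 0.1, seed = 8)
  net <- build_temporal_network(dff(generate_movie(sp)$stack),
                                W = 50, theta = 0.7, stride = 20)
  d0 <- mean_degree(net)
  expect_gt(d0, 2)
  # identity at the current degree
  same <- drop_edges(net, d0, seed = 1)
  expect_equal(sum(vapply(same$snapshots, function(s) nrow(s$edges), 1)),
               sum(vapply(net$snapshots, function(s) nrow(s$edges), 1)))
  # target zero removes everything
  none <- drop_edges(net, 0, seed = 1)
  expect_equal(sum(vapply(none$snapshots, function(s) nrow(s$edges), 1)), 0)
  expect_error(drop_edges(net, d0 + 1, seed = 1), "exceeds")
  # achieved mean degree (on original node observations) hits the target
  n_obs <- sum(vapply(net$snapshots, function(s) length(s$nodes), 1))
  half <- drop_edges(net, d0 / 2, seed = 2)
  e_half <- sum(vapply(half$snapshots, function(s) nrow(s$edges), 1))
  expect_equal(e_half, floor(d0 / 2 * n_obs / 2))
  # removal is weight-blind: kept-edge weight mean stays put across seeds
  w_all <- unlist(lapply(net$snapshots, function(s) s$edges$w))
  w_kept <- unlist(lapply(1:10, function(s)
    unlist(lapply(drop_edges(net, d0 / 2, seed = s)$snapshots,
                  function(x) x$edges$w))))
  expect_lt(abs(mean(w_kept) - mean(w_all)), 0.005)
})

test_that("dropping edges to a fifth of the degree shrinks normalized community size", {
  norm_cs_of <- function(net) {
    parts <- lapply(seq_along(net$snapshots), function(k)
      louvain(net$snapshots[[k]], seed = k))
    grp <- temporal_grouping(parts)
    col <- commdy_infer(grp)
    summarize_activation(node_metrics(col, grp))$norm_CS
  }
  res <- vapply(1:5, function(s) {
    sp <- synth_spec(height = 6, width = 9, n_frames = 120,
                     n_communities = 3, coupling = 0.9, noise_sd = 0.1,
                     seed = s)
    net <- build_temporal_network(dff(generate_movie(sp)$stack),
                                  W = 50, theta = 0.7, stride = 20)
    c(full = norm_cs_of(net),
      dropped = norm_cs_of(drop_edges(net, 0.2 * mean_degree(net),
                                      seed = s)))
  }, numeric(2))
  expect_true(all(res["dropped", ] < res["full", ]))
})
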