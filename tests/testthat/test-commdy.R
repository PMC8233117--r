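test_that("social cost charges switches, visits and absences per definition", {
  # two individuals in one group at both steps, all colors equal: cost 0
  gr <- temporal_grouping(list(list(c(1, 2)), list(c(1, 2))))
  ic <- matrix(1L, 2, 2, dimnames = list(NULL, c("1", "2")))
  col0 <- list(group_color = list(1L, 1L), individual_color = ic)
  expect_equal(social_cost(gr, col0), 0)
  # one individual changing color across two observed steps: one switch
  gr1 <- temporal_grouping(list(list(1), list(1)))
  ic1 <- matrix(c(1L, 2L), 2, 1, dimnames = list(NULL, "1"))
  col1 <- list(group_color = list(1L, 2L), individual_color = ic1)
  expect_equal(social_cost(gr1, col1), 1)
  expect_equal(social_cost(gr1, col1, commdy_costs(switch = 2.5)), 2.5)
  # the worked 4-individual instance: cost 1 with a switching to Y
  gr2 <- temporal_grouping(list(list(c(1, 2), c(3, 4)),
                                list(c(1, 3, 4), c(2))))
  ic2 <- matrix(c(1L, 1L, 2L, 2L,    # t1: a,b=X c,d=Y
                  2L, 1L, 2L, 2L),   # t2: a switched to Y, b stays X
                2, 4, byrow = TRUE,
                dimnames = list(NULL, as.character(1:4)))
  col2 <- list(group_color = list(c(1L, 2L), c(2L, 1L)),
               individual_color = ic2)
  expect_equal(social_cost(gr2, col2), 1)
  # the same cost from the independent plain-loop transcription
  expect_equal(oracle_social_cost(gr2, col2$group_color, ic2, commdy_costs()),
               1)
  expect_error(social_cost(gr2, list(group_color = list(c(1L, 2L), c(2L)),
                                     individual_color = ic2)),
               "uncolored")
})

test_that("exact inference matches exhaustive enumeration on tiny instances", {
  # identical groups at every step: zero cost, one color per persistent group
  grc <- temporal_grouping(list(list(c(1, 2), c(3, 4)),
                                list(c(1, 2), c(3, 4)),
                                list(c(1, 2), c(3, 4))))
  exc <- commdy_exact(grc)
  expect_equal(exc$total_cost, 0)
  expect_length(unique(unlist(exc$group_color)), 2)
  # the worked instance has optimum exactly 1
  gr2 <- temporal_grouping(list(list(c(1, 2), c(3, 4)),
                                list(c(1, 3, 4), c(2))))
  expect_equal(commdy_exact(gr2)$total_cost, 1)
  expect_equal(oracle_min_cost(gr2, commdy_costs()), 1)
  # a single time step never incurs temporal costs
  gr3 <- temporal_grouping(list(list(c(1, 2), c(3))))
  expect_equal(commdy_exact(gr3)$total_cost, 0)
  # refusal above the size cap
  big <- temporal_grouping(lapply(1:6, function(t) list(1:9)))
  expect_error(commdy_exact(big), "too large")
  # random tiny instances agree with the brute-force oracle
  for (s in 1:12) {
    gr <- random_grouping(s, n_ind = 4, n_steps = 3, max_groups = 2)
    expect_equal(commdy_exact(gr)$total_cost,
                 oracle_min_cost(gr, commdy_costs()),
                 label = paste("instance", s))
  }
})

test_that("the heuristic is valid, self-consistent, and close to the optimum", {
  equal_hits <- 0
  for (s in 1:100) {
    gr <- random_grouping(s, n_ind = 6, n_steps = 4, max_groups = 2)
    inf <- commdy_infer(gr)
    expect_true(validate_coloring(gr, inf))
    # unrestricted color budget so the reference optimum is global
    opt <- commdy_exact(gr, max_colors = sum(lengths(gr$groups)))$total_cost
    expect_gte(inf$total_cost, opt - 1e-9)
    expect_lte(inf$total_cost, 3 * opt + 1e-9)
    if (abs(inf$total_cost - opt) < 1e-9) equal_hits <- equal_hits + 1
  }
  expect_gte(equal_hits, 70)
})

test_that("zero heuristic cost coincides with time-consistent groupings", {
  for (s in 1:40) {
    gr <- random_grouping(200 + s, n_ind = 5, n_steps = 3, max_groups = 2,
                          p_obs = if (s %% 2) 1 else 0.7)
    zero <- commdy_infer(gr)$total_cost == 0
    expect_identical(zero, oracle_zero_cost_possible(gr),
                     label = paste("instance", s))
  }
})

test_that("doubling all cost parameters exactly doubles the optimal cost", {
  for (s in 1:10) {
    gr <- random_grouping(300 + s, n_ind = 5, n_steps = 3, max_groups = 2)
    c1 <- commdy_exact(gr, commdy_costs(1, 1, 1))$total_cost
    c2 <- commdy_exact(gr, commdy_costs(2, 2, 2))$total_cost
    expect_equal(c2, 2 * c1)
  }
})

test_that("unequal cost settings reweight the inferred solution", {
  # a being away from its group is resolved as a visit or a switch depending
  # on which is cheaper
  gr <- temporal_grouping(list(list(c(1, 2)), list(c(1, 2)), list(c(1, 3)),
                               list(c(1, 2))))
  cheap_visit <- commdy_exact(gr, commdy_costs(switch = 5, visit = 0.5))
  cheap_switch <- commdy_exact(gr, commdy_costs(switch = 0.25, visit = 5))
  expect_lt(cheap_visit$total_cost, 5)
  expect_lte(cheap_switch$total_cost, 2)
})

test_that("communities rank by occupancy with first-appearance tie-breaks", {
  gr <- temporal_grouping(list(list(c(1, 2, 3), c(4, 5)),
                               list(c(1, 2, 3), c(4, 5)),
                               list(c(1, 2, 3), c(6, 7))))
  inf <- commdy_infer(gr)
  top <- top_communities(inf, k = 20)
  # all communities returned, biggest first
  expect_lte(length(top), 20)
  occ <- sapply(top, function(c_)
    sum(inf$individual_color == c_, na.rm = TRUE))
  expect_true(all(diff(occ) <= 0))
  expect_equal(top[1], inf$group_color[[1]][1])   # the 3-member community
  # equal occupancy: earlier-appearing community first
  ge <- temporal_grouping(list(list(c(1, 2)), list(c(3, 4))))
  ie <- commdy_infer(ge)
  te <- top_communities(ie, k = 5)
  expect_equal(te[1], ie$group_color[[1]][1])
  expect_error(top_communities(ie, k = 0), "k")
})

test_that("the planted mid-movie membership switch is localized in time", {
  h <- 9; w <- 9
  m1 <- commdynet:::stripe_map(h, w, 3)
  m2 <- m1; m2[, 3] <- 2L                    # column 3 moves community 1 -> 2
  spec <- synth_spec(height = h, width = w, n_frames = 240,
                     n_communities = 3, community_map = list(m1, m2),
                     epoch_boundaries = 121L, coupling = 0.9, noise_sd = 0.1,
                     seed = 3)
  mv <- generate_movie(spec)
  net <- build_temporal_network(dff(mv$stack), W = 50, theta = 0.7,
                                stride = 10)
  parts <- lapply(seq_along(net$snapshots), function(k)
    louvain(net$snapshots[[k]], seed = k))
  grp <- temporal_grouping(parts)
  col <- commdy_infer(grp)
  sw_px <- which(mv$truth$labels[1, ] != mv$truth$labels[240, ]) - 1L
  centers <- vapply(net$snapshots, function(s) s$t + net$W / 2, numeric(1))
  expected_step <- which.min(abs(centers - 121))
  hits <- vapply(sw_px, function(p) {
    v <- col$individual_color[, match(p, col$individuals)]
    chg <- which(diff(v) != 0) + 1L
    length(chg) > 0 && any(abs(chg - expected_step) <= 2)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # non-switching pixels stay put
  stay_px <- setdiff(col$individuals, sw_px)
  n_switches <- vapply(stay_px, function(p) {
    v <- col$individual_color[, match(p, col$individuals)]
    sum(diff(v) != 0, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(n_switches > 0), 0.2)
})
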