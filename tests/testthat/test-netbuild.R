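toy_stack <- function(series_list, fps = 71) {
  # one row of pixels, one series per pixel
  n <- length(series_list[[1]])
  arr <- array(0, c(n, 1, length(series_list)))
  for (k in seq_along(series_list)) arr[, 1, k] <- series_list[[k]]
  image_stack(arr, fps)
}

test_that("frame counts convert to milliseconds as printed", {
  expect_identical(frames_to_ms(25, 71), 352L)
  expect_identical(frames_to_ms(200, 71), 2817L)
  expect_identical(frames_to_ms(0, 71), 0L)
  expect_error(frames_to_ms(10, 0), "positive")
})

test_that("window correlation graphs threshold one-sidedly on Pearson r", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5); c_ <- c(4, 3, 2, 1)
  st <- toy_stack(list(a, b, c_))
  g <- window_correlation_graph(st, t0 = 1, W = 4, theta = 0.7)
  # only {a, b} clears the threshold; c is anticorrelated with both
  expect_identical(nrow(g$edges), 1L)
  expect_identical(c(g$edges$i, g$edges$j), c(0L, 1L))
  expect_equal(g$edges$w, cor(a, b))
  expect_identical(g$nodes, 0:1)
  # identical non-constant series correlate at exactly 1
  g2 <- window_correlation_graph(toy_stack(list(a, a)), 1, 4, 0.7)
  expect_equal(g2$edges$w, 1.0)
  # anticorrelated pair carries no edge even at |r| = 1
  g3 <- window_correlation_graph(toy_stack(list(a, -a + 10)), 1, 4, 0.7)
  expect_identical(nrow(g3$edges), 0L)
  # zero-variance pixels are dropped from the snapshot
  g4 <- window_correlation_graph(toy_stack(list(a, a, rep(2, 4))), 1, 4, 0.7)
  expect_false(2L %in% g4$nodes)
  expect_error(window_correlation_graph(st, 3, 4, 0.7), "exceeds")
  expect_error(window_correlation_graph(st, 1, 4, 1.2), "theta")
})

test_that("snapshot counts follow the stride arithmetic", {
  st <- image_stack(array(rnorm(1000 * 2 * 2), c(1000, 2, 2)), fps = 71)
  expect_length(build_temporal_network(st, 50, 0.99, 1)$snapshots, 951)
  expect_length(build_temporal_network(st, 50, 0.99, 50)$snapshots, 20)
})

test_that("raising the threshold never adds edges", {
  sp <- synth_spec(height = 5, width = 5, n_frames = 60, n_communities = 2,
                   coupling = 0.7, noise_sd = 1, seed = 5)
  st <- dff(generate_movie(sp)$stack)
  thetas <- c(0.5, 0.7, 0.9)
  nets <- lapply(thetas, function(th)
    build_temporal_network(st, W = 50, theta = th, stride = 10))
  key <- function(net) lapply(net$snapshots, function(s)
    paste(s$edges$i, s$edges$j))
  for (k in 1:2) {
    lo <- key(nets[[k]]); hi <- key(nets[[k + 1]])
    for (t in seq_along(lo)) expect_true(all(hi[[t]] %in% lo[[t]]))
  }
})

test_that("degree maps normalize to the image maximum", {
  # one snapshot: star on 5 nodes (pixel row of 5)
  st <- toy_stack(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                       c(1, 2, 3), c(1, 2, 3)))
  net <- build_temporal_network(st, W = 3, theta = 0.7, stride = 1)
  # build a synthetic star by editing the snapshot's edges
  net$snapshots <- net$snapshots[1]
  net$snapshots[[1]]$edges <- data.frame(i = 0L, j = 1:4,
                                         w = rep(0.9, 4))
  net$snapshots[[1]]$nodes <- 0:4
  dm <- degree_map(net, around_peak = 1:3)
  expect_equal(as.vector(dm$raw), c(4, 1, 1, 1, 1))
  expect_equal(as.vector(dm$normalized), c(1, 0.25, 0.25, 0.25, 0.25))
  expect_error(degree_map(net, around_peak = 4000:4100), "no snapshots")
})

test_that("the peak frame is the argmax of the spatial average, earliest on ties", {
  # latent noise off: the activation transient alone should set the peak
  sp <- synth_spec(height = 5, width = 5, n_frames = 200, onset_frame = 31,
                   coupling = 0.9, noise_sd = 0.05, latent_noise = 0,
                   seed = 6)
  mv <- generate_movie(sp)
  pk <- find_peak(dff(mv$stack))
  planted <- 31 + round(0.150 * 71)
  expect_lte(abs(pk - planted), 2)
  # tie rule: constant stack gives frame 1; single frame gives 1
  expect_identical(find_peak(image_stack(array(1, c(5, 2, 2)), 10)), 1L)
  expect_identical(find_peak(image_stack(array(1, c(1, 2, 2)), 10)), 1L)
})

test_that("noiseless shared latents keep within-community weights at 1 for any window", {
  sp <- synth_spec(height = 4, width = 4, n_frames = 150, n_communities = 2,
                   coupling = 1, noise_sd = 0, seed = 2)
  mv <- generate_movie(sp)
  labs <- mv$truth$labels[1, ]
  for (W in c(25, 50, 100)) {
    g <- window_correlation_graph(dff(mv$stack), 1, W, 0.99)
    same <- labs[g$edges$i + 1] == labs[g$edges$j + 1]
    expect_true(all(abs(g$edges$w[same] - 1) < 1e-9))
    # every within-community pair is present
    n_within <- sum(choose(table(labs), 2))
    expect_gte(sum(same), n_within)
  }
})

test_that("the chosen operating point keeps pure-noise margins silent", {
  # planted communities plus an off-slice pure-noise margin (label 0):
  # at W = 50, theta = 0.7 fewer than 1% of edges touch the margin
  cmap <- commdynet:::stripe_map(8, 6, 2)
  cmap <- cbind(cmap, matrix(0L, 8, 3))   # 3 noise columns
  sp <- synth_spec(height = 8, width = 9, n_frames = 200, n_communities = 2,
                   community_map = cmap, coupling = 0.9, noise_sd = 0.1,
                   seed = 11)
  mv <- generate_movie(sp)
  st <- dff(mv$stack)
  noise_ids <- which(mv$truth$labels[1, ] == 0L) - 1L
  net <- build_temporal_network(st, W = 50, theta = 0.7, stride = 25)
  ed <- do.call(rbind, lapply(net$snapshots, function(s) s$edges))
  frac <- mean(ed$i %in% noise_ids | ed$j %in% noise_ids)
  expect_lt(frac, 0.01)
})

test_that("edge lists round-trip through the export format", {
  sp <- synth_spec(height = 4, width = 4, n_frames = 80, seed = 9)
  net <- build_temporal_network(dff(generate_movie(sp)$stack),
                                W = 50, theta = 0.7, stride = 15)
  dir <- withr::local_tempdir()
  write_temporal_network(net, file.path(dir, "net"))
  back <- read_temporal_network(file.path(dir, "net"))
  expect_equal(back$W, net$W)
  expect_equal(back$theta, net$theta)
  keep <- vapply(net$snapshots, function(s) nrow(s$edges) > 0, logical(1))
  orig <- net$snapshots[keep]
  expect_length(back$snapshots, length(orig))
  for (k in seq_along(orig)) {
    expect_equal(back$snapshots[[k]]$edges$i, orig[[k]]$edges$i)
    expect_equal(back$snapshots[[k]]$edges$w, orig[[k]]$edges$w,
                 tolerance = 1e-12)
  }
})
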