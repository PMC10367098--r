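test_that("threshold sets enforce the selenoprotein ordering", {
  th <- threshold_set()
  expect_equal(unname(th["generic"]), 70)
  expect_equal(unname(th["selenop"]), 100)
  expect_equal(unname(th["gpx3"]), 84.9)
  expect_equal(unname(th["idi"]), 64.8)
  expect_error(threshold_set(generic = 120), "ordering")
  expect_error(threshold_set(idi = -1), "positive")
})

test_that("grids are anchored, clipped and deterministic", {
  poly <- square_polygon(1)
  g <- build_grid(poly, spacing_m = 250)
  # 5x5 lattice on [0,1] at 0.25 km; boundary nodes count as inside
  expect_equal(nrow(g), 25)
  expect_equal(min(g$x), 0)
  expect_equal(attr(g, "spacing_km"), 0.25)
  expect_identical(g, build_grid(poly, spacing_m = 250))
  expect_error(build_grid(poly, spacing_m = 2000), "no grid nodes")
  expect_error(build_grid(poly, spacing_m = 0), "positive")
  # non-convex clipping: nodes in the notch of a C are dropped
  cs <- c_shape_polygon()
  gc <- build_grid(cs, spacing_m = 500)
  expect_false(any(gc$x > 2.4 & gc$y > 1.4 & gc$y < 2.6))
  # containment agrees with an independent oracle on the full lattice
  bb <- c(0, 4)
  cand <- expand.grid(x = seq(0, 4, 0.5), y = seq(0, 4, 0.5))
  oracle <- mgcv::in.out(rbind(cs, cs[1, ]), as.matrix(cand))
  on_edge <- dist_to_boundary(cand$x, cand$y, cs) < 1e-9
  ours <- point_in_polygon(cand$x, cand$y, cs)
  expect_equal(ours[!on_edge], oracle[!on_edge])
})

test_that("node counts scale inversely with spacing squared", {
  poly <- square_polygon(10)
  n1 <- nrow(build_grid(poly, spacing_m = 500))
  n2 <- nrow(build_grid(poly, spacing_m = 1000))
  expect_equal(n1 / n2, 4, tolerance = 0.25)
})

test_that("deficiency probabilities follow the Gaussian plug-in", {
  expect_equal(deficiency_probability(70, 25, 70), 0.5)
  expect_equal(deficiency_probability(70 - 1.645 * 5, 25, 70), 0.95,
               tolerance = 1e-3)
  # zero variance collapses to the indicator, ties at one half
  expect_equal(deficiency_probability(c(60, 80, 70), c(0, 0, 0), 70),
               c(1, 0, 0.5))
  expect_error(deficiency_probability(50, -4, 70), "negative")
  # monotone in the threshold, node-wise
  set.seed(14)
  pred <- rnorm(50, 60, 10); v <- runif(50, 1, 30)
  p1 <- deficiency_probability(pred, v, 64.8)
  p2 <- deficiency_probability(pred, v, 70)
  p3 <- deficiency_probability(pred, v, 84.9)
  expect_true(all(p1 <= p2 & p2 <= p3))
})

test_that("verbal classes partition [0,1] and match the calibrated scale", {
  expect_equal(as.character(verbal_classify(0.98)), "very likely")
  expect_equal(as.character(verbal_classify(0.5)), "about as likely as not")
  expect_equal(as.character(verbal_classify(1.0)), "virtually certain")
  expect_equal(as.character(verbal_classify(0)), "exceptionally unlikely")
  expect_error(verbal_classify(1.2), "0, 1")
  expect_error(verbal_classify(-0.1), "0, 1")
  sc <- ipcc_scale()
  expect_equal(sc$p_low[-1], sc$p_high[-nrow(sc)])  # contiguous bands
  expect_equal(sc$p_low[1], 0)
  expect_equal(sc$p_high[nrow(sc)], 1)
  set.seed(2)
  p <- c(runif(500), sc$p_high, sc$p_low)
  cls <- verbal_classify(p)
  expect_false(any(is.na(cls)))                     # every p gets a label
  expect_true(all(diff(as.integer(verbal_classify(sort(p)))) >= 0))  # monotone
})

test_that("probability labelling is monotone through the pipeline", {
  # composing the Gaussian plug-in with the verbal scale preserves order in
  # the standardized margin (T - pred)/sd
  margins <- seq(-4, 4, length.out = 41)
  p <- deficiency_probability(70 - margins * 5, 25, 70)
  expect_true(all(diff(as.integer(verbal_classify(p))) >= 0))
})

test_that("prevalence tables pool districts exactly", {
  expect_equal(
    prevalence_table(data.frame(group = "child", district = "A",
                                se = c(60, 80)))$pct_below_generic[1], 50)
  set.seed(99)
  rec <- data.frame(
    group = "child",
    district = rep(c("A", "B", "C"), c(30, 50, 20)),
    se = rlnorm(100, log(45), 0.4)
  )
  tab <- prevalence_table(rec)
  overall <- tab[tab$district == "Overall", ]
  by_d <- tab[tab$district != "Overall", ]
  for (col in grep("^pct_below_", names(tab), value = TRUE)) {
    expect_equal(overall[[col]], sum(by_d[[col]] * by_d$n) / sum(by_d$n),
                 tolerance = 1e-12)
  }
  # all below every threshold
  low <- data.frame(group = "wra", district = "A", se = c(10, 20))
  tl <- prevalence_table(low)
  expect_true(all(tl[1, grep("^pct_below_", names(tl))] == 100))
  # values at a threshold are not deficient (strict inequality)
  att <- data.frame(group = "wra", district = "A", se = c(70, 70))
  expect_equal(prevalence_table(att)$pct_below_generic[1], 0)
  expect_warning(
    prevalence_table(data.frame(group = "child", district = c("A", "B"),
                                se = c(50, NA))), "empty stratum")
})

test_that("surfaces average correctly over nodes or supplied locations", {
  surf <- structure(data.frame(x = c(0, 1), y = c(0, 0), value = c(0, 1)),
                    class = c("grid_surface", "data.frame"))
  expect_equal(average_surface(surf), 0.5)
  const <- structure(data.frame(x = 1:5, y = 1, value = 0.7),
                     class = c("grid_surface", "data.frame"))
  expect_equal(average_surface(const), 0.7)
  # nearest-node averaging at household locations
  at <- data.frame(x = c(0.1, 0.9), y = c(0, 0))
  expect_equal(average_surface(surf, at = at), 0.5)
  at2 <- data.frame(x = c(0.1, 0.2), y = c(0, 0))
  expect_equal(average_surface(surf, at = at2), 0)
})

test_that("kriged surfaces honour their model limits", {
  set.seed(20)
  rec <- data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10),
                    se = rnorm(40, 50, 5))
  poly <- square_polygon(10)
  grid <- build_grid(poly, spacing_m = 2000)
  nug <- variogram_model("nugget", c0 = var(rec$se), c1 = 0)
  s <- predict_surface(nug, rec, grid)
  expect_true(all(abs(s$prediction$value - mean(rec$se)) < 1e-8))
  # a node coinciding with a datum under zero nugget hits the datum
  m0 <- variogram_model("exponential", c0 = 0, c1 = 20, a = 3)
  rec2 <- rbind(rec[1:10, ], data.frame(x = 2, y = 2, se = 61))
  g1 <- data.frame(x = 2, y = 2)
  s2 <- predict_surface(m0, rec2, g1)
  expect_equal(s2$prediction$value, 61, tolerance = 1e-8)
  expect_equal(s2$variance$value, 0, tolerance = 1e-8)
})

test_that("denser sampling reduces the mean kriging variance", {
  m <- variogram_model("exponential", c0 = 40, c1 = 120, a = 5)
  poly <- square_polygon(50)
  grid <- build_grid(poly, spacing_m = 5000)
  deltas <- numeric(20)
  for (s in 1:20) {
    d1 <- reference_dataset(300 + s, n_clusters = 13, per_cluster = 10)
    d2 <- reference_dataset(600 + s, n_clusters = 26, per_cluster = 10)
    v1 <- mean(predict_surface(m, d1$records, grid)$variance$value)
    v2 <- mean(predict_surface(m, d2$records, grid)$variance$value)
    deltas[s] <- v1 - v2
  }
  expect_gt(mean(deltas > 0), 0.9)
  expect_gt(mean(deltas), 0)
})
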