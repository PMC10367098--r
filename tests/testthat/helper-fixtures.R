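# Shared fixtures: all synthetic, generated at test time.

# One clustered exponential-field dataset matching the package's reference
# simulation conditions (c0 = 40, c1 = 120, a = 5 km, 250 points in 25
# clusters of 10 inside a 50 km square).
reference_dataset <- function(seed, n_clusters = 25, per_cluster = 10,
                              c0 = 40, c1 = 120, a = 5, mean = 37,
                              family = "exponential", size_km = 50) {
  poly <- square_polygon(size_km)
  ss <- sampling_spec(poly, n_clusters = n_clusters,
                      per_cluster = per_cluster, cluster_sd = 0.5)
  fs <- field_spec(mean, family, c0 = c0, c1 = c1, a = a)
  loc <- sample_locations(ss, seed = child_seed(seed, 1L))
  z <- simulate_grf(loc[, c("x", "y")], fs, seed = child_seed(seed, 2L))
  list(records = data.frame(id = as.character(seq_along(z)),
                            x = loc$x, y = loc$y, se = z),
       truth = fs, polygon = poly)
}

# C-shaped (non-convex) polygon with a notch on the right side.
c_shape_polygon <- function() {
  as_ring <- getFromNamespace("as_ring", "sekrige")
  as_ring(cbind(
    x = c(0, 4, 4, 2, 2, 4, 4, 0),
    y = c(0, 0, 1, 1, 3, 3, 4, 4)
  ))
}

# Brute-force ordinary kriging: build the bordered system with explicit
# loops and solve it with qr.solve - independent of the package's
# vectorised path.
ok_oracle <- function(model, records, target) {
  n <- nrow(records)
  gamma_h <- function(h) {
    if (h == 0) return(0)
    model_gamma(model, h)
  }
  gamma_rec <- function(h) {
    # semivariance between distinct measurements (nugget at h = 0)
    model$c0 + model$c1 * (1 - switch(model$family,
      exponential = exp(-h / model$a),
      spherical = if (h < model$a) 1 - 1.5 * h / model$a + 0.5 * (h / model$a)^3 else 0,
      nugget = as.numeric(h == 0)))
  }
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        h <- sqrt((records$x[i] - records$x[j])^2 + (records$y[i] - records$y[j])^2)
        A[i, j] <- gamma_rec(h)
      }
    }
    A[i, n + 1] <- 1
    A[n + 1, i] <- 1
  }
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- sqrt((records$x[i] - target[1])^2 + (records$y[i] - target[2])^2)
    b[i] <- gamma_h(h)
  }
  b[n + 1] <- 1
  sol <- qr.solve(A, b)
  lambda <- sol[seq_len(n)]
  list(prediction = sum(lambda * records$se),
       variance = sum(lambda * b[seq_len(n)]) + sol[n + 1],
       weights = lambda)
}
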