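test_that("collinear same-type neighbors resolve ties by ascending cell id", {
  tab <- tiny_table(x = c(0, 10, 20, 30), y = rep(0, 4),
                    markers = list(M1 = c(1, 2, 3, 4)))
  labels <- rep("A", 4)
  nn <- knn_of_type(tab, labels, "A", "A", kmax = 1)
  # cell 2 ties between 1 and 3, cell 3 between 2 and 4: lower id wins
  expect_equal(nn$nn_row[, 1], c(2L, 1L, 2L, 3L))
  expect_equal(nn$nn_dist[, 1], rep(10, 4))
})

test_that("k-NN of type matches the exhaustive oracle on random tables", {
  for (seed in 1:6) {
    rt <- random_typed_table(n = 150 + 25 * seed, seed = seed)
    for (k in c(1, 5, 20)) {
      fast <- knn_of_type(rt$table, rt$labels, "A", "B", kmax = k)
      slow <- brute_knn(rt$table, rt$labels, "A", "B", kmax = k)
      expect_identical(fast$a_rows, slow$a_rows)
      expect_identical(fast$nn_row, slow$nn_row)
      expect_equal(fast$nn_dist, slow$nn_dist, tolerance = 1e-10)
    }
  }
})

test_that("insufficient type-B cells mark high orders unavailable", {
  tab <- tiny_table(x = c(0, 5, 9), y = c(0, 0, 0))
  labels <- c("A", "A", "B")
  nn <- knn_of_type(tab, labels, "A", "B", kmax = 2)
  expect_false(anyNA(nn$nn_row[, 1]))
  expect_true(all(is.na(nn$nn_row[, 2])))
})

test_that("correlation at k=1 matches the hand-computed Pearson r", {
  tab <- tiny_table(x = c(0, 10, 20, 30), y = rep(0, 4),
                    markers = list(M1 = exp(c(1, 2, 3, 4)) - 1))
  labels <- rep("A", 4)
  q <- correlation_query("A", "A", "M1", "M1", kmax = 1, min_pairs = 2)
  cv <- correlation_curve(tab, labels, q)
  # pairs (1->2),(2->1),(3->2),(4->3): u = 1:4, v = c(2,1,2,3)
  expect_equal(cv$pearson_r[1], 2 / sqrt(10), tolerance = 1e-12)
  expect_equal(cv$mean_distance_um[1], 10)
  expect_equal(cv$n_pairs[1], 4L)
})

test_that("correlation curve matches the brute-force oracle on random tables", {
  for (seed in 7:9) {
    rt <- random_typed_table(n = 200, seed = seed)
    q <- correlation_query("A", "B", "M1", "M2", kmax = 20, min_pairs = 5)
    expect_equal(as.data.frame(correlation_curve(rt$table, rt$labels, q)),
                 brute_curve(rt$table, rt$labels, q), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # binary variable route
    qb <- correlation_query("A", "All", "M1", "B", kmax = 10, min_pairs = 5)
    expect_equal(as.data.frame(correlation_curve(rt$table, rt$labels, qb)),
                 brute_curve(rt$table, rt$labels, qb), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("orders with fewer pairs than min_pairs are undefined", {
  rt <- random_typed_table(n = 40, seed = 10)
  q <- correlation_query("A", "B", "M1", "M2", kmax = 5, min_pairs = 1000)
  cv <- correlation_curve(rt$table, rt$labels, q)
  expect_true(all(is.na(cv$pearson_r)))
  expect_true(all(cv$n_pairs < 1000))
})

test_that("curves are invariant under rigid motions of the coordinates", {
  rt <- random_typed_table(n = 250, seed = 11)
  q <- correlation_query("A", "B", "M1", "M2", kmax = 15, min_pairs = 10)
  cv0 <- correlation_curve(rt$table, rt$labels, q)
  th <- 0.7
  rot <- rt$table
  x <- rt$table$data$x_um; y <- rt$table$data$y_um
  rot$data$x_um <- cos(th) * x - sin(th) * y + 500
  rot$data$y_um <- sin(th) * x + cos(th) * y - 120
  cv1 <- correlation_curve(rot, rt$labels, q)
  expect_equal(cv1$pearson_r, cv0$pearson_r, tolerance = 1e-9)
  expect_equal(cv1$mean_distance_um, cv0$mean_distance_um, tolerance = 1e-9)
})

test_that("constant curve fits c = r with no decay", {
  cv <- structure(
    data.frame(k = 1:3, mean_distance_um = c(10, 20, 30),
               pearson_r = c(0.5, 0.5, 0.5), n_pairs = 100L),
    class = c("correlation_curve", "data.frame")
  )
  f <- fit_exponential(cv)
  expect_equal(f$c, 0.5)
  expect_equal(f$b, 0)
  expect_true(f$significant)
  expect_equal(f$c_effective, 0.5)
})

test_that("noiseless exponential points are recovered to 1e-6", {
  d <- seq(10, 200, by = 10)
  cv <- data.frame(k = seq_along(d), mean_distance_um = d,
                   pearson_r = 0.8 * exp(-0.02 * d), n_pairs = 100L)
  f <- fit_exponential(cv)
  expect_equal(f$c, 0.8, tolerance = 1e-6)
  expect_equal(f$b, -0.02, tolerance = 1e-6)
  expect_true(f$significant)
})

test_that("an all-zero curve is insignificant with zero effective strength", {
  cv <- data.frame(k = 1:10, mean_distance_um = seq(10, 100, by = 10),
                   pearson_r = 0, n_pairs = 50L)
  f <- fit_exponential(cv)
  expect_false(f$significant)
  expect_equal(f$c_effective, 0)
})

test_that("a rising curve warns about positive decay rate", {
  cv <- data.frame(k = 1:5, mean_distance_um = seq(10, 50, by = 10),
                   pearson_r = c(0.1, 0.15, 0.2, 0.26, 0.3), n_pairs = 50L)
  expect_warning(fit_exponential(cv), "positive")
})

test_that("fewer than 3 defined points is an error", {
  cv <- data.frame(k = 1:3, mean_distance_um = c(10, 20, NA),
                   pearson_r = c(0.5, 0.4, NA), n_pairs = 50L)
  expect_error(fit_exponential(cv), ">= 3")
})

test_that("interaction class is high only when every core is significant", {
  s <- data.frame(patient_id = c("p1", "p2", "p2", "p3", "p3"),
                  significant = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  ic <- interaction_class(s)
  expect_equal(ic$class[ic$patient_id == "p1"], "high")
  expect_equal(ic$class[ic$patient_id == "p2"], "low")
  expect_equal(ic$class[ic$patient_id == "p3"], "high")
  expect_equal(ic$n_cores[ic$patient_id == "p2"], 2L)
})
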