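# independently coded exhaustive sorted-split oracle (naive per-split sums)
brute_two_means <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- list(sse = Inf)
  for (k in 1:(n - 1)) {
    left <- x[1:k]
    right <- x[(k + 1):n]
    sse <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (sse < best$sse) {
      best <- list(sse = sse, centers = c(mean(left), mean(right)), k = k)
    }
  }
  best
}

test_that("two_means_1d handles point masses and degenerate input", {
  res <- two_means_1d(c(0, 0, 1, 1))
  expect_equal(res$centers, c(0, 1))
  expect_equal(res$within_sse, 0)
  expect_equal(sort(res$sizes), c(2, 2))
  expect_error(two_means_1d(rep(0.5, 10)), "degenerate clustering")
  expect_error(two_means_1d(0.5), "degenerate")
})

test_that("two_means_1d equals the exhaustive sorted-split oracle", {
  set.seed(3)
  for (n in c(5, 20, 137, 1000)) {
    values <- runif(n)
    res <- two_means_1d(values)
    oracle <- brute_two_means(values)
    expect_equal(res$within_sse, oracle$sse, tolerance = 1e-10)
    expect_equal(res$centers, oracle$centers, tolerance = 1e-10)
    # optimal 1-D clusters are contiguous in sorted order
    o <- order(values)
    expect_true(all(diff(res$labels[o]) >= 0))
    # labels consistent with the oracle's split size
    expect_equal(sum(res$labels == 1), oracle$k)
  }
})

test_that("two_means_1d matches Lloyd k-means with many restarts", {
  set.seed(8)
  values <- c(rnorm(30, 1, 0.05), rnorm(20, 0.6, 0.1))
  res <- two_means_1d(values)
  km <- stats::kmeans(values, centers = 2, nstart = 50)
  expect_equal(res$within_sse, km$tot.withinss, tolerance = 1e-8)
  expect_equal(sort(res$centers), sort(as.numeric(km$centers)),
               tolerance = 1e-8)
})

test_that("defective threshold is the WT-like class mean minus one sd", {
  expect_equal(defective_threshold(0.89, 0.07), 0.82)
  expect_equal(defective_threshold(0.91, 0), 0.91)
  set.seed(11)
  x <- rnorm(30, 1.0, 0.05)
  # independently coded summary: running sums
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  cls <- classify_interface(score_table_of(31:62, c(x, 0.1, 0.12)))
  # the high class here is the 30 draws; its mean - sd must match the summary
  expect_equal(cls$class1_mean - cls$class1_sd, m - s, tolerance = 1e-12)
  expect_equal(defective_threshold(cls), cls$threshold)
})

test_that("interface calls require a score strictly below the threshold", {
  sc <- score_table_of(31:50, rep(1.0, 20), window = c(31, 50))
  calls <- call_interface_residues(sc, threshold = 0.82)
  expect_length(calls$interface, 0)
  expect_length(calls$uncovered, 0)

  # ties at the threshold are NOT called ("lower than")
  sc2 <- score_table_of(31:33, c(0.82, 0.819, 1.0), window = c(31, 35))
  calls2 <- call_interface_residues(sc2, threshold = 0.82)
  expect_equal(calls2$interface, 32L)
  expect_equal(calls2$uncovered, c(34L, 35L))

  expect_error(call_interface_residues(score_table_of(integer(), numeric(),
                                                      window = c(31, 35)),
                                       0.82), "empty")
})

test_that("lowering any score never removes a position from the call set", {
  set.seed(13)
  vals <- runif(30, 0.4, 1.1)
  sc <- score_table_of(31:60, vals, window = c(31, 60))
  base_calls <- call_interface_residues(sc, threshold = 0.8)$interface
  for (i in sample.int(30, 10)) {
    vals2 <- vals
    vals2[i] <- vals2[i] - runif(1, 0, 0.5)
    sc2 <- score_table_of(31:60, vals2, window = c(31, 60))
    calls2 <- call_interface_residues(sc2, threshold = 0.8)$interface
    expect_true(all(base_calls %in% calls2))
  }
})

test_that("classification fits on Asp but calls from Asp or Arg", {
  # position 40 has no Asp mutant; its Arg mutant alone must make it callable
  wt_like <- c(0.95, 1.02, 0.98, 1.0, 0.97, 1.03, 0.99, 1.01, 0.96)
  asp <- score_table_of(c(31:39, 41:50), c(wt_like, rep(0.55, 10)),
                        window = c(31, 50))
  arg <- score_table_of(40, 0.3, mut_aa = "R", window = c(31, 50))
  sc <- structure(dplyr::bind_rows(asp, arg),
                  class = class(asp), sequence_window = c(31L, 50L))
  cls <- classify_interface(sc)
  expect_gt(cls$class1_mean, cls$class2_mean)
  expect_lt(cls$threshold, cls$class1_mean)
  expect_true(40L %in% cls$interface_calls)
  expect_length(cls$uncovered, 0)
  # every considered mutant is labelled
  expect_equal(nrow(cls$labels), 20)
  expect_true(all(cls$labels$class %in% 1:2))
  # tidy/glance surface the partition
  expect_true(all(c("class", "called", "interface") %in% names(tidy(cls))))
  expect_equal(glance(cls)$threshold, cls$threshold)
})

test_that("synthetic interface recovery is accurate at default noise", {
  truth <- ground_truth()
  seeds <- 1:20
  prec <- rec <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_scan_panel(truth, positions = 31:82, seed = seeds[i])
    cls <- classify_interface(score_panel(sim$panel))
    truth_pos <- unique(sim$truth_labels$position[sim$truth_labels$interface])
    called <- cls$interface_calls
    tp <- length(intersect(called, truth_pos))
    prec[i] <- if (length(called) > 0) tp / length(called) else 0
    rec[i] <- tp / length(truth_pos)
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})
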