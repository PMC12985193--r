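test_that("Manhattan distance matches its definition and the oracle", {
  expect_equal(manhattan_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(manhattan_distance(c(0, 0), c(1, 2)), 3)
  withr::with_seed(11, {
    for (i in 1:25) {
      u <- rnorm(5); v <- rnorm(5)
      expect_equal(manhattan_distance(u, v), bf_minkowski(u, v, 1))
      expect_equal(minkowski_distance(u, v, p = 2), bf_minkowski(u, v, 2))
      expect_equal(minkowski_distance(u, v, p = 3.5),
                   bf_minkowski(u, v, 3.5))
    }
  })
})

test_that("mismatched feature vectors are a contract error", {
  expect_error(manhattan_distance(c(a = 1, b = 2), c(b = 1, a = 2)),
               "mismatched feature names")
  expect_error(manhattan_distance(1:2, 1:3), "differ in length")
  expect_error(minkowski_distance(1:2, 2:3, p = 0.5), "p must be")
})

test_that("Manhattan satisfies the metric axioms on random points", {
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
      dxy <- manhattan_distance(x, y)
      expect_gte(dxy, 0)
      expect_equal(dxy, manhattan_distance(y, x))
      expect_equal(manhattan_distance(x, x), 0)
      expect_true(dxy > 0) # distinct random points
      expect_lte(manhattan_distance(x, z),
                 dxy + manhattan_distance(y, z) + 1e-12)
    }
  })
})

test_that("nearest-label distance is 0 for an exact training duplicate", {
  co <- random_cohort(12, seed = 2)
  i <- which(co$labels == "HR")[1]
  x <- co$features[i, ]
  expect_equal(nearest_label_distance(x, co, "HR"), 0)
})

test_that("nearest-label distances match exhaustive enumeration, k = 1 and 3", {
  for (seed in 1:20) {
    co <- random_cohort(20, n_features = 3, seed = seed)
    probe <- withr::with_seed(seed + 1000, rnorm(3))
    for (lab in c("LR", "HR")) {
      expect_equal(nearest_label_distance(probe, co, lab, k = 1),
                   bf_nearest_label(probe, co, lab, k = 1))
      expect_equal(nearest_label_distance(probe, co, lab, k = 3),
                   bf_nearest_label(probe, co, lab, k = 3))
      # k = 1 lower-bounds the k-averaged variant
      expect_lte(nearest_label_distance(probe, co, lab, k = 1),
                 nearest_label_distance(probe, co, lab, k = 3) + 1e-12)
    }
  }
})

test_that("self-pairing is excluded for cohort members and k respects group size", {
  co <- random_cohort(10, seed = 5)
  i <- which(co$labels == "LR")[1]
  d_self_excluded <- nearest_label_distance(co$features[i, ], co, "LR",
                                            exclude_id = co$case_id[i])
  expect_gt(d_self_excluded, 0)
  n_hr <- sum(co$labels == "HR")
  expect_error(nearest_label_distance(rnorm(2), co, "HR", k = n_hr + 1L),
               "label 'HR'")
})

test_that("a two-member group has all five quantiles equal to its one distance", {
  tbl <- tibble::tibble(case_id = c("a", "b", "c", "d"),
                        label = c("LR", "LR", "HR", "HR"),
                        f1 = c(0, 3, 10, 10), f2 = c(0, 4, 0, 5))
  co <- labeled_cohort(tbl)
  for (def in c("all-pairs", "nearest-only")) {
    q <- within_group_quantiles(co, "LR", definition = def)
    expect_equal(unname(q), rep(7, 5))
  }
})

test_that("within-group quantiles match brute force for both populations", {
  for (seed in 1:15) {
    co <- random_cohort(14, seed = seed)
    for (lab in c("LR", "HR")) {
      M <- co$features[co$labels == lab, , drop = FALSE]
      if (nrow(M) < 2) next
      expect_equal(within_group_quantiles(co, lab, "all-pairs"),
                   bf_quantiles(bf_within_all_pairs(M)))
      expect_equal(within_group_quantiles(co, lab, "nearest-only"),
                   bf_quantiles(bf_within_nearest_only(M)))
    }
  }
})

test_that("directed mean nearest distances match the double-loop oracle", {
  for (seed in 1:15) {
    co <- random_cohort(16, n_features = 2, seed = seed)
    A <- co$features[co$labels == "LR", , drop = FALSE]
    B <- co$features[co$labels == "HR", , drop = FALSE]
    expect_equal(mean_nearest_cross_distance(co, "LR", "HR"),
                 bf_mean_nearest_cross(A, B))
    expect_equal(mean_nearest_cross_distance(co, "HR", "LR"),
                 bf_mean_nearest_cross(B, A))
    expect_equal(mean_nearest_cross_distance(co, "LR", "LR"),
                 bf_mean_nearest_cross(A, A, same = TRUE))
  }
})

test_that("two singleton groups give symmetric directed means", {
  tbl <- tibble::tibble(case_id = c("a", "b"), label = c("LR", "HR"),
                        f1 = c(0, 3), f2 = c(0, 4))
  co <- labeled_cohort(tbl)
  expect_equal(mean_nearest_cross_distance(co, "LR", "HR"), 7)
  expect_equal(mean_nearest_cross_distance(co, "HR", "LR"), 7)
})

test_that("directed means are asymmetric for a tight cluster vs an outlier", {
  # five tight LR points near the origin; one HR case far away on the x axis.
  # every LR case's nearest HR is the lone outlier (mean ~ 10) while the
  # HR case's nearest LR is the cluster edge (~ 9.8): direction matters.
  tbl <- tibble::tibble(
    case_id = sprintf("c%d", 1:6),
    label = c(rep("LR", 5), "HR"),
    f1 = c(0, 0.1, -0.1, 0.05, -0.05, 10),
    f2 = c(0, 0.05, 0.02, -0.1, 0.08, 0))
  co <- labeled_cohort(tbl)
  lr_to_hr <- mean_nearest_cross_distance(co, "LR", "HR")
  hr_to_lr <- mean_nearest_cross_distance(co, "HR", "LR")
  expect_equal(lr_to_hr,
               mean(10 - tbl$f1[1:5] + abs(tbl$f2[1:5])))
  expect_equal(hr_to_lr, min(10 - tbl$f1[1:5] + abs(tbl$f2[1:5])))
  expect_gt(lr_to_hr, hr_to_lr)
})

test_that("the distance summary is internally consistent and exportable", {
  co <- random_cohort(24, seed = 9)
  s <- distance_summary(co, definition = "all-pairs")
  for (lab in colnames(s$quantiles)) {
    expect_false(is.unsorted(s$quantiles[, lab]))
  }
  expect_equal(s$mean_nearest["LR", "HR"],
               mean_nearest_cross_distance(co, "LR", "HR"))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_distance_summary(s, csv = csv, json = json)
  got <- utils::read.csv(csv)
  expect_equal(nrow(got), 9L) # 5 quantile rows + 4 directed means
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$quantiles$LR$median, unname(s$quantiles["median", "LR"]))
})
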