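test_that("generation is a pure function of spec and seed", {
  spec <- scenario_spec("CLUSTERED_NEG_SPARSE_POS", seed = 17)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, p1)
  write_cohort_csv(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(
    generate_cohort(scenario_spec("CLUSTERED_NEG_SPARSE_POS",
                                  seed = 18))$features,
    a$features))
})

test_that("the vanishing-spread limit collapses clusters onto their centers", {
  spec <- scenario_spec("TWO_SEPARATED_CLUSTERS", n_negative = 6,
                        n_positive = 6, spread = c(1e-9, 1e-9), seed = 2)
  co <- generate_cohort(spec)
  expect_lt(max(within_group_quantiles(co, "LR", "all-pairs")), 1e-6)
  expect_lt(max(within_group_quantiles(co, "HR", "all-pairs")), 1e-6)
  expect_equal(mean_nearest_cross_distance(co, "LR", "HR"),
               manhattan_distance(spec$centers[1, ], spec$centers[2, ]),
               tolerance = 1e-5)
})

test_that("spec validation rejects invalid fields", {
  expect_error(scenario_spec("EVEN_COVERAGE", n_negative = 1), ">= 2 cases")
  expect_error(scenario_spec("EVEN_COVERAGE", spread = c(0, 1)),
               "spreads must be > 0")
  expect_error(scenario_spec("NO_SUCH_REGIME"), "arg")
  expect_error(scenario_spec("EVEN_COVERAGE",
                             centers = matrix(0, 3, 2)), "2 x n_features")
})

test_that("the clustered regime makes the negative group tighter (seed 1)", {
  co <- generate_cohort(scenario_spec("CLUSTERED_NEG_SPARSE_POS", seed = 1))
  expect_lt(within_group_quantiles(co, "LR", "all-pairs")[["median"]],
            within_group_quantiles(co, "HR", "all-pairs")[["median"]])
})

test_that("even coverage gives the two groups matching median spreads", {
  for (seed in 1:10) {
    co <- generate_cohort(scenario_spec("EVEN_COVERAGE", seed = seed))
    m_lr <- within_group_quantiles(co, "LR", "all-pairs")[["median"]]
    m_hr <- within_group_quantiles(co, "HR", "all-pairs")[["median"]]
    expect_lt(abs(m_lr - m_hr) / max(m_lr, m_hr), 0.20)
  }
})

test_that("separated clusters leave empty space between the groups", {
  for (seed in 1:10) {
    co <- generate_cohort(scenario_spec("TWO_SEPARATED_CLUSTERS",
                                        seed = seed))
    inter <- c(mean_nearest_cross_distance(co, "LR", "HR"),
               mean_nearest_cross_distance(co, "HR", "LR"))
    intra <- c(mean_nearest_cross_distance(co, "LR", "LR"),
               mean_nearest_cross_distance(co, "HR", "HR"))
    expect_true(all(outer(inter, intra, ">")))
  }
})

test_that("the crescent regime defeats a linear boundary that 1-NN handles", {
  co <- generate_cohort(scenario_spec("NONLINEAR_BOUNDARY", n_negative = 60,
                                      n_positive = 60, seed = 5))
  f <- fit_reference_classifier(co)
  cfg <- decision_config(0.5)
  pred_lin <- predict_class(f(data.frame(co$features, check.names = FALSE)),
                            cfg)
  acc_lin <- mean(pred_lin == co$labels)
  # leave-self-out 1-NN on the same cohort
  nd <- neighbor_distances(data.frame(case_id = co$case_id, co$features,
                                      check.names = FALSE), co)
  acc_nn <- mean(ifelse(nd$d_negative < nd$d_positive, "LR", "HR") ==
                   co$labels)
  expect_lt(acc_lin, acc_nn)
  expect_lt(acc_lin, 0.95) # interleaved arcs are not linearly separable
})

test_that("in-cluster probes score their cluster's label as less uncertain", {
  co <- generate_cohort(scenario_spec("TWO_SEPARATED_CLUSTERS", seed = 6))
  for (lab in c("LR", "HR")) {
    probes <- generate_boundary_cases(co, "IN_CLUSTER", n = 5, seed = 3,
                                      label = lab)
    uq <- score_cases(neighbor_distances(probes, co))
    if (lab == "LR") {
      expect_true(all(uq$uq_negative < uq$uq_positive))
    } else {
      expect_true(all(uq$uq_positive < uq$uq_negative))
    }
  }
})

test_that("empty-space outliers are farther than any within-group distance", {
  co <- generate_cohort(scenario_spec("CLUSTERED_NEG_SPARSE_POS", seed = 9))
  maxwg <- max(within_group_quantiles(co, "LR", "all-pairs")[["max"]],
               within_group_quantiles(co, "HR", "all-pairs")[["max"]])
  probes <- generate_boundary_cases(co, "OUTLIER_EMPTY_SPACE", n = 5,
                                    seed = 4)
  nd <- neighbor_distances(probes, co)
  expect_true(all(pmin(nd$d_negative, nd$d_positive) > maxwg))
})

test_that("near-boundary probes have nearly tied per-label distances", {
  co <- generate_cohort(scenario_spec("TWO_SEPARATED_CLUSTERS", seed = 10))
  probes <- generate_boundary_cases(co, "NEAR_BOUNDARY", n = 5, seed = 5)
  nd <- neighbor_distances(probes, co)
  gap <- abs(nd$d_negative - nd$d_positive) /
    pmax(nd$d_negative, nd$d_positive)
  expect_true(all(gap < 0.01))
  expect_error(generate_boundary_cases(co, "NEAR_BOUNDARY", n = 0),
               "positive integer")
})
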