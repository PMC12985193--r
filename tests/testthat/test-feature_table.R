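write_csv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a labelled CSV parses into cases with features and labels", {
  path <- write_csv_lines(c("id,sphericity,p90,label",
                            "a,0.80,110,LR", "b,0.55,190,HR",
                            "c,0.71,150,LR"))
  tbl <- read_feature_table(path, id_col = "id", label_col = "label")
  expect_s3_class(tbl, "case_table")
  expect_equal(nrow(tbl), 3L)
  expect_equal(attr(tbl, "feature_names"), c("sphericity", "p90"))
  expect_equal(tbl$label, c("LR", "HR", "LR"))
  expect_equal(tbl$sphericity, c(0.80, 0.55, 0.71))
})

test_that("label column is optional and TSV is accepted", {
  path <- write_csv_lines(c("case_id\tf1\tf2", "x\t1\t2", "y\t3\t4"))
  tbl <- read_feature_table(path, sep = "\t")
  expect_false("label" %in% names(tbl))
  expect_equal(attr(tbl, "feature_names"), c("f1", "f2"))
})

test_that("schema and validation errors are specific", {
  dup <- write_csv_lines(c("case_id,f1,label", "a,1,LR", "a,2,HR"))
  expect_error(read_feature_table(dup, label_col = "label"),
               "duplicated case_id: a")

  nocol <- write_csv_lines(c("case_id,f1", "a,1"))
  expect_error(read_feature_table(nocol, label_col = "label"),
               "missing.*label")

  bad <- write_csv_lines(c("case_id,f1,f2", "a,1,2", "b,oops,3", "c,4,"))
  expect_error(read_feature_table(bad), "case\\(s\\): b, c")

  badlab <- write_csv_lines(c("case_id,f1,label", "a,1,LR", "b,2,MAYBE"))
  expect_error(read_feature_table(badlab, label_col = "label"),
               "unknown label value")
})

test_that("a labelled cohort validates labels and fits scaling on itself", {
  path <- write_csv_lines(c("case_id,f1,f2,label",
                            "a,0,0,LR", "b,2,4,LR", "c,10,20,HR"))
  tbl <- read_feature_table(path, label_col = "label")
  co <- labeled_cohort(tbl, scaling = "minmax")
  expect_equal(unname(range(co$features)), c(0, 1))
  expect_equal(co$scaling$method, "minmax")
  # scaling parameters come from the cohort, so a new case can leave [0,1]
  sc <- distuq:::scale_like_cohort(co, matrix(c(20, 40), 1,
                                              dimnames = list(NULL,
                                                              c("f1", "f2"))))
  expect_true(all(sc > 1))

  one_label <- tbl[tbl$label == "LR", ]
  attr(one_label, "feature_names") <- c("f1", "f2")
  expect_error(labeled_cohort(one_label), "at least one case of each label")
})

test_that("reports round-trip through CSV and JSON-lines at 2 decimals", {
  reports <- tibble::tibble(
    case_id = c("p1", "p2"),
    predicted_class = c("HR", "LR"),
    probability_positive = c(0.48, 0.10),
    distance_to_nearest_negative = c(0.19, 0.21),
    distance_to_nearest_positive = c(0.28, 0.99),
    uq_negative = c(0.128928, 0.044545),
    uq_positive = c(0.412631, Inf),
    final_class = c("LR", "LR"),
    traffic_light = c("AMBER", "AMBER"))

  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile()
    write_reports(reports, path, format = fmt)
    back <- read_reports(path, format = fmt)
    expect_equal(nrow(back), 2L)
    expect_equal(names(back), names(reports))
    for (col in names(reports)) {
      v <- reports[[col]]
      if (is.numeric(v)) {
        expect_equal(back[[col]], ifelse(is.finite(v), round(v, 2), v),
                     tolerance = 1e-12)
      } else {
        expect_equal(back[[col]], v)
      }
    }
  }
})

test_that("an infinite score serializes as the literal token inf", {
  reports <- tibble::tibble(case_id = "p", predicted_class = "HR",
                            probability_positive = 1,
                            distance_to_nearest_negative = 0,
                            distance_to_nearest_positive = 1,
                            uq_negative = 0, uq_positive = Inf,
                            final_class = "LR", traffic_light = "RED")
  path <- withr::local_tempfile()
  write_reports(reports, path, format = "csv")
  expect_match(paste(readLines(path), collapse = "\n"), "inf")
})

test_that("report writing refuses an empty report set", {
  expect_error(write_reports(tibble::tibble(), withr::local_tempfile()),
               "no reports")
})

test_that("round-trip of generated cohorts preserves features and labels", {
  for (seed in 1:5) {
    co <- generate_cohort(scenario_spec("CLUSTERED_NEG_SPARSE_POS",
                                        n_negative = 8, n_positive = 5,
                                        seed = seed))
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort_csv(co, path)
    back <- labeled_cohort(read_feature_table(path, label_col = "label"))
    expect_equal(back$labels, co$labels)
    expect_equal(unname(back$features), unname(co$features),
                 tolerance = 1e-12)
  }
})
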