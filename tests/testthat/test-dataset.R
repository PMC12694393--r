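test_that("windowing floors to complete windows and keeps raw values", {
  rr <- tibble::tibble(subject_id = "s", rhythm = "SR",
                       rr_s = seq(0.5, by = 0.001, length.out = 60))
  w <- window_rr(rr, 25)
  expect_equal(nrow(w), 2) # floor(60/25), last 10 values dropped
  expect_equal(unname(unlist(w[1, grep("^rr_", names(w))])), rr$rr_s[1:25])
  expect_equal(unname(unlist(w[2, grep("^rr_", names(w))])), rr$rr_s[26:50])
  expect_equal(unique(w$label), 0L)

  rr250 <- tibble::tibble(subject_id = "s", rhythm = "AF", rr_s = runif(250, .4, 1))
  expect_equal(nrow(window_rr(rr250, 100)), 2)
  expect_equal(unique(window_rr(rr250, 100)$label), 1L)

  rr24 <- tibble::tibble(subject_id = "s", rhythm = "SR", rr_s = runif(24, .4, 1))
  expect_equal(nrow(window_rr(rr24, 25)), 0)

  # stride below the window length yields overlapping windows
  expect_equal(nrow(window_rr(rr, 25, stride = 5)), 8)
})

test_that("subject-wise folds are disjoint, sized 20/3 and reproducible", {
  subjects <- sprintf("S%02d", 1:23)
  folds <- assign_subject_folds(subjects, seed = 42)
  test_sets <- lapply(split(folds, folds$fold),
                      function(f) f$subject_id[f$role == "test"])
  expect_equal(lengths(test_sets), setNames(rep(3L, 5), 1:5))
  for (f in split(folds, folds$fold)) {
    expect_equal(sum(f$role == "train"), 20)
    expect_length(intersect(f$subject_id[f$role == "train"],
                            f$subject_id[f$role == "test"]), 0)
  }
  all_test <- unlist(test_sets)
  expect_equal(length(unique(all_test)), 15) # pairwise disjoint triples
  expect_identical(folds, assign_subject_folds(subjects, seed = 42))
  expect_false(identical(folds, assign_subject_folds(subjects, seed = 43)))
})

test_that("15 subjects over 5 folds puts each subject in exactly one test set", {
  folds <- assign_subject_folds(sprintf("S%02d", 1:15), seed = 1)
  test_count <- table(folds$subject_id[folds$role == "test"])
  expect_true(all(test_count == 1))
  expect_equal(length(test_count), 15)
  expect_error(assign_subject_folds(sprintf("S%02d", 1:14), seed = 1),
               "at least 15")
})

test_that("balancing down-samples the majority class and preserves order", {
  w <- tibble::tibble(label = rep(c(0L, 1L), c(1000, 600)), id = 1:1600)
  b <- balance_classes(w, seed = 9)
  expect_equal(sum(b$label == 0), 600)
  expect_equal(sum(b$label == 1), 600)
  expect_false(is.unsorted(b$id)) # survivor order preserved
  even <- tibble::tibble(label = rep(c(0L, 1L), each = 600))
  expect_identical(balance_classes(even, seed = 9), even)
  expect_warning(out <- balance_classes(tibble::tibble(label = rep(0L, 500)), 1),
                 "one class absent")
  expect_equal(nrow(out), 0)
})

test_that("dataset bundles reuse one fold assignment and balance every table", {
  co <- simulate_rr_cohort(n_subjects = 23, beats_per_subject = 600, seed = 13)
  b <- build_rr_datasets(co, lengths = c(25, 50), seed = 13)
  expect_equal(nrow(b), 10) # 2 lengths x 5 folds
  folds <- attr(b, "folds")
  for (i in seq_len(nrow(b))) {
    train <- b$train[[i]]; test <- b$test[[i]]
    # exact balance
    expect_equal(sum(train$label == 0), sum(train$label == 1))
    expect_equal(sum(test$label == 0), sum(test$label == 1))
    # no subject leakage
    expect_length(intersect(unique(train$subject_id),
                            unique(test$subject_id)), 0)
    # fold membership identical across lengths
    fmap <- folds[folds$fold == b$fold[[i]], ]
    expect_true(all(unique(test$subject_id) %in%
                      fmap$subject_id[fmap$role == "test"]))
  }
})

test_that("window counts before balancing follow floor(series/N) conservation", {
  co <- simulate_rr_cohort(n_subjects = 5, beats_per_subject = 700, seed = 17)
  n_rr <- 50
  w <- window_rr(co, n_rr)
  expected <- co |>
    dplyr::count(subject_id, rhythm) |>
    dplyr::mutate(n_windows = n %/% n_rr)
  expect_equal(nrow(w), sum(expected$n_windows))
})

test_that("exported CSVs carry N+1 columns, round-trip, and are deterministic", {
  co <- simulate_rr_cohort(n_subjects = 23, beats_per_subject = 400, seed = 19)
  b <- build_rr_datasets(co, lengths = 25, seed = 19)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  export_datasets(b, dir1)
  files <- list.files(dir1, pattern = "\\.csv$")
  expect_equal(length(files), 10) # 5 folds x train/test
  tr <- read_dataset_csv(file.path(dir1, "n025_fold1_train.csv"))
  expect_equal(ncol(tr), 26)
  expect_equal(tr$label, b$train[[1]]$label)
  feats <- grep("^rr_", names(tr))
  expect_equal(as.matrix(tr[feats]),
               as.matrix(b$train[[1]][grep("^rr_", names(b$train[[1]]))]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(as.matrix(tr[feats]) >= 0.25 & as.matrix(tr[feats]) <= 2))
  # manifest lists the 20/3 fold composition
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_length(man$folds[["1"]]$train_subjects, 20)
  expect_length(man$folds[["1"]]$test_subjects, 3)
  # byte-identical re-export for the same seed
  b2 <- build_rr_datasets(co, lengths = 25, seed = 19)
  export_datasets(b2, dir2)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
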