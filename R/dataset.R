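#' Cut RR series into fixed-length windows
#'
#' Slices each subject-and-rhythm RR series into windows of `n_rr` consecutive
#' intervals starting at offsets 0, `stride`, 2`stride`, ...; a trailing
#' remainder shorter than `n_rr` is discarded. Each window becomes one wide
#' row with features `rr_001..rr_N` and a binary `label`
#' (0 = sinus rhythm, 1 = atrial fibrillation).
#'
#' @param rr_tbl A tibble with columns `subject_id`, `rhythm` ("SR"/"AF") and
#'   `rr_s`, ordered by beat within each series.
#' @param n_rr Window length in beats (the classifier input size; typically
#'   25, 50 or 100).
#' @param stride Offset between window starts; defaults to `n_rr`
#'   (non-overlapping windows).
#' @return A tibble with columns `subject_id`, `label`, `window_index` and
#'   `rr_001..rr_<n_rr>`.
#' @export
#' @examples
#' rr <- tibble::tibble(subject_id = "S01", rhythm = "SR", rr_s = runif(60, .6, 1))
#' nrow(window_rr(rr, n_rr = 25)) # floor(60 / 25) = 2 windows
window_rr <- function(rr_tbl, n_rr, stride = n_rr) {
  stopifnot(all(c("subject_id", "rhythm", "rr_s") %in% names(rr_tbl)),
            n_rr >= 1, stride >= 1)
  feat_names <- sprintf("rr_%03d", seq_len(n_rr))
  groups <- dplyr::group_split(dplyr::group_by(
    tibble::as_tibble(rr_tbl), .data$subject_id, .data$rhythm))
  rows <- purrr::map(groups, function(g) {
    v <- g$rr_s
    if (length(v) < n_rr) return(NULL)
    starts <- seq(1, length(v) - n_rr + 1, by = stride)
    mat <- t(vapply(starts, function(s) v[s:(s + n_rr - 1)], numeric(n_rr)))
    colnames(mat) <- feat_names
    out <- tibble::as_tibble(mat)
    dplyr::mutate(out,
                  subject_id = g$subject_id[[1]],
                  label = as.integer(g$rhythm[[1]] == "AF"),
                  window_index = seq_along(starts) - 1L,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Assign subjects to subject-wise cross-validation folds
#'
#' Draws `n_folds * test_per_fold` distinct test subjects without replacement
#' (seeded) and partitions them into per-fold test sets; every other subject
#' is a training subject in that fold. Because windows inherit their subject's
#' assignment wholesale, no subject's windows can appear on both sides of a
#' split (no identity leakage), and no subject appears in more than one test
#' fold.
#'
#' @param subjects Character vector of subject ids, or a data frame with a
#'   `subject_id` column.
#' @param n_folds Number of folds (default 5).
#' @param test_per_fold Test subjects per fold (default 3).
#' @param seed Integer seed making the draw reproducible.
#' @return A tibble with columns `fold`, `subject_id` and `role`
#'   (`"train"`/`"test"`); `n_folds * length(subjects)` rows.
#' @export
assign_subject_folds <- function(subjects, n_folds = 5, test_per_fold = 3,
                                 seed = 1L) {
  if (is.data.frame(subjects)) subjects <- unique(subjects$subject_id)
  subjects <- as.character(subjects)
  stopifnot(!anyDuplicated(subjects))
  if (n_folds * test_per_fold > length(subjects)) {
    stop("need at least ", n_folds * test_per_fold, " subjects for ",
         n_folds, " disjoint test sets of ", test_per_fold)
  }
  set.seed(seed)
  test_pool <- sample(subjects, n_folds * test_per_fold)
  purrr::map(seq_len(n_folds), function(k) {
    test_k <- test_pool[((k - 1) * test_per_fold + 1):(k * test_per_fold)]
    tibble::tibble(
      fold = k,
      subject_id = subjects,
      role = ifelse(subjects %in% test_k, "test", "train")
    )
  }) |> dplyr::bind_rows()
}

#' Balance classes by random down-sampling
#'
#' Randomly removes majority-class rows (seeded, without replacement) until
#' both labels have equal counts; minority rows are untouched and the relative
#' order of survivors is preserved. With sinus rhythm the majority, this
#' matches the usual AF-screening prevalence correction.
#'
#' @param windows A window tibble with a binary `label` column.
#' @param seed Integer seed.
#' @return The balanced tibble. If one class is absent, an empty tibble with a
#'   warning.
#' @export
balance_classes <- function(windows, seed = 1L) {
  stopifnot("label" %in% names(windows))
  n0 <- sum(windows$label == 0); n1 <- sum(windows$label == 1)
  if (n0 == 0 || n1 == 0) {
    warning("one class absent; returning an empty window set")
    return(windows[0, , drop = FALSE])
  }
  if (n0 == n1) return(tibble::as_tibble(windows))
  maj <- if (n0 > n1) 0L else 1L
  idx_maj <- which(windows$label == maj)
  set.seed(seed)
  keep_maj <- sort(sample(idx_maj, min(n0, n1)))
  keep <- sort(c(keep_maj, which(windows$label != maj)))
  tibble::as_tibble(windows[keep, , drop = FALSE])
}

#' Build balanced subject-wise train/test datasets for several window lengths
#'
#' The full dataset-construction procedure: window the RR series at each
#' length, assign subject-wise folds once (the same fold membership is reused
#' across lengths, so lengths are comparable), split windows by the subject's
#' role, and balance classes within every train and every test table by
#' down-sampling the majority class.
#'
#' @param rr_tbl RR series tibble (`subject_id`, `rhythm`, `rr_s`).
#' @param lengths Window lengths to build (default `c(25, 50, 100)`).
#' @param n_folds,test_per_fold Fold geometry (defaults 5 and 3).
#' @param seed Integer seed driving fold assignment and balancing.
#' @param stride Window stride; default `NULL` means non-overlapping
#'   (stride = length).
#' @return A tibble with one row per length and fold: columns `n_rr`, `fold`,
#'   `train` and `test` (list columns of window tibbles), `n_train`, `n_test`.
#'   The fold assignment is attached as attribute `"folds"`, the seed as
#'   `"seed"`.
#' @export
build_rr_datasets <- function(rr_tbl, lengths = c(25, 50, 100), n_folds = 5,
                              test_per_fold = 3, seed = 1L, stride = NULL) {
  folds <- assign_subject_folds(rr_tbl, n_folds, test_per_fold, seed)
  grid <- tidyr::expand_grid(n_rr = lengths, fold = seq_len(n_folds))
  res <- purrr::pmap(grid, function(n_rr, fold) {
    st <- if (is.null(stride)) n_rr else stride
    windows <- window_rr(rr_tbl, n_rr, st)
    fmap <- folds[folds$fold == fold, ]
    role <- fmap$role[match(windows$subject_id, fmap$subject_id)]
    # per-table balancing, seeded distinctly per (length, fold, side)
    bseed <- (seed + 131L * fold + 17L * n_rr) %% .Machine$integer.max
    train <- balance_classes(windows[role == "train", , drop = FALSE], bseed)
    test <- balance_classes(windows[role == "test", , drop = FALSE], bseed + 1L)
    ntr <- nrow(train); nte <- nrow(test)
    tibble::tibble(n_rr = n_rr, fold = fold,
                   train = list(train), test = list(test),
                   n_train = ntr, n_test = nte)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  out
}

#' Export dataset bundles as CSV files plus a manifest
#'
#' Writes `n<length>_fold<k>_train.csv` / `_test.csv` per bundle row, with
#' feature columns `rr_001..rr_N` (6 decimal places) followed by `label`, and
#' a JSON manifest recording lengths, seed, fold composition and class counts.
#'
#' @param bundles Output of [build_rr_datasets()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a tibble of written file paths.
#' @export
export_datasets <- function(bundles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  folds <- attr(bundles, "folds")
  write_one <- function(tbl, path) {
    feat <- grep("^rr_\\d+$", names(tbl), value = TRUE)
    out <- tbl[, c(feat, "label")]
    out[feat] <- lapply(out[feat], function(v) sprintf("%.6f", v))
    readr::write_csv(out, path)
    path
  }
  paths <- purrr::pmap(bundles, function(n_rr, fold, train, test, ...) {
    stem <- sprintf("n%03d_fold%d", n_rr, fold)
    tibble::tibble(
      n_rr = n_rr, fold = fold,
      train_csv = write_one(train, file.path(out_dir, paste0(stem, "_train.csv"))),
      test_csv = write_one(test, file.path(out_dir, paste0(stem, "_test.csv")))
    )
  }) |> dplyr::bind_rows()
  manifest <- list(
    lengths = sort(unique(bundles$n_rr)),
    n_folds = max(bundles$fold),
    seed = attr(bundles, "seed"),
    folds = lapply(split(folds, folds$fold), function(f) list(
      train_subjects = f$subject_id[f$role == "train"],
      test_subjects = f$subject_id[f$role == "test"]
    )),
    class_counts = lapply(seq_len(nrow(bundles)), function(i) list(
      n_rr = bundles$n_rr[[i]], fold = bundles$fold[[i]],
      train = as.list(table(bundles$train[[i]]$label)),
      test = as.list(table(bundles$test[[i]]$label))
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a window dataset CSV written by [export_datasets()]
#'
#' @param path CSV path with columns `rr_001..rr_N` and `label`.
#' @return A window tibble with numeric features and an integer `label`.
#' @export
read_dataset_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x$label <- as.integer(x$label)
  x
}
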