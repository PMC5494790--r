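#' Three-class confusion matrix
#'
#' Rows are the system's output class, columns the desired (true) class:
#' entry `S[X, Y]` counts samples truly of class `Y` predicted as class `X`.
#'
#' @param truth,estimate Equal-length label vectors.
#' @param class_list Ordered class labels (default A, D, E).
#' @return A `confusion_matrix3`: an integer matrix with classes on both
#'   dimensions (`output` x `desired`).
#' @export
#' @examples
#' confusion(c("A", "A", "D"), c("D", "A", "D"))
confusion <- function(truth, estimate, class_list = c("A", "D", "E")) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length",
          class = "selmeeg_validation_error")
  }
  bad <- setdiff(unique(c(truth, estimate)), class_list)
  if (length(bad) > 0) {
    abort(paste0("labels outside class_list: ", paste(bad, collapse = ", ")),
          class = "selmeeg_validation_error")
  }
  cm <- table(factor(estimate, levels = class_list),
              factor(truth, levels = class_list))
  m <- matrix(as.integer(cm), nrow = length(class_list),
              dimnames = list(output = class_list, desired = class_list))
  structure(m, class = c("confusion_matrix3", class(m)))
}

#' Sensitivity, specificity and total accuracy from a confusion matrix
#'
#' Per-class sensitivity is the class's recall, `S_XX / S_X` (column total).
#' Per-class specificity counts every sample not of class `X` that was
#' predicted as any class other than `X` as a true negative — e.g. for class
#' A, `(S_DD + S_DE + S_ED + S_EE) / (S_D + S_E)` — so a D sample predicted
#' as E still counts as a true negative for A. Total accuracy is
#' `trace / total`.
#'
#' @param cm A [confusion()] matrix (any square labelled count matrix works).
#' @param fold Fold identifier carried into the output (default `"pooled"`).
#' @return Tibble with columns `fold`, `class`, `sensitivity`, `specificity`,
#'   `accuracy` (total accuracy, repeated on each row). A class with no true
#'   samples gets `NA` sensitivity with a warning.
#' @export
selm_metrics <- function(cm, fold = "pooled") {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m) || sum(m) == 0) {
    abort("need a non-empty square confusion matrix",
          class = "selmeeg_validation_error")
  }
  classes <- colnames(m) %||% as.character(seq_len(ncol(m)))
  total <- sum(m)
  acc <- sum(diag(m)) / total
  col_tot <- colSums(m)
  sens <- diag(m) / col_tot
  if (any(col_tot == 0)) {
    warn(paste0("no true samples for class ",
                paste(classes[col_tot == 0], collapse = ", "),
                "; sensitivity undefined"))
    sens[col_tot == 0] <- NA_real_
  }
  spec <- vapply(seq_along(classes), function(i) {
    sum(m[-i, -i]) / sum(col_tot[-i])
  }, numeric(1))
  tibble(fold = fold, class = classes,
         sensitivity = unname(sens), specificity = spec, accuracy = acc)
}

#' Tidy a confusion matrix into long counts
#' @param x A `confusion_matrix3`.
#' @param ... Unused.
#' @method tidy confusion_matrix3
#' @export
tidy.confusion_matrix3 <- function(x, ...) {
  m <- unclass(x)
  tidyr::expand_grid(output = rownames(m), desired = colnames(m)) |>
    dplyr::mutate(n = purrr::map2_int(.data$output, .data$desired,
                                      function(o, d) m[o, d]))
}

# --- cross-validation -------------------------------------------------------

#' Deterministic (stratified) k-fold assignment
#'
#' Shuffles with the given seed and deals samples to folds round-robin within
#' each stratum, so fold sizes differ by at most one and class proportions
#' are preserved. With `by = "segment"` whole segments are assigned to folds,
#' so overlapping epochs of one segment never straddle the train/test split.
#'
#' @param data Feature tibble (needs `label`, and `segment_id` when
#'   `by = "segment"`).
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @param by `"epoch"` (default) or `"segment"`.
#' @return Integer vector of fold indices in `1:k`, one per row of `data`.
#' @export
cv_plan <- function(data, k = 4L, seed = 1L, by = c("epoch", "segment")) {
  by <- match.arg(by)
  n <- nrow(data)
  if (k < 2) abort("need at least 2 folds", class = "selmeeg_validation_error")
  if (n < k) abort(sprintf("dataset of %d rows cannot be split into %d folds",
                           n, k), class = "selmeeg_validation_error")
  # deal shuffled samples to folds in one continuous cycle across strata, so
  # fold sizes stay within one of each other both per stratum and overall
  deal <- function(strata) {
    fold <- integer(length(strata))
    offset <- 0L
    for (cl in unique(strata)) {
      idx <- which(strata == cl)
      fold[sample(idx)] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    fold
  }
  with_local_seed(seed, {
    if (by == "segment") {
      segs <- unique(data[c("segment_id", "label")])
      sfold <- deal(segs$label)
      sfold[match(data$segment_id, segs$segment_id)]
    } else {
      strata <- if ("label" %in% names(data)) data$label else
        rep("all", n)
      deal(strata)
    }
  })
}

#' Materialise train/test splits from a fold assignment
#'
#' @param data Feature tibble.
#' @param fold Integer fold assignment from [cv_plan()] (or any integer
#'   vector of the same length).
#' @return List of `k` elements, each `list(fold =, train =, test =)`.
#' @export
kfold_split <- function(data, fold) {
  stopifnot(length(fold) == nrow(data))
  lapply(sort(unique(fold)), function(f) {
    list(fold = f,
         train = data[fold != f, , drop = FALSE],
         test = data[fold == f, , drop = FALSE])
  })
}

#' k-fold cross-validation of a multiclass SELM
#'
#' Trains on `k - 1` folds and tests on the held-out fold, for each fold in
#' turn. The k test-fold confusion matrices are summed into a pooled matrix
#' (so pooled accuracy is total correct over total tested); per-fold metrics
#' are reported alongside.
#'
#' @param data Feature tibble with `label` plus feature columns.
#' @param strategy,class_list,structure,C,epsilon,kernel,mode Passed to
#'   [train_multiclass()].
#' @param k,seed,by Fold plan, see [cv_plan()].
#' @return An object of class `selm_cv`: list with `confusion` (pooled),
#'   `metrics` (pooled tibble), `fold_metrics`, `accuracy`, `k`, `seed`,
#'   `strategy`.
#' @export
cross_validate <- function(data, strategy = "oao",
                           class_list = c("A", "D", "E"), structure = NULL,
                           C = 5, epsilon = 0.001, kernel = kernel_spec(),
                           mode = "newton", k = 4L, seed = 1L,
                           by = c("epoch", "segment")) {
  by <- match.arg(by)
  fold <- cv_plan(data, k = k, seed = seed, by = by)
  splits <- kfold_split(data, fold)
  per_fold <- purrr::map(splits, function(s) {
    m <- train_multiclass(s$train, strategy = strategy,
                          class_list = class_list, structure = structure,
                          C = C, epsilon = epsilon, kernel = kernel,
                          mode = mode)
    pred <- predict(m, s$test)
    confusion(s$test$label, pred, class_list)
  })
  pooled <- Reduce(`+`, purrr::map(per_fold, unclass))
  pooled <- structure(pooled, class = c("confusion_matrix3", "matrix", "array"))
  fold_metrics <- purrr::imap(per_fold, function(cmf, i) {
    selm_metrics(cmf, fold = as.character(i))
  }) |> purrr::list_rbind()
  structure(list(confusion = pooled,
                 metrics = selm_metrics(pooled, fold = "pooled"),
                 fold_metrics = fold_metrics,
                 accuracy = sum(diag(pooled)) / sum(pooled),
                 k = k, seed = seed, strategy = strategy, by = by),
            class = "selm_cv")
}

#' @export
print.selm_cv <- function(x, ...) {
  cat(sprintf("<selm_cv> %s, %d-fold (%s-level), pooled accuracy %.4f\n",
              toupper(x$strategy), x$k, x$by, x$accuracy))
  print(x$metrics)
  invisible(x)
}

#' @method tidy selm_cv
#' @export
tidy.selm_cv <- function(x, ...) {
  dplyr::bind_rows(x$metrics, x$fold_metrics)
}

#' @method glance selm_cv
#' @export
glance.selm_cv <- function(x, ...) {
  tibble(strategy = x$strategy, k = x$k, seed = x$seed, by = x$by,
         accuracy = x$accuracy, n = sum(unclass(x$confusion)))
}

# --- grid search ------------------------------------------------------------

#' Hyperparameter grids for the kernel classifiers
#'
#' Defaults are the published tuning grids: 8 values of the box bound `C`, 12
#' values of the Gaussian width `2sigma^2` and 7 polynomial degrees.
#'
#' @param C_values Box-bound grid.
#' @param two_sigma_sq_values Gaussian-width grid.
#' @param m_values Polynomial-degree grid.
#' @return A named list of class `grid_spec`.
#' @export
grid_spec <- function(C_values = c(0.1, 0.5, 1, 2, 5, 10, 20, 30),
                      two_sigma_sq_values = c(1, 5, 10, 60, 100, 200, 300,
                                              400, 500, 600, 700, 800),
                      m_values = c(1, 2, 3, 4, 5, 10, 20)) {
  stopifnot(length(C_values) > 0, all(C_values > 0),
            length(two_sigma_sq_values) > 0, all(two_sigma_sq_values > 0),
            length(m_values) > 0, all(m_values >= 1))
  structure(list(C_values = C_values,
                 two_sigma_sq_values = two_sigma_sq_values,
                 m_values = m_values),
            class = "grid_spec")
}

#' Exhaustive (C, kernel parameter) grid search by cross-validation
#'
#' Evaluates every grid combination with [cross_validate()] (same fold plan
#' throughout) and returns the full accuracy table plus the best setting.
#' Ties are broken towards smaller `C`, then smaller kernel parameter
#' (preferring the simpler, smoother model).
#'
#' @param data Feature tibble.
#' @param strategy Multiclass strategy.
#' @param family Kernel family, `"gaussian"` or `"polynomial"`.
#' @param grid A [grid_spec()].
#' @param k,seed,by Fold plan, see [cv_plan()].
#' @param ... Passed to [cross_validate()] (e.g. `structure`, `epsilon`).
#' @return Object of class `selm_grid`: `results` (tibble `C`,
#'   `kernel_param`, `accuracy`), `best` (one-row tibble), `family`,
#'   `strategy`. The results table is the input for the accuracy-vs-parameter
#'   figures.
#' @export
grid_search <- function(data, strategy = "oao",
                        family = c("gaussian", "polynomial"),
                        grid = grid_spec(), k = 4L, seed = 1L,
                        by = "epoch", ...) {
  family <- match.arg(family)
  stopifnot(inherits(grid, "grid_spec"))
  params <- grid[[if (family == "gaussian") "two_sigma_sq_values"
                  else "m_values"]]
  combos <- tidyr::expand_grid(C = grid$C_values, kernel_param = params)
  acc <- purrr::pmap_dbl(combos, function(C, kernel_param) {
    kern <- if (family == "gaussian") {
      kernel_spec("gaussian", two_sigma_sq = kernel_param)
    } else kernel_spec("polynomial", degree = kernel_param)
    cross_validate(data, strategy = strategy, C = C, kernel = kern,
                   k = k, seed = seed, by = by, ...)$accuracy
  })
  results <- dplyr::mutate(combos, accuracy = acc)
  best <- results |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$C,
                   .data$kernel_param) |>
    head(1)
  structure(list(results = results, best = best, family = family,
                 strategy = strategy, k = k, seed = seed),
            class = "selm_grid")
}

#' @export
print.selm_grid <- function(x, ...) {
  cat(sprintf("<selm_grid> %s / %s kernel, %d settings\n",
              toupper(x$strategy), x$family, nrow(x$results)))
  cat("best:\n"); print(x$best)
  invisible(x)
}

#' @method tidy selm_grid
#' @export
tidy.selm_grid <- function(x, ...) x$results

# --- protocol helpers and shipped settings ----------------------------------

#' Epoch duration and overlap in seconds
#'
#' With the standard 512/256 windows at 173.61 Hz an epoch lasts 2.95 s and
#' adjacent epochs overlap by 1.47 s.
#'
#' @param samples Number of samples (window or hop).
#' @param fs Sampling rate in Hz.
#' @return Duration in seconds.
#' @export
samples_to_seconds <- function(samples, fs = BONN_FS) samples / fs

#' The published operating point of the classifier
#'
#' Reads the shipped configuration (`inst/extdata/paper_settings.yaml`):
#' one-against-one strategy, Gaussian kernel with `2sigma^2 = 500`, `C = 5`,
#' tolerance 0.001, 512/256 epoching, 4-fold cross-validation.
#'
#' @return Named list of settings.
#' @export
paper_settings <- function() {
  path <- system.file("extdata", "paper_settings.yaml", package = "selmeeg")
  yaml::read_yaml(path)
}
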