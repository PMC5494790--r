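test_that("confusion matrix follows the output-by-desired convention", {
  cm <- confusion(rep(c("A", "D", "E"), each = 100),
                  rep(c("A", "D", "E"), each = 100))
  expect_equal(diag(unclass(cm)), c(A = 100, D = 100, E = 100))
  expect_equal(sum(unclass(cm)), 300)

  cm2 <- confusion(c("A", "A"), c("D", "A"))
  m <- unclass(cm2)
  expect_equal(m["A", "A"], 1)
  expect_equal(m["D", "A"], 1)
  expect_equal(sum(m), 2)

  withr::with_seed(10, {
    truth <- sample(c("A", "D", "E"), 60, replace = TRUE)
    pred <- sample(c("A", "D", "E"), 60, replace = TRUE)
  })
  cm3 <- confusion(truth, pred)
  expect_equal(colSums(unclass(cm3)), table(factor(truth)) |> as.numeric() |>
                 stats::setNames(c("A", "D", "E")))

  expect_error(confusion(c("A", "Z"), c("A", "A")),
               class = "selmeeg_validation_error")
  expect_error(confusion(c("A"), c("A", "A")),
               class = "selmeeg_validation_error")
})

test_that("metrics match the three-class definitions by hand", {
  perfect <- confusion(rep(c("A", "D", "E"), each = 100),
                       rep(c("A", "D", "E"), each = 100))
  mp <- selm_metrics(perfect)
  expect_true(all(mp$sensitivity == 1))
  expect_true(all(mp$specificity == 1))
  expect_true(all(mp$accuracy == 1))

  # S_AA = 90, S_DA = 10, S_DD = 100, S_EE = 100
  m <- matrix(0L, 3, 3, dimnames = list(output = c("A", "D", "E"),
                                        desired = c("A", "D", "E")))
  m["A", "A"] <- 90L; m["D", "A"] <- 10L
  m["D", "D"] <- 100L; m["E", "E"] <- 100L
  mm <- selm_metrics(m)
  expect_equal(mm$sensitivity[mm$class == "A"], 0.90)
  expect_equal(unique(mm$accuracy), 290 / 300)
  expect_equal(mm$specificity[mm$class == "A"], 1.0)   # 200 / 200

  # a D sample predicted as E is still a true negative for class A
  m2 <- m; m2["E", "D"] <- 20L
  mm2 <- selm_metrics(m2)
  expect_equal(mm2$specificity[mm2$class == "A"],
               (100 + 0 + 20 + 100) / (120 + 100))

  expect_error(selm_metrics(matrix(0, 3, 3)),
               class = "selmeeg_validation_error")
})

test_that("random confusion matrices reproduce the formula arithmetic", {
  withr::with_seed(14, {
    for (i in 1:10) {
      m <- matrix(rpois(9, 30), 3, 3,
                  dimnames = list(output = c("A", "D", "E"),
                                  desired = c("A", "D", "E")))
      mt <- selm_metrics(m)
      for (ci in 1:3) {
        expect_equal(mt$sensitivity[ci], m[ci, ci] / sum(m[, ci]))
        expect_equal(mt$specificity[ci], sum(m[-ci, -ci]) / sum(m[, -ci]))
      }
      expect_equal(unique(mt$accuracy), sum(diag(m)) / sum(m))
      expect_true(all(dplyr::select(mt, sensitivity:accuracy) >= 0 &
                        dplyr::select(mt, sensitivity:accuracy) <= 1))
    }
  })
})

test_that("missing true class yields NA sensitivity with a warning", {
  m <- matrix(c(5L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 4L), 3, 3,
              dimnames = list(output = c("A", "D", "E"),
                              desired = c("A", "D", "E")))
  m[, "D"] <- 0L
  expect_warning(mt <- selm_metrics(m), "sensitivity undefined")
  expect_true(is.na(mt$sensitivity[mt$class == "D"]))
})

test_that("fold plans partition, balance, stratify and reproduce", {
  d <- tibble::tibble(segment_id = rep(sprintf("s%02d", 1:24), each = 5),
                      label = rep(rep(c("A", "D", "E"), each = 8), each = 5),
                      f1 = rnorm(120))
  fold <- cv_plan(d, k = 4, seed = 9)
  expect_equal(sort(unique(fold)), 1:4)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  # stratified: each class spread over folds
  expect_true(all(table(fold, d$label) == 10))
  expect_identical(fold, cv_plan(d, k = 4, seed = 9))
  expect_false(identical(fold, cv_plan(d, k = 4, seed = 10)))

  # segment-level folds never split a segment
  fseg <- cv_plan(d, k = 4, seed = 9, by = "segment")
  expect_true(all(tapply(fseg, d$segment_id,
                         function(v) length(unique(v))) == 1))

  splits <- kfold_split(d, fold)
  expect_length(splits, 4)
  got <- sort(unlist(purrr::map(splits, function(s) which(fold == s$fold))))
  expect_equal(got, 1:120)
  for (s in splits) expect_equal(nrow(s$train) + nrow(s$test), 120)

  expect_error(cv_plan(d[1:3, ], k = 4), class = "selmeeg_validation_error")
  expect_error(cv_plan(d, k = 1), class = "selmeeg_validation_error")
})

test_that("cross-validation pools fold confusions exactly", {
  d <- separable_features(12, seed = 21)
  cv <- cross_validate(d, "oao", kernel = kernel_spec(two_sigma_sq = 5),
                       k = 3, seed = 4)
  expect_gte(cv$accuracy, 0.99)
  expect_equal(sum(unclass(cv$confusion)), nrow(d))
  # pooled accuracy = total correct / total tested, not mean of fold rates
  expect_equal(cv$accuracy, sum(diag(unclass(cv$confusion))) / nrow(d))
  expect_equal(nrow(cv$fold_metrics), 3 * 3)
  expect_equal(glance(cv)$n, nrow(d))
})

test_that("two folds of ten epochs split five and five", {
  d <- tibble::tibble(label = rep(c("A", "D", "E"), length.out = 10),
                      f1 = rnorm(10), f2 = rnorm(10))
  splits <- kfold_split(d, cv_plan(d, k = 2, seed = 1))
  expect_equal(vapply(splits, function(s) nrow(s$test), numeric(1)), c(5, 5))
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  d <- separable_features(6, seed = 33)
  g1 <- grid_search(d, grid = grid_spec(C_values = 2,
                                        two_sigma_sq_values = 5),
                    k = 2, seed = 1)
  expect_equal(nrow(g1$results), 1)
  expect_equal(g1$best$C, 2)

  g <- grid_search(d, grid = grid_spec(C_values = c(1, 5),
                                       two_sigma_sq_values = c(5, 50)),
                   k = 2, seed = 1)
  expect_equal(nrow(g$results), 4)
  # separable data: every setting is perfect, tie-break -> smallest C then width
  expect_true(all(g$results$accuracy == 1))
  expect_equal(g$best$C, 1)
  expect_equal(g$best$kernel_param, 5)
})

test_that("default grids carry the published tuning values", {
  gs <- grid_spec()
  expect_length(gs$C_values, 8)
  expect_length(gs$two_sigma_sq_values, 12)
  expect_length(gs$m_values, 7)
  expect_equal(tidyr::expand_grid(C = gs$C_values,
                                  s = gs$two_sigma_sq_values) |> nrow(), 96)
})

test_that("shipped settings file describes the operating point", {
  ps <- paper_settings()
  expect_equal(ps$strategy, "oao")
  expect_equal(ps$kernel$two_sigma_sq, 500)
  expect_equal(ps$C, 5)
  expect_equal(ps$epsilon, 0.001)
  expect_equal(ps$window, 512)
  expect_equal(ps$hop, 256)
  expect_equal(ps$k_folds, 4)
})

test_that("epoch timing arithmetic in seconds", {
  expect_equal(round(samples_to_seconds(256), 2), 1.47)
  expect_equal(round(samples_to_seconds(512), 1), 2.9)
})

test_that("autoplot methods return ggplot objects", {
  d <- separable_features(6, seed = 2)
  cv <- cross_validate(d, "oao", kernel = kernel_spec(two_sigma_sq = 5),
                       k = 2, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  g <- grid_search(d, grid = grid_spec(C_values = 1, two_sigma_sq_values = 5),
                   k = 2, seed = 1)
  expect_s3_class(autoplot(g), "ggplot")
  segs <- generate_synthetic_dataset(
    synth_spec(n_segments_per_class = 1, segment_length = 256, seed = 1))
  expect_s3_class(plot_segments(segs), "ggplot")
})
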