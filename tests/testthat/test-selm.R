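test_that("kernel evaluations match their closed forms", {
  g <- kernel_spec("gaussian", two_sigma_sq = 500)
  x <- c(1, 2, 3)
  expect_equal(kernel_eval(x, x, g), 1)
  y <- x + sqrt(500 / 3)            # ||x - y||^2 = 500
  expect_equal(kernel_eval(x, y, g), exp(-1))

  p <- kernel_spec("polynomial", degree = 4)
  expect_equal(kernel_eval(c(1, 0), c(0, 1), p), 1)     # x.y = 0
  expect_equal(kernel_eval(c(1, 1), c(2, 1), p), (1 + 3)^4)

  l <- kernel_spec("laplacian", sigma = 2)
  expect_equal(kernel_eval(c(0, 0), c(3, 4), l), exp(-5 / 4))
  l2 <- kernel_spec("laplacian", sigma = 2, laplacian_denom = "sigma")
  expect_equal(kernel_eval(c(0, 0), c(3, 4), l2), exp(-5 / 2))

  expect_error(kernel_eval(1:2, 1:3, g), class = "selmeeg_validation_error")
  expect_error(kernel_spec("gaussian", two_sigma_sq = -1))
})

test_that("kernel_matrix agrees with pairwise kernel_eval", {
  withr::with_seed(1, {
    X <- matrix(rnorm(12), 4, 3)
    Y <- matrix(rnorm(6), 2, 3)
  })
  for (spec in list(kernel_spec("gaussian", two_sigma_sq = 3),
                    kernel_spec("laplacian", sigma = 1.5),
                    kernel_spec("polynomial", degree = 3))) {
    K <- kernel_matrix(X, Y, spec)
    for (i in 1:4) for (j in 1:2) {
      expect_equal(K[i, j], kernel_eval(X[i, ], Y[j, ], spec))
    }
  }
})

test_that("fresh training state sits at alpha = 0 with J = -1", {
  st <- selm_init_state(matrix(rnorm(10), 5, 2), c(1, -1, 1, -1, 1))
  expect_equal(st$alpha, numeric(5))
  expect_equal(st$g, rep(-1, 5))
  expect_equal(st$d, rep(1, 5))
  expect_equal(st$J, rep(-1, 5))
  expect_equal(selm_select_index(st), 1L)   # all tied at -1: lowest index

  st1 <- selm_init_state(matrix(1, 1, 1), 1)
  expect_length(st1$alpha, 1)
  expect_error(selm_init_state(matrix(1, 1, 1), 1, C = 0),
               class = "selmeeg_validation_error")
  expect_error(selm_init_state(matrix(1, 2, 1), c(1, 2)),
               class = "selmeeg_validation_error")
})

test_that("index selection applies the argmin and the stopping rule", {
  st <- selm_init_state(matrix(rnorm(6), 3, 2), c(1, -1, 1), epsilon = 0.001)
  st$J <- c(-0.5, -2.0, -0.1)
  expect_equal(selm_select_index(st), 2L)
  st$J <- c(0.01, 0.005, 0.2)
  expect_true(is.na(selm_select_index(st)))   # min J = 0.005 > -0.001
  st$J <- c(-0.0005, 0.1, 0.1)
  expect_true(is.na(selm_select_index(st)))   # within tolerance
})

test_that("single-sample update reaches the closed-form optimum and stops", {
  st <- selm_init_state(matrix(c(2, 3), 1, 2), 1,
                        kernel = kernel_spec("gaussian", two_sigma_sq = 5))
  st <- selm_update_multiplier(st, 1)
  expect_equal(st$alpha, 1)       # alpha* = 1 / k(x,x) = 1
  expect_equal(st$g, 0)
  expect_equal(st$J, 0)
  expect_true(is.na(selm_select_index(st)))
})

test_that("updates clip to the box and propagate the clipped increment", {
  # k(x,x) = (1 + 8)^1 = 9 for this polynomial kernel; literal step
  # alpha <- 0 - (-1) = 1 would overshoot C = 0.5
  st <- selm_init_state(matrix(c(2, 2), 1, 2), 1, C = 0.5,
                        kernel = kernel_spec("polynomial", degree = 1))
  st_lit <- selm_update_multiplier(st, 1, mode = "literal")
  expect_equal(st_lit$alpha, 0.5)                 # clipped at C
  expect_equal(st_lit$g, -1 + 9 * 0.5)            # propagated with clipped value
  expect_equal(st_lit$d, -1)                      # at upper bound
  # newton mode lands inside the box at the true optimum 1/9
  st_new <- selm_update_multiplier(st, 1, mode = "newton")
  expect_equal(st_new$alpha, 1 / 9)
  expect_equal(st_new$g, 0)

  # negative trial values clip to zero
  st2 <- selm_init_state(matrix(c(1, 0, 0, 1), 2, 2), c(1, -1), C = 5)
  st2$g <- c(2, -1)    # force a downhill trial from alpha = 0
  out <- selm_update_multiplier(st2, 1, mode = "literal")
  expect_equal(out$alpha[1], 0)
  expect_error(selm_update_multiplier(st2, 9),
               class = "selmeeg_internal_error")
})

test_that("two-point training matches the exhaustive fine-grid QP minimum", {
  X <- rbind(c(-1, 0), c(1, 0.5))
  t <- c(-1, 1)
  spec <- kernel_spec("gaussian", two_sigma_sq = 1)
  fit <- selm_fit(X, t, C = 5, kernel = spec)
  H <- outer(t, t) * kernel_matrix(X, spec = spec)
  expect_equal(fit$dual_objective, oracle_qp_grid2(H, C = 5),
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gt(fit$final_min_J, -fit$epsilon)
})

test_that("duplicated point with opposite labels drives both alphas to C", {
  X <- rbind(c(1, 1), c(1, 1))
  t <- c(1, -1)
  spec <- kernel_spec("gaussian", two_sigma_sq = 2)
  fit <- selm_fit(X, t, C = 0.5, kernel = spec)
  expect_equal(sort(fit$alpha), c(0.5, 0.5))
  H <- outer(t, t) * kernel_matrix(X, spec = spec)
  expect_equal(fit$dual_objective, oracle_qp_grid2(H, C = 0.5),
               tolerance = 1e-3)
})

test_that("solver matches the projected-gradient oracle on random tiny QPs", {
  withr::with_seed(31, {
    for (i in 1:30) {
      inst <- random_qp_instance()
      fit <- suppressWarnings(   # single-label draws are legitimate QPs
        selm_fit(inst$X, inst$t, C = inst$C, kernel = inst$spec))
      expect_true(fit$converged)
      expect_true(all(fit$alpha >= 0 & fit$alpha <= inst$C))
      expect_gt(fit$final_min_J, -fit$epsilon)
      expect_equal(fit$dual_objective, oracle_qp_pg(inst$H, inst$C),
                   tolerance = 1e-3)
    }
  })
})

test_that("box feasibility and objective descent hold along the trajectory", {
  withr::with_seed(7, {
    X <- matrix(rnorm(8), 4, 2)
    t <- c(1, 1, -1, -1)
  })
  spec <- kernel_spec("polynomial", degree = 2)
  st <- selm_init_state(X, t, C = 2, kernel = spec)
  obj_prev <- selm_dual_objective(st)
  repeat {
    c <- selm_select_index(st)
    if (is.na(c)) break
    st <- selm_update_multiplier(st, c, mode = "newton")
    expect_true(all(st$alpha >= 0 & st$alpha <= st$C))
    expect_equal(st$J, st$g * st$d)
    obj <- selm_dual_objective(st)
    expect_lte(obj, obj_prev + 1e-12)
    obj_prev <- obj
  }
  expect_gt(min(st$J), -st$epsilon)
})

test_that("literal and newton modes coincide for the unit-diagonal Gaussian", {
  withr::with_seed(13, {
    X <- matrix(rnorm(20), 10, 2)
    t <- rep(c(1, -1), 5)
  })
  spec <- kernel_spec("gaussian", two_sigma_sq = 3)
  a <- selm_fit(X, t, C = 5, kernel = spec, mode = "literal")
  b <- selm_fit(X, t, C = 5, kernel = spec, mode = "newton")
  expect_equal(a$alpha, b$alpha)
  expect_equal(a$iterations, b$iterations)
})

test_that("a separable cloud trains to zero error and a sparse model", {
  withr::with_seed(17, {
    X <- rbind(matrix(rnorm(100, -2, 0.5), 50), matrix(rnorm(100, 2, 0.5), 50))
    t <- rep(c(-1, 1), each = 50)
  })
  fit <- selm_fit(X, t, C = 5, kernel = kernel_spec("gaussian",
                                                    two_sigma_sq = 4))
  expect_equal(predict(fit, X), t)
  expect_lt(fit$n_support, fit$n_train)   # strictly sparse
})

test_that("predictions depend only on the stored support vectors", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
    t <- rep(c(-1, 1), each = 20)
    q <- matrix(rnorm(10), 5, 2)
  })
  fit <- selm_fit(X, t, C = 5, kernel = kernel_spec("gaussian",
                                                    two_sigma_sq = 2))
  manual <- drop(kernel_matrix(q, fit$support_vectors, fit$kernel) %*%
                   fit$weights)
  expect_equal(decision_value(fit, q), manual)
})

test_that("label flip negates every decision value", {
  withr::with_seed(29, {
    X <- matrix(rnorm(24), 12, 2)
    t <- rep(c(1, -1), 6)
    q <- matrix(rnorm(8), 4, 2)
  })
  spec <- kernel_spec("gaussian", two_sigma_sq = 2)
  f1 <- selm_fit(X, t, C = 3, kernel = spec)
  f2 <- selm_fit(X, -t, C = 3, kernel = spec)
  expect_equal(decision_value(f2, q), -decision_value(f1, q),
               tolerance = 1e-8)
})

test_that("empty models and sign ties predict +1", {
  empty <- suppressWarnings(
    selm_fit(matrix(c(0, 0), 1, 2), 1, C = 5,
             kernel = kernel_spec("gaussian", two_sigma_sq = 1)))
  empty$support_vectors <- empty$support_vectors[0, , drop = FALSE]
  empty$weights <- numeric(0); empty$n_support <- 0L
  expect_equal(decision_value(empty, c(1, 2)), 0)
  expect_equal(predict(empty, c(1, 2)), 1)
})

test_that("JSON serialization round-trips models exactly", {
  withr::with_seed(3, {
    X <- matrix(rnorm(16), 8, 2)
    t <- rep(c(1, -1), 4)
    q <- matrix(rnorm(6), 3, 2)
  })
  fit <- selm_fit(X, t, C = 2, kernel = kernel_spec("gaussian",
                                                    two_sigma_sq = 0.7))
  f <- withr::local_tempfile(fileext = ".json")
  write_selm(fit, f)
  back <- read_selm(f)
  expect_identical(back$weights, fit$weights)
  expect_identical(unname(back$support_vectors),
                   unname(fit$support_vectors))
  expect_identical(decision_value(back, q), decision_value(fit, q))
})

test_that("glance and tidy summarise the fitted model", {
  withr::with_seed(8, {
    X <- matrix(rnorm(12), 6, 2)
    t <- rep(c(1, -1), 3)
  })
  fit <- selm_fit(X, t, C = 1, kernel = kernel_spec("gaussian",
                                                    two_sigma_sq = 1))
  g <- glance(fit)
  expect_equal(g$n_support, nrow(tidy(fit)))
  expect_equal(g$sparsity, g$n_support / g$n_train)
  expect_true(all(tidy(fit)$alpha > 0))
})
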