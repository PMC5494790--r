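# Independent oracles used across the suite. These deliberately avoid the
# package's lifting/solver code paths: the wavelet oracle is direct circular
# convolution + dyadic decimation, the QP oracles are exhaustive grid search
# and long-run projected gradient descent.

# db4 analysis filters, written out from their closed forms.
oracle_db4 <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(h = h, g = c(-h[4], h[3], -h[2], h[1]))
}

# One analysis level by circular convolution/decimation:
#   approx[l] = sum_m h[m] x[2l + m],  detail[l] = sum_m g[m] x[2l - 2 + m]
# (0-based indices, modulo length(x)).
oracle_dwt_level <- function(x) {
  f <- oracle_db4()
  L <- length(x)
  n <- L / 2
  a <- vapply(0:(n - 1), function(l) {
    sum(f$h * x[((2 * l + 0:3) %% L) + 1])
  }, numeric(1))
  d <- vapply(0:(n - 1), function(l) {
    sum(f$g * x[((2 * l - 2 + 0:3) %% L) + 1])
  }, numeric(1))
  list(approx = a, detail = d)
}

oracle_dwt3 <- function(x) {
  l1 <- oracle_dwt_level(x)
  l2 <- oracle_dwt_level(l1$approx)
  l3 <- oracle_dwt_level(l2$approx)
  list(a3 = l3$approx, d3 = l3$detail, d2 = l2$detail, d1 = l1$detail)
}

# Dual objective L_d(alpha) = 0.5 a' H a - sum(a) with H = (t t') * K.
oracle_qp_obj <- function(alpha, H) {
  0.5 * sum(alpha * (H %*% alpha)) - sum(alpha)
}

# Exhaustive fine-grid minimiser of the 2-variable box QP.
oracle_qp_grid2 <- function(H, C, step = 1e-3) {
  g <- seq(0, C, by = step)
  best <- Inf
  # vectorised over alpha2 for each alpha1
  for (a1 in g) {
    v <- 0.5 * (H[1, 1] * a1^2 + 2 * H[1, 2] * a1 * g + H[2, 2] * g^2) -
      a1 - g
    m <- min(v)
    if (m < best) best <- m
  }
  best
}

# Projected-gradient minimiser of the box QP (any N). Step 1/||H||_2,
# run long enough that the objective is resolved well below 1e-3.
oracle_qp_pg <- function(H, C, iters = 20000) {
  n <- nrow(H)
  lr <- 1 / max(abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  alpha <- rep(0, n)
  for (i in seq_len(iters)) {
    alpha <- alpha - lr * (H %*% alpha - 1)
    alpha <- pmin(pmax(as.numeric(alpha), 0), C)
  }
  oracle_qp_obj(alpha, H)
}

# A fake binary selm whose decision value at a fixed query point `x0` is
# exactly `value`: a single Gaussian support vector sitting on x0.
stub_selm <- function(x0, value) {
  structure(list(support_vectors = matrix(x0, nrow = 1),
                 weights = value, alpha = abs(value),
                 sv_labels = sign(value),
                 kernel = kernel_spec("gaussian", two_sigma_sq = 1),
                 C = 5, epsilon = 1e-3, mode = "newton",
                 converged = TRUE, iterations = 0L, final_min_J = 0,
                 n_train = 1L, n_support = 1L, sparsity = 1,
                 dual_objective = 0, feature_names = NULL),
            class = "selm")
}

# A stub three-class model over classes A/D/E whose binary decision values at
# query x0 are given per role.
stub_multiclass <- function(strategy, x0, values, structure = NULL) {
  models <- purrr::imap(values, function(v, nm) stub_selm(x0, v))
  base::structure(list(strategy = strategy, class_list = c("A", "D", "E"),
                       structure = structure, binary_models = models,
                       feature_names = NULL),
                  class = "selm_multiclass")
}

# Small well-separated three-class feature set for multiclass tests.
separable_features <- function(n_per_class = 15, seed = 42, spread = 0.3) {
  withr::with_seed(seed, {
    centers <- list(A = c(0, 0), D = c(5, 0), E = c(0, 5))
    purrr::imap(centers, function(mu, cl) {
      tibble::tibble(label = cl,
                     f1 = rnorm(n_per_class, mu[1], spread),
                     f2 = rnorm(n_per_class, mu[2], spread))
    }) |> purrr::list_rbind()
  })
}

# Random tiny QP instance (N <= 4) for solver-correctness checks.
random_qp_instance <- function(n = sample(2:4, 1)) {
  X <- matrix(rnorm(n * 2), n, 2)
  t <- sample(c(-1, 1), n, replace = TRUE)
  C <- sample(c(0.5, 1, 5), 1)
  spec <- kernel_spec("gaussian", two_sigma_sq = sample(c(0.5, 2, 10), 1))
  K <- kernel_matrix(X, spec = spec)
  list(X = X, t = t, C = C, spec = spec, H = outer(t, t) * K)
}
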