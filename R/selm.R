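#' Initialise the sparse-ELM training state
#'
#' Training minimises the box-constrained dual quadratic programme
#' \deqn{L_d(\alpha) = \tfrac12 \sum_{ij} \alpha_i \alpha_j t_i t_j
#'   k(x_i, x_j) - \sum_i \alpha_i, \qquad 0 \le \alpha_i \le C,}
#' which — unlike the SVM dual — carries no equality (sum) constraint, hence
#' no bias term; one multiplier is updated per iteration. At the start
#' \eqn{\alpha = 0}, the gradient is \eqn{g_i = -1} everywhere, the feasible
#' update direction is \eqn{d_i = +1} and \eqn{J_i = g_i d_i = -1}.
#'
#' @param x Numeric matrix (rows = training samples) or data frame containing
#'   the feature columns.
#' @param t Labels in \{-1, +1\}.
#' @param C Box bound (> 0).
#' @param epsilon Stopping tolerance \eqn{\varepsilon} (default 0.001):
#'   iteration stops when \eqn{\min_i J_i > -\varepsilon}.
#' @param kernel A [kernel_spec()].
#' @param gram_threshold Precompute the full N x N Gram matrix when
#'   \eqn{N \le} this (results are identical either way; only speed differs).
#' @return A `selm_state` list: `X`, `t`, `alpha`, `g`, `d`, `J`, `C`,
#'   `epsilon`, `kernel`, `iter`, plus the cached Gram matrix or kernel
#'   diagonal.
#' @export
selm_init_state <- function(x, t, C = 5, epsilon = 0.001,
                            kernel = kernel_spec(), gram_threshold = 6000L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  t <- as.numeric(t)
  n <- nrow(X)
  if (n < 1) abort("need at least one training sample",
                   class = "selmeeg_validation_error")
  if (length(t) != n || !all(t %in% c(-1, 1))) {
    abort("labels t must be a vector of -1/+1, one per training row",
          class = "selmeeg_validation_error")
  }
  if (!is.numeric(C) || C <= 0) {
    abort("box bound C must be positive", class = "selmeeg_validation_error")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    abort("tolerance epsilon must be positive",
          class = "selmeeg_validation_error")
  }
  stopifnot(inherits(kernel, "kernel_spec"))
  K <- if (n <= gram_threshold) kernel_matrix(X, spec = kernel) else NULL
  kdiag <- if (is.null(K)) {
    vapply(seq_len(n), function(i) kernel_eval(X[i, ], X[i, ], kernel),
           numeric(1))
  } else diag(K)
  structure(list(X = X, t = t, C = as.numeric(C),
                 epsilon = as.numeric(epsilon), kernel = kernel,
                 K = K, kdiag = kdiag,
                 alpha = numeric(n), g = rep(-1, n),
                 d = rep(1, n), J = rep(-1, n), iter = 0L),
            class = "selm_state")
}

# Feasible update direction: +1 at the lower bound, -1 at the upper bound,
# -sign(g) strictly inside the box. alpha hits 0/C exactly via clipping, so
# equality tests are safe.
selm_directions <- function(alpha, g, C) {
  d <- -sign(g)
  d[alpha == 0] <- 1
  d[alpha == C] <- -1
  d
}

#' Pick the multiplier to update, or signal convergence
#'
#' Returns the index minimising \eqn{J_i = g_i d_i} (ties to the lowest
#' index), or `NA` when \eqn{\min_i J_i > -\varepsilon} — the stopping rule.
#'
#' @param state A `selm_state`.
#' @return Integer index, or `NA_integer_` when training is finished.
#' @export
selm_select_index <- function(state) {
  c <- which.min(state$J)
  if (state$J[c] > -state$epsilon) NA_integer_ else as.integer(c)
}

#' One single-multiplier coordinate update
#'
#' Updates \eqn{\alpha_c \leftarrow \alpha_c - g_c} (`mode = "literal"`, the
#' printed rule, exact for unit-diagonal kernels) or
#' \eqn{\alpha_c \leftarrow \alpha_c - g_c / k(x_c, x_c)} (`mode = "newton"`,
#' the exact one-dimensional minimiser for any kernel; the two coincide for
#' the Gaussian kernel). The trial value is clipped to \eqn{[0, C]}, the
#' gradient is propagated with the clipped increment
#' \eqn{g_i \leftarrow g_i + t_i t_c k(x_i, x_c)(\alpha_c^{clip} -
#' \alpha_c^{old})}, and \eqn{d}, \eqn{J} are refreshed.
#'
#' @param state A `selm_state`.
#' @param c Index from [selm_select_index()].
#' @param mode `"newton"` (default) or `"literal"`.
#' @return The updated `selm_state`.
#' @export
selm_update_multiplier <- function(state, c, mode = c("newton", "literal")) {
  mode <- match.arg(mode)
  n <- length(state$alpha)
  if (!is.numeric(c) || is.na(c) || c < 1 || c > n) {
    abort("invalid multiplier index", class = "selmeeg_internal_error")
  }
  old <- state$alpha[c]
  step <- if (mode == "newton") state$g[c] / state$kdiag[c] else state$g[c]
  trial <- old - step
  new <- min(max(trial, 0), state$C)
  kcol <- if (!is.null(state$K)) state$K[, c] else
    drop(kernel_matrix(state$X, state$X[c, , drop = FALSE], state$kernel))
  state$alpha[c] <- new
  state$g <- state$g + state$t * state$t[c] * kcol * (new - old)
  state$d <- selm_directions(state$alpha, state$g, state$C)
  state$J <- state$g * state$d
  state$iter <- state$iter + 1L
  state
}

#' Dual objective value of the current multipliers
#'
#' @param state A `selm_state` (with cached Gram matrix), or a numeric
#'   `alpha` vector together with `t` and Gram matrix `K`.
#' @param t,K Labels and Gram matrix when `state` is a bare alpha vector.
#' @return The value of \eqn{L_d(\alpha)}.
#' @export
selm_dual_objective <- function(state, t = NULL, K = NULL) {
  if (inherits(state, "selm_state")) {
    alpha <- state$alpha; t <- state$t
    K <- state$K %||% kernel_matrix(state$X, spec = state$kernel)
  } else alpha <- state
  v <- alpha * t
  0.5 * drop(crossprod(v, K %*% v)) - sum(alpha)
}

#' Train a binary sparse extreme learning machine
#'
#' Runs the single-multiplier coordinate solver ([selm_select_index()] /
#' [selm_update_multiplier()]) to convergence (\eqn{\min_i J_i > -\varepsilon})
#' or `max_iter`, then retains only the samples with \eqn{\alpha_i > 0} as
#' support vectors with weights \eqn{\alpha_i t_i}.
#'
#' @inheritParams selm_init_state
#' @param max_iter Iteration cap (default `50 * N`); reaching it flags the
#'   model as non-converged.
#' @param mode Update rule, see [selm_update_multiplier()].
#' @return An object of class `selm`: list with `support_vectors` (matrix),
#'   `weights` (\eqn{\alpha_i t_i}), `kernel`, `converged`, `iterations`,
#'   `final_min_J`, `n_train`, `sparsity` (\eqn{N_s / N}), `dual_objective`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' fit <- selm_fit(x, rep(c(-1, 1), each = 20), C = 5,
#'                 kernel = kernel_spec("gaussian", two_sigma_sq = 4))
#' glance(fit)
selm_fit <- function(x, t, C = 5, epsilon = 0.001, kernel = kernel_spec(),
                     max_iter = NULL, mode = c("newton", "literal"),
                     gram_threshold = 6000L) {
  mode <- match.arg(mode)
  state <- selm_init_state(x, t, C = C, epsilon = epsilon, kernel = kernel,
                           gram_threshold = gram_threshold)
  n <- length(state$alpha)
  if (length(unique(state$t)) < 2) {
    warn("training set contains a single class; the model is degenerate")
  }
  max_iter <- max_iter %||% (50L * n)
  converged <- FALSE
  repeat {
    c <- selm_select_index(state)
    if (is.na(c)) { converged <- TRUE; break }
    if (state$iter >= max_iter) break
    state <- selm_update_multiplier(state, c, mode = mode)
  }
  sv <- state$alpha > 0
  structure(list(support_vectors = state$X[sv, , drop = FALSE],
                 weights = state$alpha[sv] * state$t[sv],
                 alpha = state$alpha[sv],
                 sv_labels = state$t[sv],
                 kernel = state$kernel,
                 C = state$C, epsilon = state$epsilon, mode = mode,
                 converged = converged, iterations = state$iter,
                 final_min_J = min(state$J),
                 n_train = n, n_support = sum(sv),
                 sparsity = sum(sv) / n,
                 dual_objective = selm_dual_objective(state),
                 feature_names = colnames(state$X)),
            class = "selm")
}

#' Raw decision value of a binary model
#'
#' \eqn{\sum_{i=1}^{N_s} \alpha_i t_i k(x, x_i)} over the support vectors —
#' the pre-sign value of the decision function. A model with no support
#' vectors returns 0.
#'
#' @param model A fitted `selm`.
#' @param x Numeric vector, matrix or data frame of query points (rows).
#' @return Numeric vector of decision values, one per query row.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "selm"))
  X <- query_matrix(model, x)
  if (model$n_support == 0) return(numeric(nrow(X)))
  drop(kernel_matrix(X, model$support_vectors, model$kernel) %*% model$weights)
}

#' @export
#' @describeIn decision_value Predicted -1/+1 labels; `sign(0)` maps to `+1`.
predict.selm <- function(object, newdata, ...) {
  f <- decision_value(object, newdata)
  ifelse(f >= 0, 1, -1)
}

query_matrix <- function(model, x) {
  if (is.data.frame(x)) {
    fn <- model$feature_names
    if (!is.null(fn) && all(fn %in% names(x))) x <- x[fn]
    x <- as.matrix(x)
  } else if (is.null(dim(x))) {
    x <- matrix(as.numeric(x), nrow = 1)
  }
  if (ncol(x) != ncol(model$support_vectors) && model$n_support > 0) {
    abort(sprintf("query dimension %d does not match training dimension %d",
                  ncol(x), ncol(model$support_vectors)),
          class = "selmeeg_validation_error")
  }
  x
}

#' @export
print.selm <- function(x, ...) {
  cat("<selm> binary sparse extreme learning machine\n")
  cat("  kernel:", x$kernel$family, "| C =", x$C, "| epsilon =", x$epsilon, "\n")
  cat(sprintf("  support vectors: %d / %d (sparsity %.3f), %s after %d iterations\n",
              x$n_support, x$n_train, x$sparsity,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binary SELM: one row per support vector
#' @param x A fitted `selm`.
#' @param ... Unused.
#' @method tidy selm
#' @export
tidy.selm <- function(x, ...) {
  svm <- x$support_vectors
  if (is.null(colnames(svm)) && ncol(svm) > 0) {
    colnames(svm) <- paste0("x", seq_len(ncol(svm)))
  }
  sv <- as_tibble(svm)
  dplyr::bind_cols(tibble(alpha = x$alpha, label = x$sv_labels,
                          weight = x$weights), sv)
}

#' One-row training summary of a binary SELM
#' @param x A fitted `selm`.
#' @param ... Unused.
#' @method glance selm
#' @export
glance.selm <- function(x, ...) {
  tibble(n_train = x$n_train, n_support = x$n_support,
         sparsity = x$sparsity, iterations = x$iterations,
         converged = x$converged, final_min_J = x$final_min_J,
         dual_objective = x$dual_objective)
}

# --- serialization ----------------------------------------------------------

#' Serialize / restore a binary SELM as JSON
#'
#' Doubles are written at full precision so the round trip is exact.
#'
#' @param model A fitted `selm` (or, for multiclass, see
#'   [write_selm_multiclass()]).
#' @param path File path.
#' @return `read_selm()` returns the model; the writer returns `path`
#'   invisibly.
#' @export
write_selm <- function(model, path) {
  stopifnot(inherits(model, "selm"))
  obj <- unclass(model)
  obj$kernel <- unclass(obj$kernel)
  obj$support_vectors <- unname(as.matrix(obj$support_vectors))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_selm
#' @export
read_selm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$kernel <- structure(obj$kernel, class = "kernel_spec")
  sv <- obj$support_vectors
  if (is.null(sv) || length(sv) == 0) sv <- matrix(numeric(), 0, 0)
  obj$support_vectors <- as.matrix(sv)
  if (!is.null(obj$feature_names) && ncol(obj$support_vectors) > 0) {
    colnames(obj$support_vectors) <- obj$feature_names
  }
  for (f in c("weights", "alpha", "sv_labels")) {
    obj[[f]] <- as.numeric(obj[[f]] %||% numeric())
  }
  structure(obj, class = "selm")
}
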