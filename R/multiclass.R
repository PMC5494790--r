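#' Train a three-class SELM classifier
#'
#' Combines binary sparse-ELM classifiers into a multiclass decision rule
#' using one of five strategies:
#' \describe{
#'   \item{oaa}{One-against-all: one model per class (that class +1, rest -1);
#'     predict by the largest raw decision value.}
#'   \item{oao}{One-against-one: one model per class pair, trained only on
#'     that pair's samples; majority vote, with the 1-1-1 tie resolved by the
#'     pairwise classifier of largest absolute decision value.}
#'   \item{dag}{Same three pairwise models as `oao`; prediction walks a rooted
#'     directed acyclic graph, eliminating one class per node (two binary
#'     evaluations per query).}
#'   \item{ecoc}{Same models as `oaa`; the sign vector of the three outputs is
#'     matched to the target codes (1,-1,-1), (-1,1,-1), (-1,-1,1) by minimum
#'     Hamming distance.}
#'   \item{bt}{Binary tree: a root model splits one class from the rest, a
#'     second model separates the remaining pair (two models total).}
#' }
#'
#' @param data Data frame with a label column and the feature columns (the
#'   eight [feature_names()] columns if present, otherwise every numeric
#'   column).
#' @param strategy One of `"oao"`, `"oaa"`, `"dag"`, `"ecoc"`, `"bt"`.
#' @param class_list Ordered class labels (default A, D, E); order fixes the
#'   numbering used by tie-breaks and pair construction.
#' @param structure Strategy structure: for `dag`, the root pair as a length-2
#'   character vector (default the first and last class, `c("A","E")`); for
#'   `bt`, the class split off at the root (default `"E"`, the most separable
#'   ictal class). Ignored otherwise.
#' @param label Name of the label column (default `"label"`).
#' @param C,epsilon,kernel,mode,max_iter Passed to [selm_fit()].
#' @return An object of class `selm_multiclass`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   label = rep(c("A", "D", "E"), each = 20),
#'   f1 = rnorm(60, rep(c(0, 3, 6), each = 20)),
#'   f2 = rnorm(60, rep(c(0, 3, 6), each = 20)))
#' m <- train_multiclass(d, "oao", kernel = kernel_spec(two_sigma_sq = 10))
#' table(predict(m, d), d$label)
train_multiclass <- function(data,
                             strategy = c("oao", "oaa", "dag", "ecoc", "bt"),
                             class_list = c("A", "D", "E"),
                             structure = NULL, label = "label",
                             C = 5, epsilon = 0.001,
                             kernel = kernel_spec(),
                             mode = c("newton", "literal"),
                             max_iter = NULL) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (!label %in% names(data)) {
    abort(paste0("no label column '", label, "' in data"),
          class = "selmeeg_validation_error")
  }
  y <- as.character(data[[label]])
  k <- length(class_list)
  missing <- setdiff(class_list, unique(y))
  if (length(missing) > 0) {
    abort(paste0("training data has no samples of class: ",
                 paste(missing, collapse = ", ")),
          class = "selmeeg_validation_error")
  }
  X <- multiclass_matrix(data, label)
  fit1 <- function(rows, t) {
    selm_fit(X[rows, , drop = FALSE], t, C = C, epsilon = epsilon,
             kernel = kernel, mode = mode, max_iter = max_iter)
  }
  models <- switch(strategy,
    oaa = ,
    ecoc = lapply(class_list, function(cl) {
      fit1(seq_along(y), ifelse(y == cl, 1, -1))
    }) |> stats::setNames(class_list),
    oao = ,
    dag = {
      pairs <- utils::combn(class_list, 2, simplify = FALSE)
      lapply(pairs, function(pr) {
        rows <- which(y %in% pr)
        fit1(rows, ifelse(y[rows] == pr[1], 1, -1))
      }) |> stats::setNames(vapply(pairs, paste, "", collapse = "|"))
    },
    bt = {
      root <- (structure %||% "E")[1]
      if (!root %in% class_list) {
        abort("bt structure must name a class in class_list",
              class = "selmeeg_validation_error")
      }
      rest <- setdiff(class_list, root)
      list(root = fit1(seq_along(y), ifelse(y == root, 1, -1)),
           pair = {
             rows <- which(y %in% rest)
             fit1(rows, ifelse(y[rows] == rest[1], 1, -1))
           })
    })
  if (strategy == "dag") {
    structure <- structure %||% c(class_list[1], class_list[k])
    if (length(structure) != 2 || !all(structure %in% class_list)) {
      abort("dag structure must be a pair of classes from class_list",
            class = "selmeeg_validation_error")
    }
  }
  if (strategy == "bt") structure <- (structure %||% "E")[1]
  base::structure(
    list(strategy = strategy, class_list = class_list,
         structure = structure, binary_models = models,
         feature_names = colnames(X)),
    class = "selm_multiclass")
}

multiclass_matrix <- function(data, label) {
  fn <- feature_names()
  if (all(fn %in% names(data))) return(feature_matrix(data))
  num <- vapply(data, is.numeric, logical(1))
  num[label] <- FALSE
  as.matrix(data[num])
}

mc_query <- function(model, x) {
  if (is.data.frame(x)) {
    fn <- model$feature_names
    if (all(fn %in% names(x))) x <- x[fn]
    x <- as.matrix(x)
  } else if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x
}

#' @export
print.selm_multiclass <- function(x, ...) {
  cat("<selm_multiclass> strategy:", toupper(x$strategy),
      "| classes:", paste(x$class_list, collapse = ", "), "\n")
  if (!is.null(x$structure))
    cat("  structure:", paste(x$structure, collapse = " vs "), "\n")
  cat("  binary models:", length(x$binary_models), "\n")
  invisible(x)
}

#' Predict classes from a multiclass SELM
#'
#' Dispatches to the strategy-specific rule ([predict_oaa()],
#' [predict_oao()], [predict_dag()], [predict_ecoc()], [predict_bt()]).
#'
#' @param object A `selm_multiclass`.
#' @param newdata Feature data frame or matrix (rows = queries).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.selm_multiclass <- function(object, newdata, ...) {
  switch(object$strategy,
         oaa = predict_oaa(object, newdata),
         oao = predict_oao(object, newdata),
         dag = predict_dag(object, newdata),
         ecoc = predict_ecoc(object, newdata),
         bt = predict_bt(object, newdata))
}

#' One-against-all decision rule
#'
#' Argmax of the raw (pre-sign) one-vs-rest decision values; ties go to the
#' class earliest in `class_list`.
#'
#' @param model A `selm_multiclass` trained with the matching strategy.
#' @param x Query features (data frame or matrix).
#' @return Character vector of class labels.
#' @export
predict_oaa <- function(model, x) {
  stopifnot(model$strategy %in% c("oaa", "ecoc"))
  F <- oaa_values(model, x)
  model$class_list[apply(F, 1, which.max)]
}

oaa_values <- function(model, x) {
  x <- mc_query(model, x)
  vapply(model$binary_models, decision_value, numeric(nrow(x)), x = x) |>
    matrix(nrow = nrow(x))
}

pairwise_values <- function(model, x) {
  x <- mc_query(model, x)
  F <- vapply(model$binary_models, decision_value, numeric(nrow(x)), x = x)
  matrix(F, nrow = nrow(x),
         dimnames = list(NULL, names(model$binary_models)))
}

#' One-against-one majority vote
#'
#' Each pairwise model votes by its sign (`sign(0)` counts for the pair's
#' first class). With three classes the vote is either 2-1 (majority wins) or
#' 1-1-1; the tie is resolved by the pairwise classifier with the largest
#' absolute decision value, whose sign picks the class.
#'
#' @inheritParams predict_oaa
#' @export
predict_oao <- function(model, x) {
  stopifnot(model$strategy %in% c("oao", "dag"))
  cl <- model$class_list
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  F <- pairwise_values(model, x)
  vapply(seq_len(nrow(F)), function(r) {
    votes <- stats::setNames(numeric(length(cl)), cl)
    for (j in seq_along(pairs)) {
      winner <- if (F[r, j] >= 0) pairs[[j]][1] else pairs[[j]][2]
      votes[winner] <- votes[winner] + 1
    }
    top <- max(votes)
    if (sum(votes == top) == 1) {
      names(votes)[which.max(votes)]
    } else {
      # 1-1-1 tie: the most confident pairwise classifier decides
      j <- which.max(abs(F[r, ]))
      if (F[r, j] >= 0) pairs[[j]][1] else pairs[[j]][2]
    }
  }, character(1))
}

#' Directed-acyclic-graph decision rule
#'
#' Starts at the root pair; each evaluated pairwise classifier eliminates its
#' losing class and the walk descends to the pair of survivors. With three
#' classes exactly two binary evaluations are made per query.
#'
#' @inheritParams predict_oaa
#' @export
predict_dag <- function(model, x) {
  stopifnot(model$strategy == "dag")
  cl <- model$class_list
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  keys <- vapply(pairs, paste, "", collapse = "|")
  F <- pairwise_values(model, x)
  pair_col <- function(a, b) {
    key <- paste(sort_by_list(c(a, b), cl), collapse = "|")
    match(key, keys)
  }
  root <- model$structure
  vapply(seq_len(nrow(F)), function(r) {
    p <- sort_by_list(root, cl)
    j <- pair_col(p[1], p[2])
    loser <- if (F[r, j] >= 0) p[2] else p[1]
    surv <- setdiff(cl, loser)
    j2 <- pair_col(surv[1], surv[2])
    if (F[r, j2] >= 0) surv[1] else surv[2]
  }, character(1))
}

sort_by_list <- function(x, class_list) x[order(match(x, class_list))]

#' Error-correcting-output-code decision rule
#'
#' The sign vector of the three one-vs-rest outputs is compared with the
#' target codes (1,-1,-1), (-1,1,-1), (-1,-1,1); the class at minimum Hamming
#' distance wins, ties to the earliest class in `class_list`.
#'
#' @inheritParams predict_oaa
#' @export
predict_ecoc <- function(model, x) {
  stopifnot(model$strategy == "ecoc")
  k <- length(model$class_list)
  codes <- 2 * diag(k) - 1          # rows: target code per class
  S <- sign(oaa_values(model, x))
  S[S == 0] <- 1
  pred <- apply(S, 1, function(s) {
    which.min(colSums(abs(t(codes) - s) > 0))
  })
  model$class_list[pred]
}

#' Binary-tree decision rule
#'
#' The root model either claims its class (one evaluation) or defers to the
#' second model on the remaining pair.
#'
#' @inheritParams predict_oaa
#' @export
predict_bt <- function(model, x) {
  stopifnot(model$strategy == "bt")
  root <- model$structure
  rest <- setdiff(model$class_list, root)
  f1 <- decision_value(model$binary_models$root, mc_query(model, x))
  f2 <- decision_value(model$binary_models$pair, mc_query(model, x))
  ifelse(f1 >= 0, root, ifelse(f2 >= 0, rest[1], rest[2]))
}

#' Tidy a multiclass model: one row per binary model
#' @param x A `selm_multiclass`.
#' @param ... Unused.
#' @method tidy selm_multiclass
#' @export
tidy.selm_multiclass <- function(x, ...) {
  purrr::imap(x$binary_models, function(m, role) {
    dplyr::bind_cols(tibble(role = role), glance(m))
  }) |> purrr::list_rbind()
}

#' Serialize / restore a multiclass SELM as JSON
#'
#' @param model A `selm_multiclass`.
#' @param path File path.
#' @return `read_selm_multiclass()` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_selm_multiclass <- function(model, path) {
  stopifnot(inherits(model, "selm_multiclass"))
  tmp <- tempfile(fileext = rep(".json", length(model$binary_models)))
  bin <- purrr::map2(model$binary_models, tmp, function(m, p) {
    write_selm(m, p)
    jsonlite::read_json(p)
  })
  unlink(tmp)
  obj <- list(strategy = model$strategy, class_list = model$class_list,
              structure = model$structure,
              feature_names = model$feature_names,
              binary_models = bin)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_selm_multiclass
#' @export
read_selm_multiclass <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  bin <- purrr::map(obj$binary_models, function(b) {
    p <- tempfile(fileext = ".json")
    jsonlite::write_json(b, p, digits = I(17), auto_unbox = TRUE, null = "null")
    on.exit(unlink(p))
    read_selm(p)
  })
  names(bin) <- names(obj$binary_models)
  base::structure(
    list(strategy = obj$strategy,
         class_list = unlist(obj$class_list),
         structure = if (is.null(obj$structure)) NULL else
           unlist(obj$structure),
         binary_models = bin,
         feature_names = unlist(obj$feature_names)),
    class = "selm_multiclass")
}
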