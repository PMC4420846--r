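# Soft-margin linear support vector machine for active/inactive
# discrimination, with C-grid search under stratified, compound-grouped
# cross-validation.
#
# The classifier solves the standard primal
#   min_{w,b}  1/2 ||w||^2 + C sum_i xi_i
#   s.t.       y_i (<w, x_i> - b) >= 1 - xi_i,  xi_i >= 0
# equivalently its dual
#   max_a  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j <x_i, x_j>
#   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0,
# with the linear kernel only. The quadratic program is delegated to
# libsvm (via e1071); the returned model always carries the dual
# multipliers so that feasibility (sum a_i y_i = 0, 0 <= a_i <= C) can be
# checked post-hoc, and w = sum_i a_i y_i x_i is reconstructed explicitly.

#' Fit a soft-margin linear SVM
#'
#' @param x Numeric feature matrix (instances x positions) or a
#'   `feature_matrix`.
#' @param y Labels in \{-1, +1\}; ignored when `x` is a `feature_matrix`.
#' @param C Soft-margin cost parameter (> 0), the upper bound on the dual
#'   multipliers.
#' @return Object of class `linear_svm` with components `w` (hyperplane
#'   normal), `b` (offset; the decision value is `<w, x> - b`), `C`,
#'   `alpha` (dual multipliers, zero off the support set), `xi` (training
#'   slacks), `support` (support-vector row indices) and `dual_objective`.
#' @export
svm_linear <- function(x, y = NULL, C = 1) {
  if (inherits(x, "feature_matrix")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (!is.numeric(C) || C <= 0) stop("C must be positive")
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho
  # libsvm orients the decision function towards its internal first class;
  # normalise so that sign(<w,x> - b) predicts +1
  pred <- as.integer(as.character(stats::predict(fit, x)))
  raw <- drop(x %*% w) - b
  agree <- mean(sign(raw) == pred, na.rm = TRUE)
  if (!is.nan(agree) && agree < 0.5) { w <- -w; b <- -b }
  alpha <- numeric(nrow(x))
  raw <- drop(x %*% w) - b
  # coefs = (+-1) * alpha_i * y_i in libsvm's orientation; recover alpha
  a_sv <- as.numeric(fit$coefs) * y[fit$index]
  if (length(a_sv) > 0 && sum(a_sv) < 0) a_sv <- -a_sv
  alpha[fit$index] <- a_sv
  xi <- pmax(0, 1 - y * raw)
  structure(list(w = w, b = b, C = C, alpha = alpha, xi = xi, y = y,
                 support = fit$index,
                 dual_objective = sum(alpha) - 0.5 * sum(w^2),
                 levels = c(-1L, 1L)),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("Linear SVM: %d features, %d support vectors, C = %g\n",
              length(x$w), length(x$support), x$C))
  cat(sprintf("  dual objective %.6g, |sum alpha_i y_i| = %.2e\n",
              x$dual_objective, abs(sum(x$alpha * x$y))))
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) {
  c(b = object$b, object$w)
}

#' Predict from a fitted linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Feature matrix or `feature_matrix`.
#' @param type `"class"` for \{-1, +1\} labels, `"decision"` for the raw
#'   decision value `<w, x> - b`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  f <- drop(as.matrix(newdata) %*% object$w) - object$b
  if (type == "decision") f else ifelse(f >= 0, 1L, -1L)
}

#' Verify dual feasibility of a fitted model
#'
#' Checks `sum_i alpha_i y_i = 0` (within `tol`) and
#' `0 <= alpha_i <= C` for all multipliers.
#'
#' @param model A `linear_svm`.
#' @param y Training labels the model was fitted on; taken from the model
#'   when omitted.
#' @param tol Tolerance on the equality constraint.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_dual_feasibility <- function(model, y = model$y, tol = 1e-6) {
  if (any(model$alpha < -tol) || any(model$alpha > model$C + tol))
    stop("dual multipliers outside [0, C]")
  r <- abs(sum(model$alpha * y))
  if (r > tol * max(1, sum(model$alpha)))
    stop("sum alpha_i y_i = ", r, " violates the equality constraint")
  invisible(TRUE)
}

#' @noRd
default_C_grid <- function() c(0.01, 0.1, 1, 10, 100, 1000, 10000)

# Stratified, group-aware fold assignment: per class, whole parent-compound
# groups are shuffled and dealt round-robin over folds.
#' @noRd
make_folds <- function(y, groups, k, seed) {
  fold_of_group <- list()
  rng <- local({ set.seed(seed); function(n) sample(n) })
  for (cls in c(1L, -1L)) {
    g <- unique(groups[y == cls])
    if (length(g) < k)
      stop("class ", cls, " has ", length(g),
           " compound groups; too few for ", k, "-fold stratification")
    g <- g[rng(length(g))]
    fold_of_group[g] <- rep_len(seq_len(k), length(g))
  }
  unlist(fold_of_group[groups], use.names = FALSE)
}

#' C-grid search under stratified group-aware cross-validation
#'
#' For each candidate cost `C`, fits the linear SVM on k-1 folds and
#' predicts the held-out fold; confusion counts are pooled over the k
#' folds and the pooled MCC is the selection criterion (the mean of
#' per-fold MCCs is also reported). Folds are stratified by class and
#' grouped by parent compound so that protonation-state instances of one
#' compound never straddle a fold boundary.
#'
#' @param data A [feature_matrix()].
#' @param C_grid Candidate costs; defaults to
#'   `0.01, 0.1, 1, 10, 100, 1000, 10000`.
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `svm_cv`: list with `per_C` (data.frame of
#'   `C`, `mcc_pooled`, `mcc_fold_mean`, `auroc_pooled`), `best_C` (tie
#'   broken towards the smaller cost), `best_mcc`, `counts` (pooled
#'   [confusion_counts()] at `best_C`), `per_fold_counts`, `folds`.
#' @export
cross_validate <- function(data, C_grid = default_C_grid(), k_folds = 10,
                           seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"), k_folds >= 2)
  folds <- make_folds(data$y, data$groups, k_folds, seed)
  per_C <- data.frame(C = C_grid, mcc_pooled = NA_real_,
                      mcc_fold_mean = NA_real_, auroc_pooled = NA_real_)
  all_counts <- vector("list", length(C_grid))
  for (ci in seq_along(C_grid)) {
    pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    fold_counts <- vector("list", k_folds)
    dec <- numeric(length(data$y))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      m <- svm_linear(data$x[tr, , drop = FALSE], data$y[tr], C = C_grid[ci])
      p <- predict(m, data$x[!tr, , drop = FALSE])
      dec[!tr] <- predict(m, data$x[!tr, , drop = FALSE], type = "decision")
      cc <- count_confusion(data$y[!tr], p)
      fold_counts[[f]] <- cc
      pooled <- pooled + unlist(cc)
    }
    all_counts[[ci]] <- list(
      pooled = confusion_counts(pooled["tp"], pooled["tn"],
                                pooled["fp"], pooled["fn"]),
      per_fold = fold_counts)
    per_C$mcc_pooled[ci] <- compute_mcc(all_counts[[ci]]$pooled)
    per_C$mcc_fold_mean[ci] <- mean(vapply(fold_counts, compute_mcc,
                                           numeric(1)))
    per_C$auroc_pooled[ci] <- compute_auroc(dec[data$y == 1],
                                            dec[data$y == -1])
  }
  best <- which(per_C$mcc_pooled == max(per_C$mcc_pooled))
  best <- best[which.min(per_C$C[best])]
  structure(list(per_C = per_C, best_C = per_C$C[best],
                 best_mcc = per_C$mcc_pooled[best],
                 counts = all_counts[[best]]$pooled,
                 per_fold_counts = all_counts[[best]]$per_fold,
                 folds = folds, k_folds = k_folds, seed = seed),
            class = "svm_cv")
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d costs\n", x$k_folds,
              nrow(x$per_C)))
  print(x$per_C, row.names = FALSE)
  cat(sprintf("best C = %g (pooled MCC %.4f)\n", x$best_C, x$best_mcc))
  invisible(x)
}
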