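#' Kernel matrix for LS-SVM kernels
#'
#' Supported kernels: `linear` (x.y), `quadratic` and `cubic` (inhomogeneous
#' polynomial (x.y + 1)^p with p = 2, 3), and `rbf`
#' (exp(-||x - y||^2 / (2 sigma^2))).
#'
#' @param x,y Numeric matrices with observations in rows (same number of
#'   columns).
#' @param kernel One of `"linear"`, `"quadratic"`, `"cubic"`, `"rbf"`.
#' @param sigma RBF bandwidth (required for `"rbf"`).
#' @return The `nrow(x)` by `nrow(y)` kernel matrix.
#' @export
lssvm_kernel <- function(x, y, kernel = c("linear", "quadratic", "cubic", "rbf"),
                         sigma = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x); y <- as.matrix(y)
  if (kernel == "rbf") {
    if (is.null(sigma)) abort("`sigma` is required for the rbf kernel.")
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    return(exp(-d2 / (2 * sigma^2)))
  }
  g <- tcrossprod(x, y)
  switch(kernel, linear = g, quadratic = (g + 1)^2, cubic = (g + 1)^3)
}

#' Train a binary least-squares SVM
#'
#' Solves the LS-SVM dual in one ridge-regularised linear system
#' \deqn{\begin{pmatrix} 0 & 1^\top \\ 1 & K + I/C \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' with labels \eqn{y_i \in \{-1, +1\}}. The decision value at `x` is
#' \eqn{\sum_i \alpha_i k(x_i, x) + b} and the predicted label is its sign.
#'
#' @param x Training matrix (rows = observations).
#' @param y Labels coded -1 / +1.
#' @param kernel,sigma See [lssvm_kernel()].
#' @param C Positive box-constraint-like regularisation parameter; larger C
#'   means less regularisation.
#' @return A `ct_lssvm` model (support coefficients `alpha`, bias `b`, the
#'   training data and kernel spec).
#' @export
lssvm_train <- function(x, y, kernel = "rbf", C = 1, sigma = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) abort("`y` must be coded -1 / +1.")
  if (length(y) != nrow(x)) abort("`x` and `y` sizes disagree.")
  assert_scalar_number(C, "C", positive = TRUE)
  n <- nrow(x)
  K <- lssvm_kernel(x, x, kernel, sigma)
  A <- rbind(
    c(0, rep(1, n)),
    cbind(rep(1, n), K + diag(n) / C)
  )
  sol <- tryCatch(solve(A, c(0, y)), error = function(e) {
    abort(sprintf("LS-SVM system is singular (%s).", conditionMessage(e)))
  })
  structure(
    list(alpha = sol[-1], b = sol[1], x = x, y = y,
         kernel = kernel, C = C, sigma = sigma),
    class = "ct_lssvm"
  )
}

#' Decision values of a trained LS-SVM
#'
#' @param model A `ct_lssvm` from [lssvm_train()].
#' @param newdata Matrix of rows to score.
#' @return Numeric decision values; the predicted label is their sign.
#' @export
lssvm_decision <- function(model, newdata) {
  K <- lssvm_kernel(as.matrix(newdata), model$x, model$kernel, model$sigma)
  drop(K %*% model$alpha) + model$b
}

#' @export
predict.ct_lssvm <- function(object, newdata, ...) {
  sign(lssvm_decision(object, newdata))
}

# ---- hierarchical multiclass tree -----------------------------------------

tree_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Binary-split tree for hierarchical LS-SVM multiclass classification
#'
#' A tree is a nested list where a leaf is a class name and an inner node is
#' `list(left = , right = )`; each inner node carries one binary LS-SVM
#' separating the classes under its left child from those under its right
#' child. The default tree for the dantrolene response classes first splits
#' responders + semi-responders against non-responders, then responders
#' against semi-responders (mirroring the class-merging analyses); for other
#' label sets the classes are peeled off one by one in sorted order.
#'
#' @param classes Character vector of class labels.
#' @return A tree (nested list) whose leaves are exactly `classes`.
#' @export
lssvm_default_tree <- function(classes) {
  classes <- unique(classes)
  if (setequal(classes, c("responder", "semi_responder", "non_responder"))) {
    return(list(left = list(left = "responder", right = "semi_responder"),
                right = "non_responder"))
  }
  classes <- sort(classes)
  if (length(classes) == 1L) return(classes)
  list(left = classes[1], right = lssvm_default_tree(classes[-1]))
}

validate_tree <- function(tree, classes) {
  lv <- tree_leaves(tree)
  if (anyDuplicated(lv) || !setequal(lv, classes)) {
    abort(sprintf(
      "malformed LS-SVM tree: leaves (%s) must cover the classes (%s) exactly once.",
      paste(lv, collapse = ", "), paste(classes, collapse = ", ")
    ))
  }
  invisible(tree)
}

hierarchical_lssvm_train <- function(x, labels, tree, kernel, C, sigma) {
  if (is.character(tree)) return(tree)  # leaf
  left_cl <- tree_leaves(tree$left)
  right_cl <- tree_leaves(tree$right)
  in_node <- labels %in% c(left_cl, right_cl)
  y <- ifelse(labels[in_node] %in% left_cl, 1, -1)
  model <- if (length(unique(y)) == 2L) {
    lssvm_train(x[in_node, , drop = FALSE], y, kernel, C, sigma)
  } else {
    NULL  # a fold can lose a class; route by the majority side
  }
  list(
    model = model,
    default_side = if (!length(y) || mean(y == 1) >= 0.5) "left" else "right",
    left = hierarchical_lssvm_train(x, labels, tree$left, kernel, C, sigma),
    right = hierarchical_lssvm_train(x, labels, tree$right, kernel, C, sigma)
  )
}

#' Route rows through a hierarchical LS-SVM
#'
#' @param node A trained tree from the internal hierarchical trainer (as
#'   stored in LS-SVM fits produced by [fit_predict()]).
#' @param newdata Matrix of rows to classify.
#' @return Character vector of leaf class labels.
#' @export
hierarchical_predict <- function(node, newdata) {
  newdata <- as.matrix(newdata)
  if (is.character(node)) return(rep(node, nrow(newdata)))
  side <- if (is.null(node$model)) {
    rep(node$default_side == "left", nrow(newdata))
  } else {
    lssvm_decision(node$model, newdata) >= 0
  }
  out <- character(nrow(newdata))
  if (any(side)) {
    out[side] <- hierarchical_predict(node$left,
                                      newdata[side, , drop = FALSE])
  }
  if (any(!side)) {
    out[!side] <- hierarchical_predict(node$right,
                                       newdata[!side, , drop = FALSE])
  }
  out
}
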