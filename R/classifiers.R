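ct_families <- c("knn", "lda", "qda", "mahalanobis_da", "cart",
                 "multinomial_logistic", "nb_gaussian", "nb_kernel",
                 "random_forest", "lssvm")
ct_knn_metrics <- c("chebychev", "cityblock", "correlation", "cosine",
                    "euclidean", "mahalanobis", "seuclidean", "spearman")
ct_knn_weightings <- c("equal", "inverse", "squared_inverse")
ct_nb_kernels <- c("normal", "box", "epanechnikov", "triangle")
ct_lssvm_kernels <- c("linear", "quadratic", "cubic", "rbf")

#' Configure a classifier from the zoo
#'
#' Families and their hyperparameters:
#'
#' * `knn`: `metric` (one of chebychev, cityblock, correlation, cosine,
#'   euclidean, mahalanobis, seuclidean, spearman), `weighting` (`equal`,
#'   `inverse` = 1/d, `squared_inverse` = 1/d^2), `K` (odd, 1-37).
#' * `lda`, `qda`: no hyperparameters (pooled / per-class covariance
#'   discriminants with log-determinant term, via MASS).
#' * `mahalanobis_da`: per-class Mahalanobis-distance classification without
#'   the log-determinant term.
#' * `cart`: classification tree (rpart, deterministic, no internal
#'   cross-validation).
#' * `multinomial_logistic`: multinomial logistic regression (logistic in
#'   the binary case), via nnet.
#' * `nb_gaussian`: naive Bayes with Gaussian class-conditional densities.
#' * `nb_kernel`: naive Bayes with univariate kernel density estimates;
#'   `kernel` one of `normal`, `box`, `epanechnikov`, `triangle`, Silverman
#'   bandwidth per class and variable.
#' * `random_forest`: `n_trees` (1-100) and `seed`.
#' * `lssvm`: least-squares SVM; `kernel` one of `linear`, `quadratic`,
#'   `cubic`, `rbf`, regularisation `C` and (rbf only) bandwidth `sigma`,
#'   both in \[2^-12, 2^17\]; multiclass problems are decomposed by a
#'   hierarchical binary tree (`tree`, default [lssvm_default_tree()]).
#'
#' @param family Classifier family name.
#' @param ... Family-specific hyperparameters, validated against the spaces
#'   above.
#' @param seed Integer seed used by stochastic fits (random forest,
#'   multinomial logistic initialisation) so results are reproducible.
#' @param regularize Add a small ridge to covariance estimates for the
#'   Mahalanobis-type methods when they would otherwise be singular.
#' @return A `ct_classifier_config`.
#' @export
classifier_config <- function(family, ..., seed = 20200504L,
                              regularize = FALSE) {
  if (!family %in% ct_families) {
    abort(sprintf("unknown classifier family '%s'.", family))
  }
  p <- list(...)
  bad <- function(msg) abort(sprintf("invalid %s hyperparameters: %s", family, msg))
  if (family == "knn") {
    p$metric <- p$metric %||% "euclidean"
    p$weighting <- p$weighting %||% "equal"
    p$K <- p$K %||% 1L
    if (!p$metric %in% ct_knn_metrics) bad(sprintf("metric '%s'.", p$metric))
    if (!p$weighting %in% ct_knn_weightings) bad(sprintf("weighting '%s'.", p$weighting))
    if (p$K < 1 || p$K > 37 || p$K %% 2 != 1) bad("K must be odd in 1..37.")
  } else if (family == "nb_kernel") {
    p$kernel <- p$kernel %||% "normal"
    if (!p$kernel %in% ct_nb_kernels) bad(sprintf("kernel '%s'.", p$kernel))
  } else if (family == "random_forest") {
    p$n_trees <- p$n_trees %||% 50L
    if (p$n_trees < 1 || p$n_trees > 100) bad("n_trees must be in 1..100.")
  } else if (family == "lssvm") {
    p$kernel <- p$kernel %||% "rbf"
    p$C <- p$C %||% 1
    if (!p$kernel %in% ct_lssvm_kernels) bad(sprintf("kernel '%s'.", p$kernel))
    if (p$C < 2^-12 || p$C > 2^17) bad("C must lie in [2^-12, 2^17].")
    if (p$kernel == "rbf") {
      p$sigma <- p$sigma %||% 1
      if (p$sigma < 2^-12 || p$sigma > 2^17) bad("sigma must lie in [2^-12, 2^17].")
    }
  }
  structure(
    list(family = family, params = p, seed = as.integer(seed),
         regularize = isTRUE(regularize)),
    class = "ct_classifier_config"
  )
}

#' @export
print.ct_classifier_config <- function(x, ...) {
  hp <- x$params[!vapply(x$params, is.null, logical(1))]
  hp <- hp[!vapply(hp, is.list, logical(1))]
  cat(sprintf("<ct_classifier_config> %s(%s)\n", x$family,
              paste(names(hp), unlist(hp), sep = " = ", collapse = ", ")))
  invisible(x)
}

feature_matrix <- function(features) {
  as.matrix(features[, ct_feature_names, drop = FALSE])
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# ---- KNN ------------------------------------------------------------------

knn_distances <- function(xtr, xte, metric, regularize = FALSE) {
  row_center <- function(m) m - rowMeans(m)
  unit_rows <- function(m) {
    nr <- sqrt(rowSums(m^2))
    nr[nr == 0] <- 1
    m / nr
  }
  switch(metric,
    euclidean = ,
    seuclidean = ,
    mahalanobis = {
      if (metric == "seuclidean") {
        v <- apply(xtr, 2, var)
        if (any(v == 0)) {
          if (!regularize) {
            abort("zero variance for seuclidean metric; set regularize = TRUE.")
          }
          v[v == 0] <- 1e-8
        }
        xtr <- sweep(xtr, 2, sqrt(v), "/")
        xte <- sweep(xte, 2, sqrt(v), "/")
      }
      if (metric == "mahalanobis") {
        S <- stats::cov(xtr)
        if (regularize) S <- S + diag(mean(diag(S)) * 1e-6, ncol(S))
        ch <- tryCatch(chol(S), error = function(e) {
          abort("singular covariance for mahalanobis metric; set regularize = TRUE.")
        })
        W <- backsolve(ch, diag(ncol(S)), transpose = FALSE)
        xtr <- xtr %*% W
        xte <- xte %*% W
      }
      d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      t(apply(xte, 1, function(r) colSums(abs(t(xtr) - r))))
    },
    chebychev = {
      t(apply(xte, 1, function(r) apply(abs(sweep(xtr, 2, r)), 1, max)))
    },
    correlation = {
      1 - tcrossprod(unit_rows(row_center(xte)), unit_rows(row_center(xtr)))
    },
    cosine = {
      1 - tcrossprod(unit_rows(xte), unit_rows(xtr))
    },
    spearman = {
      rk <- function(m) t(apply(m, 1, rank))
      1 - tcrossprod(unit_rows(row_center(rk(xte))), unit_rows(row_center(rk(xtr))))
    }
  )
}

knn_fit_predict <- function(xtr, ytr, xte, metric, weighting, K,
                            regularize = FALSE) {
  D <- knn_distances(xtr, xte, metric, regularize)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(xte))
  K <- min(K, nrow(xtr))
  lev <- levels(ytr)
  scores <- matrix(0, nrow(xte), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(xte))) {
    d <- D[i, ]
    nn <- order(d)[seq_len(K)]
    dn <- d[nn]
    w <- if (any(dn == 0) && weighting != "equal") {
      as.numeric(dn == 0)  # exact matches dominate inverse-distance weights
    } else {
      switch(weighting,
        equal = rep(1, K),
        inverse = 1 / pmax(dn, .Machine$double.eps),
        squared_inverse = 1 / pmax(dn, .Machine$double.eps)^2
      )
    }
    votes <- tapply(w, ytr[nn], sum, default = 0)
    scores[i, names(votes)] <- votes
  }
  scores <- scores / pmax(rowSums(scores), .Machine$double.eps)
  list(labels = factor(lev[max.col(scores, ties.method = "first")], levels = lev),
       scores = scores)
}

# ---- Mahalanobis discriminant ---------------------------------------------

mahalanobis_da_fit_predict <- function(xtr, ytr, xte, regularize = FALSE) {
  lev <- levels(ytr)
  d2 <- sapply(lev, function(cl) {
    xc <- xtr[ytr == cl, , drop = FALSE]
    mu <- colMeans(xc)
    S <- stats::cov(xc)
    if (regularize) S <- S + diag(mean(diag(S)) * 1e-6, ncol(S))
    tryCatch(stats::mahalanobis(xte, mu, S), error = function(e) {
      abort(sprintf(
        "singular covariance for class '%s' in mahalanobis_da; set regularize = TRUE.", cl
      ))
    })
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = nrow(xte), dimnames = list(NULL, lev))
  scores <- softmax_rows(-0.5 * d2)
  list(labels = factor(lev[max.col(-d2, ties.method = "first")], levels = lev),
       scores = scores)
}

# ---- kernel naive Bayes ---------------------------------------------------

nb_kernel_density <- function(x, sample, h, kernel) {
  u <- outer(x, sample, "-") / h
  k <- switch(kernel,
    normal = stats::dnorm(u),
    box = 0.5 * (abs(u) <= 1),
    epanechnikov = 0.75 * pmax(1 - u^2, 0),
    triangle = pmax(1 - abs(u), 0)
  )
  rowMeans(k) / h
}

nb_kernel_fit_predict <- function(xtr, ytr, xte, kernel) {
  lev <- levels(ytr)
  logpost <- sapply(lev, function(cl) {
    xc <- xtr[ytr == cl, , drop = FALSE]
    lp <- log(nrow(xc) / nrow(xtr))
    for (j in seq_len(ncol(xtr))) {
      s <- sd(xc[, j])
      iqr <- stats::IQR(xc[, j])
      h <- 0.9 * min(s, if (iqr > 0) iqr / 1.34 else Inf) * nrow(xc)^(-1 / 5)
      if (!is.finite(h) || h <= 0) h <- 1e-6
      f <- nb_kernel_density(xte[, j], xc[, j], h, kernel)
      lp <- lp + log(pmax(f, 1e-300))
    }
    lp
  })
  if (is.null(dim(logpost))) {
    logpost <- matrix(logpost, nrow = nrow(xte), dimnames = list(NULL, lev))
  }
  list(labels = factor(lev[max.col(logpost, ties.method = "first")], levels = lev),
       scores = softmax_rows(logpost))
}

# ---- dispatcher -----------------------------------------------------------

#' Fit a classifier on training peaks and predict test peaks
#'
#' One-shot train-and-predict over the 12 feature columns. The training
#' rows define the class set; the result gives one predicted label per test
#' row plus, for families that provide them, per-class scores (posterior
#' probabilities or normalised vote weights) used by the majority-vote tie
#' rule. Results are deterministic given `(config, train, test)`: stochastic
#' families draw from the seed stored in the config.
#'
#' @param config A [classifier_config()].
#' @param train Feature tibble with a `label` column and the 12 variables.
#' @param test Feature tibble of rows to classify.
#' @return A tibble with column `.pred` (factor over the training classes)
#'   and optional `.score_<class>` columns.
#' @export
fit_predict <- function(config, train, test) {
  if (!inherits(config, "ct_classifier_config")) {
    abort("`config` must come from classifier_config().")
  }
  ytr <- factor(train$label)
  if (nlevels(ytr) < 2L) abort("training data must contain at least 2 classes.")
  xtr <- feature_matrix(train)
  xte <- feature_matrix(test)
  lev <- levels(ytr)
  p <- config$params

  res <- switch(config$family,
    knn = knn_fit_predict(xtr, ytr, xte, p$metric, p$weighting, p$K,
                          config$regularize),
    lda = {
      fit <- MASS::lda(xtr, grouping = ytr)
      pr <- predict(fit, xte)
      list(labels = factor(as.character(pr$class), levels = lev),
           scores = pr$posterior)
    },
    qda = {
      fit <- MASS::qda(xtr, grouping = ytr)
      pr <- predict(fit, xte)
      list(labels = factor(as.character(pr$class), levels = lev),
           scores = pr$posterior)
    },
    mahalanobis_da = mahalanobis_da_fit_predict(xtr, ytr, xte,
                                                config$regularize),
    cart = {
      df <- data.frame(.y = ytr, xtr)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(xval = 0))
      pr <- predict(fit, data.frame(xte), type = "prob")
      list(labels = factor(colnames(pr)[max.col(pr, ties.method = "first")],
                           levels = lev),
           scores = pr)
    },
    multinomial_logistic = {
      df <- data.frame(.y = ytr, xtr)
      fit <- with_ct_seed(config$seed,
        nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300)
      )
      pr <- predict(fit, data.frame(xte), type = "probs")
      if (is.null(dim(pr))) {  # binary case returns P(second level)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- lev
      }
      list(labels = factor(colnames(pr)[max.col(pr, ties.method = "first")],
                           levels = lev),
           scores = pr)
    },
    nb_gaussian = {
      fit <- e1071::naiveBayes(xtr, ytr)
      pr <- predict(fit, xte, type = "raw")
      list(labels = factor(colnames(pr)[max.col(pr, ties.method = "first")],
                           levels = lev),
           scores = pr)
    },
    nb_kernel = nb_kernel_fit_predict(xtr, ytr, xte, p$kernel),
    random_forest = {
      fit <- with_ct_seed(config$seed,
        randomForest::randomForest(xtr, ytr, ntree = p$n_trees)
      )
      pr <- predict(fit, xte, type = "prob")
      list(labels = factor(colnames(pr)[max.col(pr, ties.method = "first")],
                           levels = lev),
           scores = pr)
    },
    lssvm = {
      if (nlevels(ytr) == 2L) {
        y <- ifelse(ytr == lev[1], 1, -1)
        m <- lssvm_train(xtr, y, p$kernel, p$C, p$sigma %||% 1)
        f <- lssvm_decision(m, xte)
        scores <- cbind(f, -f)
        colnames(scores) <- lev
        list(labels = factor(ifelse(f >= 0, lev[1], lev[2]), levels = lev),
             scores = scores)
      } else {
        tree <- p$tree %||% lssvm_default_tree(lev)
        validate_tree(tree, lev)
        node <- hierarchical_lssvm_train(xtr, as.character(ytr), tree,
                                         p$kernel, p$C, p$sigma %||% 1)
        list(labels = factor(hierarchical_predict(node, xte), levels = lev),
             scores = NULL)
      }
    }
  )

  out <- tibble::tibble(.pred = res$labels)
  if (!is.null(res$scores)) {
    sc <- as.matrix(res$scores)
    colnames(sc) <- paste0(".score_", colnames(sc))
    out <- dplyr::bind_cols(out, tibble::as_tibble(sc))
  }
  out
}
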