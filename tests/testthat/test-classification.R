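test_that("z-score standardization yields mean 0 / sd 1 and flags constants", {
  ft <- cloud_features(n = 30)
  z <- zscore_standardize(ft)
  for (cn in peak_feature_names()) {
    expect_lt(abs(mean(z[[cn]])), 1e-12)
    expect_lt(abs(sd(z[[cn]]) - 1), 1e-12)
  }
  ft$A_l <- 7
  expect_warning(z2 <- zscore_standardize(ft), "zero-variance")
  expect_equal(unique(z2$A_l), 0)
})

test_that("whole-dataset and train-only standardization differ across folds", {
  ft <- cloud_features(n = 10, peaks_per_signal = 5, sep = 4)
  cfg <- classifier_config("knn", K = 1)
  whole <- loo_classify(ft, cfg, standardize = "whole_dataset")
  # recompute one fold by hand: train stats exclude the held-out signal,
  # so the standardized test rows must differ from the whole-dataset ones
  id <- ft$signal_id[1]
  train <- ft[ft$signal_id != id, ]
  test <- ft[ft$signal_id == id, ]
  z_whole <- zscore_standardize(ft)
  z_fold <- zscore_standardize(test,
                               stats = attr(zscore_standardize(train),
                                            "scaling"))
  expect_false(isTRUE(all.equal(z_fold$A_l,
                                z_whole$A_l[z_whole$signal_id == id])))
  expect_s3_class(whole, "ct_loo")
})

test_that("1-NN returns the label of an identical training row", {
  ft <- cloud_features(n = 20)
  cfg <- classifier_config("knn", metric = "euclidean", K = 1)
  pred <- fit_predict(cfg, ft, ft[c(1, 39), ])
  expect_equal(as.character(pred$.pred), ft$label[c(1, 39)])
})

test_that("KNN with K = n_train and equal weights returns the majority label", {
  ft <- cloud_features(n = 15, peaks_per_signal = 3)
  ft <- ft[c(1:15, 16:25), ]  # 15 'a' vs 10 'b'
  cfg <- classifier_config("knn", K = 25)
  pred <- fit_predict(cfg, ft, ft[c(1, 20), ])
  expect_equal(as.character(pred$.pred), c("a", "a"))
})

test_that("every family separates well-separated Gaussian clouds", {
  train <- cloud_features(n = 50, sep = 10, seed = 11)
  test <- cloud_features(n = 50, sep = 10, seed = 99)
  configs <- list(
    classifier_config("knn", metric = "chebychev", weighting = "inverse",
                      K = 5),
    classifier_config("lda"),
    classifier_config("qda"),
    classifier_config("mahalanobis_da"),
    classifier_config("cart"),
    classifier_config("multinomial_logistic"),
    classifier_config("nb_gaussian"),
    classifier_config("nb_kernel", kernel = "epanechnikov"),
    classifier_config("random_forest", n_trees = 30),
    classifier_config("lssvm", kernel = "rbf", C = 10, sigma = 4)
  )
  for (cfg in configs) {
    pred <- fit_predict(cfg, train, test)
    acc <- mean(as.character(pred$.pred) == test$label)
    expect_gte(acc, 0.98)
  }
})

test_that("LS-SVM coefficients equal an independent dense KKT solve", {
  withr::with_seed(4, {
    for (trial in 1:3) {
      n <- sample(4:10, 1)
      x <- matrix(rnorm(n * 3), ncol = 3)
      y <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1] <- -y[1]
      C <- runif(1, 0.5, 8)
      for (kern in c("linear", "quadratic", "cubic", "rbf")) {
        m <- lssvm_train(x, y, kern, C = C, sigma = 1.7)
        K <- lssvm_kernel(x, x, kern, sigma = 1.7)
        A <- cbind(rbind(0, matrix(1, n)), rbind(1, K + diag(n) / C))
        sol <- solve(A, c(0, y))
        expect_lt(abs(m$b - sol[1]), 1e-8)
        expect_lt(max(abs(m$alpha - sol[-1])), 1e-8)
      }
    }
  })
})

test_that("duplicating training points preserves the LS-SVM sign pattern", {
  withr::with_seed(7, {
    x <- rbind(matrix(rnorm(20, -2), ncol = 2), matrix(rnorm(20, 2), ncol = 2))
    y <- rep(c(-1, 1), each = 10)
    probe <- matrix(runif(40, -3, 3), ncol = 2)
    m1 <- lssvm_train(x, y, "rbf", C = 5, sigma = 2)
    m2 <- lssvm_train(rbind(x, x), c(y, y), "rbf", C = 5, sigma = 2)
    expect_equal(sign(lssvm_decision(m1, probe)),
                 sign(lssvm_decision(m2, probe)))
  })
})

test_that("an all-zero alpha model returns its bias everywhere", {
  m <- structure(list(alpha = c(0, 0), b = 1.25,
                      x = matrix(rnorm(4), ncol = 2),
                      kernel = "linear", C = 1, sigma = 1),
                 class = "ct_lssvm")
  expect_equal(lssvm_decision(m, matrix(rnorm(6), ncol = 2)),
               rep(1.25, 3))
})

test_that("LS-SVM training error vanishes as C grows on separable data", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(24, -3), ncol = 2), matrix(rnorm(24, 3), ncol = 2))
    y <- rep(c(-1, 1), each = 12)
    errs <- vapply(c(0.001, 1, 1000), function(C) {
      m <- lssvm_train(x, y, "rbf", C = C, sigma = 2)
      mean(sign(lssvm_decision(m, x)) != y)
    }, numeric(1))
    expect_true(all(diff(errs) <= 0))
    expect_equal(errs[3], 0)
  })
})

test_that("hierarchical routing follows the tree and recovers toy clusters", {
  # routing: a row sent to the NR side is NR regardless of the other node
  tree <- lssvm_default_tree(c("responder", "semi_responder", "non_responder"))
  expect_equal(catrans:::tree_leaves(tree),
               c("responder", "semi_responder", "non_responder"))
  expect_equal(hierarchical_predict("non_responder", matrix(0, 2, 3)),
               rep("non_responder", 2))  # single-class degenerate tree

  withr::with_seed(5, {
    centers <- list(responder = c(0, 0), semi_responder = c(8, 0),
                    non_responder = c(0, 8))
    x <- do.call(rbind, lapply(centers, function(mu) {
      sweep(matrix(rnorm(40, sd = 0.5), ncol = 2), 2, mu, "+")
    }))
    labels <- rep(names(centers), each = 20)
    node <- catrans:::hierarchical_lssvm_train(x, labels, tree, "rbf",
                                               C = 10, sigma = 2)
    expect_equal(hierarchical_predict(node, x), labels)
  })
  expect_error(
    catrans:::validate_tree(list(left = "a", right = "a"), c("a", "b")),
    "malformed"
  )
})

test_that("majority voting takes the mode and resolves ties deterministically", {
  expect_equal(majority_vote(c("A", "A", "B")),
               list(label = "A", tie = FALSE))
  expect_equal(majority_vote("A"), list(label = "A", tie = FALSE))
  expect_error(majority_vote(character()), "non-empty")

  # 5 vs 5 tie: resolved by summed scores first
  labs <- rep(c("A", "B"), each = 5)
  sc <- matrix(c(rep(0.4, 10), rep(0.6, 10)), ncol = 2,
               dimnames = list(NULL, c("A", "B")))
  v <- majority_vote(labs, scores = sc)
  expect_true(v$tie)
  expect_equal(v$label, "B")
  # without scores: training priors decide
  v2 <- majority_vote(labs, train_labels = c("A", "B", "B"))
  expect_equal(v2$label, "B")
  # no scores, flat priors: lexicographic
  v3 <- majority_vote(labs, train_labels = c("A", "B"))
  expect_equal(v3$label, "A")
})

test_that("leave-one-out folds are hygienic, complete and deterministic", {
  ft <- cloud_features(n = 30, sep = 6, peaks_per_signal = 5,
                       classes = c("a", "b", "c"))
  cfg <- classifier_config("random_forest", n_trees = 15)
  res <- loo_classify(ft, cfg)
  expect_equal(nrow(res$signals), length(unique(ft$signal_id)))
  expect_setequal(res$signals$signal_id, unique(ft$signal_id))
  expect_false(any(res$audit$train_overlap))
  expect_equal(res$audit$n_train_rows + res$audit$n_test_rows,
               rep(nrow(ft), nrow(res$audit)))
  # signal prediction equals the tie-resolved mode of its peak predictions
  for (id in res$signals$signal_id[1:3]) {
    pl <- res$peaks$pred[res$peaks$signal_id == id]
    expect_equal(res$signals$pred[res$signals$signal_id == id],
                 majority_vote(pl)$label)
  }
  res2 <- loo_classify(ft, cfg)
  expect_identical(res, res2)
})

test_that("a fold that loses a class proceeds with a warning", {
  ft <- cloud_features(n = 10, sep = 8, peaks_per_signal = 5,
                       classes = c("a", "b"))
  # class 'b' lives in a single signal: its fold trains on 'a' alone plus
  # nothing else from 'b'
  ft$signal_id[ft$label == "b"] <- "b_only"
  expect_warning(
    res <- loo_classify(ft, classifier_config("knn", K = 1)),
    "absent from training"
  )
  expect_equal(nrow(res$signals), length(unique(ft$signal_id)))
})

test_that("hyperparameter grids enumerate the stated spaces", {
  knn <- classifier_grid("knn")
  expect_equal(length(unique(knn$K)), 19L)  # odd 1..37
  expect_equal(nrow(knn), 8L * 3L * 19L)
  expect_true(all(knn$K %% 2 == 1))

  rbf <- classifier_grid("lssvm", kernel = "rbf")
  expect_equal(nrow(rbf), 900L)
  poly <- classifier_grid("lssvm", kernel = "cubic")
  expect_equal(nrow(poly), 30L)

  rf <- classifier_grid("random_forest")
  expect_equal(nrow(rf), 100L)

  expect_error(classifier_config("knn", K = 4), "odd")
  expect_error(classifier_config("knn", metric = "minkowski3"), "metric")
  expect_error(classifier_config("lssvm", C = 2^20), "C must lie")
  expect_error(classifier_config("random_forest", n_trees = 200), "n_trees")
  expect_error(classifier_config("boosted_stump"), "unknown")
})

test_that("grid search returns the full table and breaks ties to simplicity", {
  ft <- cloud_features(n = 20, sep = 8, peaks_per_signal = 5)
  grid <- classifier_grid("knn", metrics = "euclidean",
                          weightings = "equal", K = c(1L, 3L))
  gs <- grid_search(ft, grid)
  expect_equal(nrow(gs$results), 2L)
  expect_true(all(c("loo_accuracy") %in% names(gs$results)))
  # both K values are perfect on this toy set; the simpler K = 1 wins
  expect_equal(gs$best$K, 1L)
  expect_s3_class(gs$best_config, "ct_classifier_config")
  # grid of size 1 returns that configuration
  g1 <- grid_search(ft, grid[2, ])
  expect_equal(g1$best$K, 3L)
  expect_error(grid_search(ft, grid[0, ]), "non-empty")
})
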