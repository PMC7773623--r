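test_that("confusion matrices count true-by-predicted labels", {
  cm <- confusion_matrix(c("R", "R", "SR", "NR"), c("R", "R", "SR", "NR"))
  expect_equal(sum(diag(cm)), 4L)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(rownames(cm), c("R", "SR", "NR"))

  # label vectors realizing a printed three-class matrix
  truth <- rep(c("R", "SR", "NR"), times = c(59, 28, 41))
  pred <- c(rep(c("R", "SR", "NR"), times = c(47, 3, 9)),
            rep(c("R", "SR", "NR"), times = c(12, 10, 6)),
            rep(c("R", "SR", "NR"), times = c(12, 2, 27)))
  cm3 <- confusion_matrix(truth, pred, labels = c("R", "SR", "NR"))
  expect_equal(unclass(cm3),
               matrix(c(47L, 3L, 9L, 12L, 10L, 6L, 12L, 2L, 27L),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(true = c("R", "SR", "NR"),
                                      predicted = c("R", "SR", "NR"))))
  expect_equal(unname(rowSums(cm3)), c(59, 28, 41))

  expect_error(confusion_matrix("a", c("a", "b")), "same length")
  expect_error(confusion_matrix("a", "b", labels = "a"), "not in")
})

test_that("accuracy and sensitivity follow their confusion-matrix formulas", {
  cm3 <- as_confusion(c(47, 3, 9, 12, 10, 6, 12, 2, 27), c("R", "SR", "NR"))
  expect_equal(accuracy(cm3), 65.6)
  expect_equal(unname(sensitivity(cm3)), c(79.7, 35.7, 65.9))

  cm4 <- as_confusion(c(79, 8, 19, 22), c("RSR", "NR"))
  expect_equal(accuracy(cm4), 78.9)

  ident <- as_confusion(c(5, 0, 0, 5), c("x", "y"))
  expect_equal(accuracy(ident), 100)
  expect_equal(unname(sensitivity(ident)), c(100, 100))

  expect_error(accuracy(as_confusion(c(0, 0, 0, 0), c("x", "y"))), "empty")
  expect_error(sensitivity(cm4, "Q"), "not in")
  zero_row <- as_confusion(c(0, 0, 3, 4), c("x", "y"))
  expect_error(sensitivity(zero_row, "x"), "no true cases")
})

test_that("accuracy is invariant under a simultaneous label permutation", {
  withr::with_seed(14, {
    for (i in 1:5) {
      k <- sample(2:4, 1)
      counts <- sample(0:20, k * k, replace = TRUE)
      labs <- letters[1:k]
      cm <- as_confusion(counts, labs)
      perm <- sample(k)
      cmp <- as_confusion(as.vector(t(unclass(cm)[perm, perm])), labs[perm])
      expect_equal(accuracy(cm, digits = 6), accuracy(cmp, digits = 6))
    }
  })
})

test_that("2x2 accuracy is the row-weighted mean of the sensitivities", {
  withr::with_seed(15, {
    for (i in 1:10) {
      counts <- sample(1:50, 4)
      cm <- as_confusion(counts, c("p", "q"))
      sens <- sensitivity(cm, digits = 8)
      w <- rowSums(cm) / sum(cm)
      expect_equal(accuracy(cm, digits = 6),
                   catrans:::round_half_up(sum(w * sens), 6))
    }
  })
})

test_that("class merging maps labels totally and preserves counts", {
  labels <- rep(c("responder", "semi_responder", "non_responder"),
                times = c(59, 28, 41))
  rsr <- merge_classes(labels, merge_scheme("rsr"))
  expect_equal(unname(table(rsr)[c("RSR", "NR")]), c(87L, 41L),
               ignore_attr = TRUE)
  snr <- merge_classes(labels, merge_scheme("snr"))
  expect_equal(unname(table(snr)[c("R", "SNR")]), c(59L, 69L),
               ignore_attr = TRUE)
  none <- merge_classes(labels, merge_scheme("none"))
  expect_equal(unname(table(none)[c("R", "SR", "NR")]), c(59L, 28L, 41L),
               ignore_attr = TRUE)
  expect_error(merge_classes(c("responder", "mystery"), merge_scheme("rsr")),
               "unmapped")
  # already-merged labels pass through
  expect_equal(merge_classes(c("RSR", "NR"), merge_scheme("rsr")),
               c("RSR", "NR"))
})

test_that("merging mutually confused classes never lowers accuracy", {
  truth <- rep(c("responder", "semi_responder", "non_responder"), each = 10)
  withr::with_seed(16, {
    for (i in 1:5) {
      pred <- sample(unique(truth), length(truth), replace = TRUE)
      a0 <- accuracy(confusion_matrix(truth, pred), digits = 6)
      m <- merge_scheme("rsr")
      a1 <- accuracy(confusion_matrix(merge_classes(truth, m),
                                      merge_classes(pred, m)), digits = 6)
      expect_gte(a1, a0)
    }
  })
})

test_that("feature summaries report sample sd, with 0 for singleton classes", {
  ft <- cloud_features(n = 4, peaks_per_signal = 2)
  one <- ft[1, ]
  one$label <- "solo"
  smry <- summarize_features(dplyr::bind_rows(ft, one))
  solo <- smry[smry$class == "solo", ]
  expect_equal(nrow(solo), 12L)
  expect_equal(solo$sd, rep(0, 12))
  expect_equal(solo$mean, as.numeric(one[peak_feature_names()]))
  # two identical peaks: sd 0 as well
  two <- dplyr::bind_rows(one, one)
  two$label <- "pair"
  smry2 <- summarize_features(dplyr::bind_rows(ft, two))
  expect_equal(smry2$sd[smry2$class == "pair"], rep(0, 12))
})

test_that("loo results tidy into signal tables and confusion matrices", {
  ft <- cloud_features(n = 20, sep = 8, peaks_per_signal = 5)
  res <- loo_classify(ft, classifier_config("lda"))
  td <- tidy(res)
  expect_equal(names(td), c("signal_id", "truth", "pred", "tie", "n_peaks"))
  gl <- glance(res)
  expect_equal(gl$n_signals, nrow(td))
  cm <- loo_confusion(res)
  expect_equal(sum(cm), nrow(td))
  expect_equal(glance(cm)$accuracy, gl$accuracy)
  expect_equal(sum(tidy(cm)$n), sum(cm))
})
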