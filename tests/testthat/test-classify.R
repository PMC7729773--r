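# classifier suite, cross-validation, detection metrics, ROC

# a linearly separable synthetic sample set: falls plunge (negative
# gamma), churn the legs (epsilon) and stay unstable (tau)
separable_samples <- function(n_per_class = 30, seed = 1, margin_ok = TRUE) {
  set.seed(seed)
  fall <- data.frame(gamma = rnorm(n_per_class, -5, 0.4),
                     epsilon = rnorm(n_per_class, 3, 0.3),
                     tau = round(rnorm(n_per_class, 18, 1)), label = "FALL")
  adl <- data.frame(gamma = rnorm(n_per_class, 0, 0.4),
                    epsilon = rnorm(n_per_class, 0.5, 0.2),
                    tau = round(rnorm(n_per_class, 6, 1)), label = "ADL")
  rbind(fall, adl)
}

# brute-force separability check: a perceptron converges iff the set is
# linearly separable (finite mistake bound on separable data)
perceptron_separable <- function(samples, max_epochs = 500) {
  x <- cbind(1, as.matrix(samples[, c("gamma", "epsilon", "tau")]))
  y <- ifelse(samples$label == "FALL", 1, -1)
  w <- rep(0, ncol(x))
  for (e in seq_len(max_epochs)) {
    mistakes <- 0
    for (i in seq_len(nrow(x))) {
      if (y[i] * sum(w * x[i, ]) <= 0) { w <- w + y[i] * x[i, ]; mistakes <- mistakes + 1 }
    }
    if (mistakes == 0) return(TRUE)
  }
  FALSE
}

test_that("a linear SVM fits a verified-separable corpus perfectly and deterministically", {
  s <- separable_samples(seed = 4)
  expect_true(perceptron_separable(s))   # oracle: separability first
  model <- fall_classifier(s, classifier_config("SVM_LINEAR", seed = 2))
  expect_equal(mean(predict(model, s) == s$label), 1.0)
  model2 <- fall_classifier(s, classifier_config("SVM_LINEAR", seed = 2))
  probe <- separable_samples(seed = 77)
  expect_identical(predict(model, probe), predict(model2, probe))
})

test_that("training rejects single-class and malformed input", {
  s <- separable_samples()
  expect_error(fall_classifier(s[s$label == "FALL", ]), "both")
  expect_error(fall_classifier(s[0, ]), "at least 2")
  s$gamma[1] <- NA
  expect_error(fall_classifier(s), "finite")
})

test_that("every classifier kind trains and predicts on the separable corpus", {
  s <- separable_samples(seed = 9)
  probe <- separable_samples(n_per_class = 10, seed = 10)
  for (kind in c("SVM_LINEAR", "SVM_POLY", "SVM_RBF", "KNN", "DT", "RF")) {
    model <- fall_classifier(s, classifier_config(kind, seed = 5))
    pred <- predict(model, probe)
    expect_s3_class(pred, "factor")
    expect_gte(mean(pred == probe$label), 0.9)
    sc <- decision_score(model, probe)
    expect_length(sc, nrow(probe))
    # scores orient toward FALL
    expect_gt(mean(sc[probe$label == "FALL"]), mean(sc[probe$label == "ADL"]))
  }
})

test_that("1-NN memorises any duplicate-free corpus", {
  s <- separable_samples(seed = 12)
  model <- fall_classifier(s, classifier_config("KNN", knn_k = 1))
  expect_equal(mean(predict(model, s) == s$label), 1.0)
})

test_that("standardisation leaves linear-SVM training predictions unchanged on a unit-variance corpus", {
  set.seed(30)
  n <- 40
  s <- data.frame(gamma = scale(rnorm(n))[, 1], epsilon = scale(rnorm(n))[, 1],
                  tau = scale(rnorm(n))[, 1])
  s$label <- ifelse(s$gamma + 0.3 * s$epsilon < 0, "FALL", "ADL")
  m_std <- fall_classifier(s, classifier_config("SVM_LINEAR", standardize = TRUE))
  m_raw <- fall_classifier(s, classifier_config("SVM_LINEAR", standardize = FALSE))
  expect_identical(predict(m_std, s), predict(m_raw, s))
})

test_that("stratified 3-fold cross-validation separates the verified corpus and collapses under label permutation", {
  s <- separable_samples(seed = 15)
  rep <- cross_validate(s, classifier_config("SVM_LINEAR", seed = 3), folds = 3)
  expect_gte(rep$accuracy, 0.95)
  expect_equal(nrow(rep$per_fold), 3L)
  expect_equal(sum(rep$confusion), nrow(s))
  # permutation null: accuracy hovers at chance
  set.seed(8)
  null_acc <- replicate(30, {
    sh <- s; sh$label <- sample(sh$label)
    cross_validate(sh, classifier_config("SVM_LINEAR", seed = 3), folds = 3)$accuracy
  })
  expect_gt(mean(null_acc), 0.35)
  expect_lt(mean(null_acc), 0.65)
  expect_error(cross_validate(s[c(1, 31), ], folds = 3), "at least as many")
})

test_that("per-action count tables collapse to the published-style metric arithmetic", {
  counts <- data.frame(
    action = c("Walking", "Squat", "StandSit", "BendOver", "Falling"),
    predicted_nonfall = c(92, 23, 76, 65, 4),
    predicted_fall = c(0, 0, 3, 4, 147))
  m <- confusion_metrics(counts, fall_actions = "Falling")
  expect_equal(m$accuracy, 403 / 414, tolerance = 1e-12)
  expect_equal(round(m$accuracy, 4), 0.9734)
  expect_equal(m$recall, 147 / 151, tolerance = 1e-12)
  expect_equal(m$precision, 147 / 154, tolerance = 1e-12)
  expect_equal(m$precision_nonfall, 256 / 260, tolerance = 1e-12)
  # independent recount
  o <- oracle_metrics(tp = 147, fp = 7, fn = 4, tn = 256)
  expect_equal(m$accuracy, o$accuracy)
  expect_equal(m$f1, o$f1)

  perfect <- data.frame(action = c("Walk", "Fall"),
                        predicted_nonfall = c(10, 0),
                        predicted_fall = c(0, 10))
  expect_equal(confusion_metrics(perfect, "Fall")$accuracy, 1.0)

  tiny <- data.frame(action = c("Fall", "Walk"),
                     predicted_nonfall = c(0, 0),
                     predicted_fall = c(1, 1))
  mt <- confusion_metrics(tiny, "Fall")
  expect_equal(mt$precision, 0.5)
  expect_equal(mt$recall, 1.0)
  expect_error(confusion_metrics(data.frame(), "Fall"), "nonempty")
})

test_that("metrics agree with a from-first-principles recount on random tables", {
  set.seed(44)
  for (rep in 1:25) {
    counts <- data.frame(action = c("A", "B", "C", "Fall1", "Fall2"),
                         predicted_nonfall = rpois(5, 20),
                         predicted_fall = rpois(5, 10))
    m <- confusion_metrics(counts, fall_actions = c("Fall1", "Fall2"))
    tp <- sum(counts$predicted_fall[4:5]); fn <- sum(counts$predicted_nonfall[4:5])
    fp <- sum(counts$predicted_fall[1:3]); tn <- sum(counts$predicted_nonfall[1:3])
    o <- oracle_metrics(tp, fp, fn, tn)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
  }
})

test_that("ROC endpoints behave: perfect, uninformative and anti-correlated scores", {
  s <- separable_samples(n_per_class = 15, seed = 20)
  perfect <- ifelse(s$label == "FALL", 1, 0) + seq_len(nrow(s)) * 1e-6
  expect_equal(roc_curve(NULL, s, scores = perfect)$auc, 1.0)
  expect_equal(roc_curve(NULL, s, scores = rep(0.5, nrow(s)))$auc, 0.5)
  expect_equal(roc_curve(NULL, s, scores = -perfect)$auc, 0.0)
  expect_error(roc_curve(NULL, s[s$label == "FALL", ], scores = 1:15),
               "both classes")
  # model route: trained scores on the separable corpus reach AUC 1
  model <- fall_classifier(s, classifier_config("SVM_LINEAR"))
  r <- roc_curve(model, s)
  expect_equal(r$auc, 1.0)
  expect_true(all(diff(r$points$fpr) >= 0))
})

test_that("classifiers persist to disk and reload intact", {
  s <- separable_samples(seed = 25)
  model <- fall_classifier(s, classifier_config("RF", seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_identical(predict(back, s), predict(model, s))
  saveRDS(42, path)
  expect_error(read_classifier(path), "fall_classifier")
})
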