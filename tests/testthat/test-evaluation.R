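# Metrics, cross-validation, thresholds and site ranking.

brute_force_metrics <- function(scores, truth, threshold) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] > threshold
    if (pred && truth[i]) tp <- tp + 1
    if (pred && !truth[i]) fp <- fp + 1
    if (!pred && truth[i]) fn <- fn + 1
    if (!pred && !truth[i]) tn <- tn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

brute_force_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("metrics match direct substitution on a worked confusion table", {
  # TP=3, FN=1, TN=5, FP=1
  scores <- c(1, 1, 1, -1, -1, -1, -1, -1, -1, 1)
  truth <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))
  m <- compute_metrics(scores, truth, threshold = 0)
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 5); expect_equal(m$fp, 1)
  expect_equal(m$sn, 0.75)
  expect_equal(m$sp, 5 / 6)
  expect_equal(m$acc, 0.8)
  expect_equal(m$mcc, 14 / 24)
})

test_that("metrics handle perfect, degenerate and undefined cases", {
  m <- compute_metrics(c(2, 2, -2, -2), c(TRUE, TRUE, FALSE, FALSE), 0)
  expect_equal(c(m$sn, m$sp, m$acc, m$mcc, m$auc), rep(1, 5))

  m <- compute_metrics(c(-1, -2, -3, -4), c(TRUE, TRUE, FALSE, FALSE), 0)
  expect_equal(m$sn, 0)
  expect_equal(m$sp, 1)
  expect_false(m$mcc_defined)
  expect_equal(m$mcc, 0)

  m <- compute_metrics(c(1, 2), c(TRUE, TRUE), 0)
  expect_false(m$auc_defined)

  expect_error(compute_metrics(1:3, c(TRUE, FALSE)), "same length")
})

test_that("metrics and AUC agree with brute-force oracles on random vectors", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      n <- sample(5:40, 1)
      scores <- round(rnorm(n), 1)  # rounding forces score ties
      truth <- runif(n) < 0.5
      if (!any(truth) || all(truth)) next
      thr <- rnorm(1)
      m <- compute_metrics(scores, truth, thr)
      o <- brute_force_metrics(scores, truth, thr)
      expect_equal(unlist(m[c("tp", "tn", "fp", "fn")]),
                   unlist(o), ignore_attr = TRUE)
      expect_equal(m$auc, brute_force_auc(scores, truth), tolerance = 1e-12)
      expect_equal(m$sn, o$tp / (o$tp + o$fn))
      expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(123, {
    scores <- c(rnorm(30, 1), rnorm(40))
    truth <- rep(c(TRUE, FALSE), c(30, 40))
    m <- compute_metrics(scores, truth, 0)
    expect_equal(m$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("class swap negates MCC and reflects AUC", {
  withr::with_seed(88, {
    for (rep in 1:10) {
      scores <- rnorm(30)
      truth <- runif(30) < 0.4
      if (!any(truth) || all(truth)) next
      m1 <- compute_metrics(scores, truth, 0)
      m2 <- compute_metrics(scores, !truth, 0)
      expect_equal(m2$mcc, -m1$mcc, tolerance = 1e-12)
      expect_equal(m2$auc, 1 - m1$auc, tolerance = 1e-12)
    }
  })
})

test_that("raising the cutoff never raises Sn nor lowers Sp", {
  withr::with_seed(41, {
    scores <- rnorm(50)
    truth <- runif(50) < 0.5
    cuts <- sort(rnorm(10))
    sn <- sp <- numeric(10)
    for (i in 1:10) {
      m <- compute_metrics(scores, truth, cuts[i])
      sn[i] <- m$sn; sp[i] <- m$sp
    }
    expect_true(all(diff(sn) <= 0))
    expect_true(all(diff(sp) >= 0))
  })
})

test_that("stratified cross-validation pools all held-out rows once", {
  blobs <- make_blobs(20, 25, seed = 10)
  expect_warning(cv <- cross_validate(blobs$p, blobs$n, 10, 0.1, folds = 30),
                 "Reducing folds")
  cv <- cross_validate(blobs$p, blobs$n, 10, 0.1, folds = 10, seed = 4)
  expect_equal(cv$pooled$tp + cv$pooled$tn + cv$pooled$fp + cv$pooled$fn, 45)
  expect_equal(nrow(cv$per_fold), 10)
  # stratification: per-class fold sizes differ by at most one
  for (cls in c(TRUE, FALSE)) {
    sizes <- table(cv$fold[cv$truth == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv2 <- cross_validate(blobs$p, blobs$n, 10, 0.1, folds = 10, seed = 4)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$scores, cv2$scores)
  # separable blobs cross-validate perfectly
  expect_equal(cv$pooled$auc, 1)
})

test_that("threshold calibration matches an exhaustive cutoff scan", {
  withr::with_seed(55, {
    scores <- round(rnorm(10), 1)
    truth <- rep(c(TRUE, FALSE), 5)
    neg <- scores[!truth]
    for (target in c(0, 0.4, 0.8, 1)) {
      got <- calibrate_thresholds(scores, truth, c(x = target))$cutoff
      # oracle: smallest candidate cutoff achieving the target specificity
      cand <- sort(unique(c(min(scores) - 1, scores)))
      ok <- cand[vapply(cand, function(cc) mean(neg <= cc) >= target,
                        logical(1))]
      expect_equal(got, min(ok))
    }
    expect_equal(calibrate_thresholds(scores, truth, c(all = 1))$cutoff,
                 max(neg))
    expect_lt(calibrate_thresholds(scores, truth, c(none = 0))$cutoff,
              min(scores))
  })
})

test_that("named threshold tiers order cutoffs with specificity", {
  withr::with_seed(60, {
    scores <- rnorm(200)
    truth <- runif(200) < 0.3
    ths <- calibrate_thresholds(scores, truth,
                                c(high = 0.99, medium = 0.95, low = 0.90))
    expect_equal(ths$name, c("high", "medium", "low"))
    expect_true(all(diff(ths$cutoff) <= 0))
    expect_error(calibrate_thresholds(scores[truth], truth[truth]),
                 "No negative rows")
  })
})

test_that("test-set evaluation yields one report per tier with monotone Sn/Sp", {
  sim <- small_sim(seed = 19)
  w <- extract_windows(sim$proteins, sim$annotations)
  model <- pup_train(w, fast_config(seed = 19))
  tiers <- c(high = 0.8, medium = 0.1, low = -0.6)
  rep3 <- evaluate_on_test(model, w, tiers)
  expect_equal(rep3$threshold_name, c("high", "medium", "low"))
  expect_true(all(diff(rep3$sn) >= 0))  # lower cutoff, higher sensitivity
  expect_true(all(diff(rep3$sp) <= 0))
  rep1 <- evaluate_on_test(model, w, c(single = 0))
  expect_equal(nrow(rep1), 1)
  expect_error(evaluate_on_test(model, w[0, ], tiers), "empty")
})

test_that("unlabeled-site ranking is descending with lexicographic ties", {
  sim <- small_sim(seed = 23)
  w <- extract_windows(sim$proteins, sim$annotations)
  model <- pup_train(w, fast_config(seed = 23))
  n_unlab <- sum(w$label != "positive")
  top <- rank_unlabeled_sites(model, w, top_n = 20)
  expect_equal(nrow(top), min(20, n_unlab))
  expect_true(all(diff(top$score) <= 0))
  # annotated sites are never candidates
  expect_false(any(paste(top$protein_id, top$position) %in%
                     paste(sim$annotations$protein_id, sim$annotations$site)))
  all_sites <- rank_unlabeled_sites(model, w, top_n = 10 * n_unlab)
  expect_equal(nrow(all_sites), n_unlab)
  # equal scores sort by protein then position
  tied <- tibble::tibble(
    protein_id = c("b", "a", "a"), position = c(1L, 9L, 2L),
    peptide = w$peptide[c(1, 1, 1)], label = "unlabeled"
  )
  rt <- rank_unlabeled_sites(model, tied, 3)
  expect_equal(rt$protein_id, c("a", "a", "b"))
  expect_equal(rt$position, c(2L, 9L, 1L))
})
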