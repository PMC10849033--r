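test_that("shuffle_negatives re-pairs without touching positives", {
  # proteins {A,B,C,D} with positives (A,B),(C,D): 4 admissible negatives
  pos4 <- data.frame(idA = c("A", "C"), idB = c("B", "D"))
  one <- shuffle_negatives(pos4, 1, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_true(paste(one$idA, one$idB) %in%
                c("A C", "A D", "B C", "B D"))
  expect_error(shuffle_negatives(pos4, 5, seed = 1), "admissible")
  # a single positive pair over {A,B} admits no negatives at all
  expect_error(shuffle_negatives(data.frame(idA = "A", idB = "B"), 1),
               "admissible")

  set.seed(1)
  pos2 <- data.frame(idA = sprintf("P%03d", seq(1, 40, 2)),
                     idB = sprintf("P%03d", seq(2, 40, 2)))
  for (sd in 1:5) {
    neg <- shuffle_negatives(pos2, 100, seed = sd)
    expect_equal(nrow(neg), 100L)
    keys <- paste(neg$idA, neg$idB)
    expect_false(any(duplicated(keys)))
    expect_false(any(neg$idA == neg$idB))
    expect_length(intersect(paste(pos2$idA, pos2$idB), keys), 0L)
  }
  # deterministic given seed
  expect_identical(shuffle_negatives(pos2, 50, seed = 7),
                   shuffle_negatives(pos2, 50, seed = 7))
  # n_neg = 0 -> empty
  expect_equal(nrow(shuffle_negatives(pos2, 0)), 0L)
})

test_that("confusion_at_threshold partitions the set", {
  set <- labeled_pairs(c("a", "b", "c", "d", "e", "f"),
                       c("x", "y", "z", "u", "v", "w"),
                       z = c(9, 9, 5, 6, 2, 1),
                       label = c("positive", "positive", "positive",
                                 "negative", "negative", "negative"))
  cf <- confusion_at_threshold(set, 8.8)
  expect_equal(unclass(cf)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 3L, fn = 1L))
  # below min z -> all predicted positive
  lo <- confusion_at_threshold(set, -Inf)
  expect_equal(c(lo$tp, lo$fp), c(3L, 3L))
  # above max z -> all predicted negative
  hi <- confusion_at_threshold(set, 100)
  expect_equal(c(hi$tn, hi$fn), c(3L, 3L))
  # partition invariants
  for (t in c(-1, 3, 6.5, 20)) {
    cf <- confusion_at_threshold(set, t)
    expect_equal(cf$tp + cf$fn, 3L)
    expect_equal(cf$fp + cf$tn, 3L)
  }
})

test_that("prediction metrics reproduce the imbalance benchmark rows", {
  # worked F-measure values at 4-decimal rounding
  expect_equal(round(f_measure(0.5000, 1.0000), 4), 0.6667)
  expect_equal(round(f_measure(0.2185, 0.2245), 4), 0.2215)
  expect_equal(round(f_measure(0.2458, 0.1003), 4), 0.1425)

  m <- prediction_metrics(list(tp = 10, fp = 10, tn = 0, fn = 0))
  expect_equal(m$precision, 0.5)
  expect_equal(m$tpr, 1.0)
  expect_equal(m$f_measure, 2 / 3)

  # tp = 0 with predictions -> all-zero convention
  m0 <- prediction_metrics(list(tp = 0, fp = 5, tn = 5, fn = 10))
  expect_equal(c(m0$precision, m0$f_measure), c(0, 0))
  # no predicted positives -> precision defined as 0 with warning
  expect_warning(mw <- prediction_metrics(list(tp = 0, fp = 0, tn = 10, fn = 10)),
                 "precision")
  expect_equal(mw$precision, 0)
})

test_that("roc_auc equals the pair-counting oracle and handles edge cases", {
  # perfectly separated
  sep <- labeled_pairs(letters[1:4], LETTERS[1:4], z = c(9, 8, 2, 1),
                       label = c("positive", "positive", "negative", "negative"))
  expect_equal(roc_auc(sep)$auc, 1.0)
  # all tied -> diagonal
  tied <- labeled_pairs(letters[1:4], LETTERS[1:4], z = rep(3, 4),
                        label = c("positive", "positive", "negative", "negative"))
  expect_equal(roc_auc(tied)$auc, 0.5)
  expect_error(roc_auc(labeled_pairs("a", "b", 1, "positive")), "one positive")

  # oracle equivalence on random small instances with ties
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    zq <- sample(c(rnorm(n), round(rnorm(n), 0)), n)  # induce ties
    lab <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    set <- labeled_pairs(sprintf("L%02d", 1:n), sprintf("R%02d", 1:n),
                         z = zq, label = lab)
    expect_equal(roc_auc(set)$auc, auc_paircount_oracle(set),
                 tolerance = 1e-12)
  }
  # monotone fpr along the curve
  bm <- gen_benchmark(40, 40, preset = "model", seed = 2)
  pts <- roc_auc(bm$set)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("calibrate_threshold finds the F optimum with a conservative tie-break", {
  # identical class score distributions: the all-positive degenerate optimum
  dset <- degenerate_balanced_set(10)
  cal <- calibrate_threshold(dset)
  expect_equal(cal$threshold, min(dset$z))
  expect_equal(cal$metrics$tpr, 1.0)
  expect_equal(cal$metrics$fpr, 1.0)
  expect_equal(cal$metrics$precision, 0.5)
  expect_equal(round(cal$metrics$f_measure, 4), 0.6667)

  # perfect separation -> F = 1 at the separating threshold
  sep <- labeled_pairs(letters[1:4], LETTERS[1:4], z = c(9, 8, 2, 1),
                       label = c("positive", "positive", "negative", "negative"))
  expect_equal(calibrate_threshold(sep)$metrics$f_measure, 1.0)
  expect_equal(calibrate_threshold(sep)$threshold, 8)

  # candidate restriction and largest-threshold tie-break
  cal2 <- calibrate_threshold(sep, candidates = c(5, 7))
  expect_equal(cal2$threshold, 7)  # both give F=1; tie -> larger

  # sweep columns and agreement with confusion_at_threshold at each row
  sw <- calibrate_threshold(dset)$sweep
  for (i in seq_len(nrow(sw))) {
    m <- prediction_metrics(confusion_at_threshold(dset, sw$threshold[i]))
    expect_equal(sw$f[i], m$f_measure, tolerance = 1e-12)
    expect_equal(sw$fpr[i], m$fpr, tolerance = 1e-12)
  }
})

test_that("imbalance pushes the F-optimal threshold up and its FPR down", {
  for (sd in 1:10) {
    bm <- gen_benchmark(n_pos = 200, n_neg = 20000, preset = "model",
                        seed = sd)
    set <- bm$set
    is_neg <- set$label == "negative"
    sub_1_1 <- set[c(which(!is_neg), which(is_neg)[1:200]), ]
    sub_1_10 <- set[c(which(!is_neg), which(is_neg)[1:2000]), ]
    cal1 <- calibrate_threshold(sub_1_1)
    cal10 <- calibrate_threshold(sub_1_10)
    cal100 <- calibrate_threshold(set)
    expect_gt(cal100$threshold, cal1$threshold)
    expect_gte(cal10$metrics$fpr, cal100$metrics$fpr)
    expect_gte(cal1$metrics$fpr, cal10$metrics$fpr)
  }
})
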