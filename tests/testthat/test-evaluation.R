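test_that("confusion counts cross-tabulate with MF positive", {
  gold <- c(rep("MF", 4), rep("NF+BF", 6))
  cm <- confusion(gold, gold)
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 4, fn = 0, fp = 0, tn = 6))
  cm2 <- confusion(rep("NF+BF", 10), gold)
  expect_equal(c(cm2$tp, cm2$fn, cm2$fp, cm2$tn), c(0, 4, 0, 6))
  expect_error(confusion("MF", c("MF", "MF")), "length")
  expect_error(confusion("maybe", "MF"), "labels")
})

test_that("confusion counts equal a brute-force tally and are order invariant", {
  set.seed(14)
  for (i in 1:5) {
    n <- 40
    gold <- sample(c("MF", "NF+BF"), n, replace = TRUE)
    pred <- sample(c("MF", "NF+BF"), n, replace = TRUE)
    cm <- confusion(pred, gold)
    tally <- c(tp = 0, fn = 0, fp = 0, tn = 0)
    for (k in seq_len(n)) {
      key <- if (gold[k] == "MF") {
        if (pred[k] == "MF") "tp" else "fn"
      } else {
        if (pred[k] == "MF") "fp" else "tn"
      }
      tally[key] <- tally[key] + 1
    }
    expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), unname(tally))
    expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, n)
    perm <- sample(n)
    expect_equal(unclass(confusion(pred[perm], gold[perm])), unclass(cm))
  }
})

test_that("sensitivity and specificity match the clinical-count decompositions", {
  cm <- structure(list(tp = 9, fn = 2, fp = 1, tn = 49), class = "mwi_confusion")
  m <- sensitivity_specificity(cm)
  expect_equal(round(m[["sensitivity"]], 2), 81.82)   # 9 of 11 malignant
  expect_equal(m[["specificity"]], 98)                # 49 of 50 others
  perfect <- structure(list(tp = 5, fn = 0, fp = 0, tn = 7),
                       class = "mwi_confusion")
  expect_equal(unname(sensitivity_specificity(perfect)), c(100, 100))
  empty <- structure(list(tp = 0, fn = 0, fp = 1, tn = 9),
                     class = "mwi_confusion")
  expect_error(sensitivity_specificity(empty), "undefined")
})

test_that("metrics are invariant to duplicating the cohort", {
  set.seed(15)
  gold <- sample(c("MF", "NF+BF"), 30, replace = TRUE, prob = c(0.3, 0.7))
  pred <- sample(c("MF", "NF+BF"), 30, replace = TRUE)
  m1 <- sensitivity_specificity(confusion(pred, gold))
  m2 <- sensitivity_specificity(confusion(rep(pred, 2), rep(gold, 2)))
  expect_equal(m1, m2)
  expect_true(all(m1 >= 0 & m1 <= 100))
})

test_that("zone agreement counts only comparable entries", {
  za <- zone_agreement(c("upper", "lower", "upper"),
                       c("Upper Zone", "Lower Zone", "Upper Zone"))
  expect_equal(za$agreement, 1)
  za2 <- zone_agreement(c("upper", "upper"), c("Upper Zone", "Lower Zone"))
  expect_equal(za2$agreement, 0.5)
  za3 <- zone_agreement(c("upper", "lower", "upper", NA),
                        c("Upper Zone", "More Areas", "Not Available", "Lower Zone"))
  expect_equal(za3$comparable, 1)
  expect_equal(za3$agreement, 1)
  expect_error(zone_agreement("upper", "More Areas"), "comparable")
})
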