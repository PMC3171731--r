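test_that("confusion counts and rates match the hand-computed example", {
  # tp=3 fp=1 fn=2 tn=4: R=0.6 P=0.75 Q2=0.7 MCC=10/sqrt(600)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
              FALSE)
  rep <- confusion_and_rates(scores, labels, threshold = 0.5)
  expect_equal(unname(rep$counts), c(3, 1, 4, 2))  # tp fp tn fn
  expect_equal(rep$recall, 0.6)
  expect_equal(rep$precision, 0.75)
  expect_equal(rep$q2, 0.7)
  expect_equal(rep$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(rep$f1, f1_score(0.75, 0.6), tolerance = 1e-12)
})

test_that("perfect and degenerate predictions hit the conventions", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- confusion_and_rates(c(1, 0.9, 0.1, 0), lab)
  expect_equal(c(perfect$recall, perfect$precision, perfect$q2, perfect$f1,
                 perfect$mcc), rep(1, 5))

  all_neg <- confusion_and_rates(c(0.1, 0.2, 0.1, 0.2), lab, threshold = 0.5)
  expect_equal(all_neg$recall, 0)
  expect_equal(all_neg$mcc, 0)       # zero-marginal convention
  expect_equal(all_neg$precision, 0) # undefined, reported as 0 with flag
  expect_true(all_neg$precision_undefined)
  expect_error(confusion_and_rates(c(0.5, NA), c(TRUE, FALSE)), "labeled")
})

test_that("metric identities hold to numerical precision", {
  set.seed(11)
  for (r in 1:20) {
    scores <- runif(60)
    labels <- runif(60) < 0.3
    if (!any(labels) || all(labels)) next
    rep <- confusion_and_rates(scores, labels, threshold = runif(1))
    cc <- rep$counts
    expect_equal(sum(cc), 60)
    expect_equal(rep$q2, (cc[["tp"]] + cc[["tn"]]) / 60, tolerance = 1e-12)
    if (rep$precision + rep$recall > 0) {
      expect_equal(rep$f1,
                   2 * rep$precision * rep$recall /
                     (rep$precision + rep$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("ROC/AUC follow the rank formulation with tie handling", {
  lab <- c(rep(TRUE, 3), rep(FALSE, 4))
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.1), lab)
  expect_equal(r$auc, 1)
  expect_equal(r$roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
  expect_false(is.unsorted(r$roc$fpr))
  expect_false(is.unsorted(r$roc$tpr))

  expect_equal(roc_auc(rep(0.5, 7), lab)$auc, 0.5)  # all tied
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the concordant-pair count on a 12-point toy set", {
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
              FALSE, FALSE, TRUE)
  # brute-force pair enumeration with ties counted one half
  pos <- which(labels); neg <- which(!labels)
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
  }
  want <- conc / (length(pos) * length(neg))
  expect_equal(roc_auc(scores, labels)$auc, want, tolerance = 1e-12)
  # trapezoidal area under the step curve agrees
  r <- roc_auc(scores, labels)$roc
  trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  expect_equal(trap, want, tolerance = 1e-12)
})

test_that("the rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- round(runif(80), 2)  # forces ties
  labels <- runif(80) < 0.4
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, want, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- runif(50)
  labels <- runif(50) < 0.35
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(scores^3, labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(plogis(8 * scores - 2), labels)$auc, a0,
               tolerance = 1e-12)
})

test_that("paired-bootstrap AUC comparison behaves at the identity and under signal", {
  set.seed(41)
  labels <- rep(c(TRUE, FALSE), c(120, 380))
  informative <- ifelse(labels, rnorm(500, 1.2), rnorm(500))
  noise <- rnorm(500)

  same <- compare_auc(informative, informative, labels, n_boot = 300,
                      seed = 5)
  expect_equal(same$delta_auc, 0)
  expect_gt(same$p_value, 0.9)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  diff <- compare_auc(informative, noise, labels, n_boot = 2000, seed = 5)
  expect_lt(diff$p_value, 0.01)
  expect_true(diff$ci[1] <= diff$delta_auc && diff$delta_auc <= diff$ci[2])

  # deterministic given the seed
  diff2 <- compare_auc(informative, noise, labels, n_boot = 2000, seed = 5)
  expect_identical(diff, diff2)
  expect_error(compare_auc(informative[-1], noise, labels), "same residues")
})

test_that("two-decimal truncation reproduces printed-style metrics", {
  expect_equal(trunc2(0.4186), 0.41)
  expect_equal(trunc2(0.4990), 0.49)
  expect_equal(trunc2(0.70), 0.70)
  expect_equal(trunc2(0.999999), 0.99)
})

test_that("the experiment matrix has the cell contract and is seed-stable", {
  units <- small_units()
  tab <- run_experiment_matrix(units, subsets = list("s", c("s", "b")),
                               modes = c("voronoi", "none"), folds = 2,
                               seed = 3, ntree = 60, inner_folds = 2)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$available))
  expect_true(all(is.finite(tab$auc)))
  tab2 <- run_experiment_matrix(units, subsets = list("s", c("s", "b")),
                                modes = c("voronoi", "none"), folds = 2,
                                seed = 3, ntree = 60, inner_folds = 2)
  expect_identical(tab, tab2)

  # infeasible cell: conservation requested but units carry no MSA
  no_msa <- lapply(units, function(u) { u$msa <- NULL; u })
  tab3 <- run_experiment_matrix(no_msa, subsets = list("c"),
                                modes = "voronoi", folds = 2, seed = 3,
                                ntree = 40, inner_folds = 2)
  expect_false(tab3$available)
  expect_match(tab3$note, "MSA")
})
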