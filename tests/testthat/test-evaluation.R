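test_that("metrics follow the closed-form confusion-matrix definitions", {
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect, list(Sn = 100, Sp = 100, Acc = 100, MCC = 1))

  m <- compute_metrics(list(TP = 25, FN = 25, TN = 40, FP = 10))
  expect_equal(m$Sn, 50)
  expect_equal(m$Sp, 80)
  expect_equal(m$Acc, 65)
  expect_equal(m$MCC, (25 * 40 - 10 * 25) / sqrt(35 * 50 * 50 * 65))

  anti <- compute_metrics(list(TP = 0, TN = 0, FP = 50, FN = 50))
  expect_equal(anti, list(Sn = 0, Sp = 0, Acc = 0, MCC = -1))

  expect_error(compute_metrics(list(TP = -1, TN = 1, FP = 0, FN = 0)),
               "domain error")
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "domain error")
})

test_that("undefined MCC is NaN with a warning, not clamped", {
  expect_warning(m <- compute_metrics(list(TP = 10, FN = 0, TN = 0, FP = 5)),
                 "MCC undefined")
  expect_true(is.nan(m$MCC))
})

test_that("metrics agree with direct formula evaluation on random tables", {
  withr::with_seed(37, {
    for (rep in 1:1000) {
      v <- stats::setNames(sample(0:40, 4, TRUE), c("TP", "TN", "FP", "FN"))
      if (sum(v) == 0) next
      m <- suppressWarnings(compute_metrics(as.list(v)))
      TP <- v["TP"]; TN <- v["TN"]; FP <- v["FP"]; FN <- v["FN"]
      expect_equal(m$Acc, unname(100 * (TP + TN) / sum(v)))
      if (TP + FN > 0) expect_equal(m$Sn, unname(100 * TP / (TP + FN)))
      denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
      if (denom > 0) {
        expect_equal(m$MCC, unname((TP * TN - FP * FN) / denom))
        expect_true(m$MCC >= -1 && m$MCC <= 1)
      } else {
        expect_true(is.nan(m$MCC))
      }
    }
  })
})

test_that("ROC/PR curves hit the canonical fixed points", {
  sep <- roc_pr_curves(c(2, 3, -1, -2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auroc, 1)
  expect_equal(sep$auprc, 1)

  # brute force over the 4 positive-negative pairs: (1 + 1 + 1 + 0) / 4
  mixed <- roc_pr_curves(c(0.9, 0.4, 0.6, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$auroc, 0.75)

  expect_equal(unlist(sep$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(sep$roc[nrow(sep$roc), ]), c(fpr = 1, tpr = 1))

  expect_error(roc_pr_curves(1:4, rep(TRUE, 4)), "curve error")
})

test_that("trapezoidal AUROC equals the pairwise Mann-Whitney statistic", {
  withr::with_seed(41, {
    for (rep in 1:50) {
      n_pos <- sample(3:40, 1)
      n_neg <- sample(3:40, 1)
      score <- round(c(rnorm(n_pos, 0.5), rnorm(n_neg)), 1)  # force ties
      truth <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
      res <- roc_pr_curves(score, truth)
      expect_equal(res$auroc, auroc_pairwise(score, truth), tolerance = 1e-9)
      expect_true(res$auroc >= 0 && res$auroc <= 1)
    }
  })
})

test_that("AUROC agrees with an established ROC implementation", {
  withr::with_seed(43, {
    score <- rnorm(60)
    truth <- rep(c(TRUE, FALSE), 30)
    ours <- roc_pr_curves(score, truth)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  })
})

test_that("jackknife matches an independent leave-one-out loop", {
  d <- tiny_dataset(n = 8, l = 11, seed = 47)
  cfg <- svm_config(C_grid = 4, gamma_grid = 2^-3, inner_cv_folds = 3,
                    seed = 3)
  rep_jack <- jackknife_evaluate(d, cfg)

  # independent oracle: direct libsvm loop, no package CV machinery
  X <- encode_windows(d)
  y <- factor(d$label, levels = c("negative", "positive"))
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    fit <- e1071::svm(x = X[-i, ], y = y[-i], type = "C-classification",
                      kernel = "radial", cost = 4, gamma = 2^-3,
                      scale = FALSE)
    p <- predict(fit, X[i, , drop = FALSE], decision.values = TRUE)
    dv <- attr(p, "decision.values")
    if (startsWith(colnames(dv)[1], "negative")) -dv[1] else dv[1]
  }, numeric(1))
  expect_equal(rep_jack$scores$score, unname(oracle), tolerance = 1e-12)
  expect_equal(sum(unlist(rep_jack$counts)), nrow(d))
})

test_that("jackknife separates a trivially separable dataset", {
  d <- tiny_dataset(n = 10, l = 11, seed = 53)
  rep <- jackknife_evaluate(d, tiny_config())
  expect_equal(rep$Acc, 100)
  expect_equal(rep$scheme, "jackknife")
})

test_that("k-fold CV partitions the data and is seed-deterministic", {
  d <- tiny_dataset(n = 15, l = 11, seed = 59)
  cfg <- tiny_config()
  r1 <- kfold_evaluate(d, k = 5, config = cfg, seed = 11)
  r2 <- kfold_evaluate(d, k = 5, config = cfg, seed = 11)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$folds, r2$folds)
  expect_equal(unlist(lapply(r1[c("Sn", "Sp", "Acc", "MCC")], unname)),
               unlist(r2[c("Sn", "Sp", "Acc", "MCC")]))

  # every window held out exactly once, folds stratified
  expect_length(r1$folds, nrow(d))
  expect_equal(sort(unique(r1$folds)), 1:5)
  expect_true(all(table(r1$folds, d$label) == 3))

  expect_equal(r1$Acc, 100)  # separable construction
  expect_error(kfold_evaluate(d, k = 20, config = cfg), "evaluation error")
})

test_that("reported metrics are recomputable from reported counts", {
  d <- tiny_dataset(n = 12, l = 11, seed = 61, signal_strength = 0.6)
  r <- kfold_evaluate(d, k = 4, config = tiny_config())
  m <- suppressWarnings(compute_metrics(r$counts))
  expect_equal(r$Sn, m$Sn)
  expect_equal(r$Sp, m$Sp)
  expect_equal(r$Acc, m$Acc)
  expect_equal(r$MCC, m$MCC)
  curves <- roc_pr_curves(r$scores$score, r$scores$truth)
  expect_equal(r$AUROC, curves$auroc)
  expect_equal(r$AUPRC, curves$auprc)
})

test_that("self cross-evaluation equals resubstitution", {
  d <- tiny_dataset(n = 10, l = 11, seed = 67)
  cfg <- tiny_config()
  r <- suppressWarnings(cross_evaluate(d, d, cfg))
  m <- grid_search_train(d, cfg)
  expect_equal(r$scores$score, predict(m, d)$score)
  expect_equal(r$scheme, "independent")
  expect_equal(r$tags, c("tiny", "tiny"))

  other <- tiny_dataset(n = 5, l = 13, seed = 2)
  expect_error(cross_evaluate(d, other, cfg), "compatibility error")
})

test_that("the ablation table covers the five masks", {
  d <- tiny_dataset(n = 15, l = 11, seed = 71)
  tab <- ablation_study(d, tiny_config(), k = 3)
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$mask, c("ring", "hbond", "functionality", "density",
                              "all"))
  expect_true(all(tab$Acc >= 0 & tab$Acc <= 100))
  expect_length(attr(tab, "reports"), 5L)
})

test_that("evaluation reports serialize to JSON with provenance", {
  d <- tiny_dataset(n = 10, l = 11, seed = 73)
  r <- kfold_evaluate(d, k = 5, config = tiny_config())
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(r, json, tsv_path = tsv)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$metrics$Acc, r$Acc)
  expect_equal(back$counts$TP, r$counts$TP)
  expect_equal(back$provenance$tool, "m1Apred")
  expect_equal(back$auprc_convention, "stepwise")
  expect_equal(nrow(utils::read.delim(tsv)), 1L)
})
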