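test_that("threshold classification reproduces the fixture confusion matrices", {
  v <- table2_variants()

  pph2 <- classify_variants(v, "pph2")
  expect_equal(as.list(attr(pph2, "confusion")),
               list(tp = 15L, fp = 5L, fn = 4L, tn = 11L))

  prov <- classify_variants(v, "provean")
  expect_equal(ifelse(prov$.damaging, "Damaging", "Neutral"),
               prov$provean_prediction)

  toy <- tibble::tibble(disease_associated = c(TRUE, FALSE),
                        s = c(1, 0))
  cls <- classify_variants(toy, spec_s())
  cm <- attr(cls, "confusion")
  expect_equal(cm$fp + cm$fn, 0L)

  # missing scores are excluded with a warning and counted
  v2 <- v
  v2$pph2_score[1] <- NA
  expect_warning(cls2 <- classify_variants(v2, "pph2"), "excluded")
  expect_equal(attr(cls2, "n_excluded"), 1L)
  expect_equal(nrow(cls2), 34)
})

test_that("MCC matches its closed form and flags undefined margins", {
  expect_equal(mcc(tibble::tibble(tp = 1, fp = 0, fn = 0, tn = 1)), 1)
  v <- table2_variants()
  expect_equal(round(mcc(attr(classify_variants(v, "pph2"), "confusion")), 2), 0.48)
  expect_equal(round(mcc(attr(classify_variants(v, "provean"), "confusion")), 2), 0.37)
  expect_error(mcc(tibble::tibble(tp = 0, fp = 0, fn = 2, tn = 2)), "margin")

  # antisymmetry under label flip
  withr::with_seed(8, {
    for (rep in 1:20) {
      cm <- tibble::tibble(tp = sample(1:9, 1), fp = sample(1:9, 1),
                           fn = sample(1:9, 1), tn = sample(1:9, 1))
      flipped <- tibble::tibble(tp = cm$fn, fp = cm$tn, fn = cm$tp, tn = cm$fp)
      expect_equal(mcc(flipped), -mcc(cm))
    }
  })
})

test_that("precision/recall at fixed thresholds match hand-enumerated counts", {
  v <- table2_variants()
  fc07 <- precision_recall_at(v, "fc", 0.7)
  expect_equal(fc07$precision, 1)
  expect_equal(fc07$recall, 8 / 19)

  pp05 <- precision_recall_at(v, "pph2", 0.5)
  expect_equal(pp05$precision, 15 / 20)
  expect_equal(pp05$recall, 15 / 19)

  fc05 <- precision_recall_at(v, "fc", 0.5)
  expect_equal(fc05$tp, 15L)

  expect_error(precision_recall_at(v, "fc", 1), "no variant predicted")
})

test_that("Clopper-Pearson intervals agree with tail-sum bisection", {
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)

  ci1 <- clopper_pearson(15, 18)
  expect_equal(round(c(ci1$lower, ci1$upper), 3), c(0.586, 0.964))
  ci2 <- clopper_pearson(15, 20)
  expect_equal(round(c(ci2$lower, ci2$upper), 3), c(0.509, 0.913))

  withr::with_seed(4, {
    for (rep in 1:15) {
      n <- sample(5:40, 1)
      k <- sample(0:n, 1)
      got <- clopper_pearson(k, n)
      want <- oracle_cp_interval(k, n)
      expect_equal(c(got$lower, got$upper), want, tolerance = 1e-6)
    }
  })
  expect_error(clopper_pearson(5, 4), "k <= n")
})

test_that("PR curves process tie blocks atomically and integrate correctly", {
  # perfect separation
  sep <- tibble::tibble(disease_associated = c(TRUE, TRUE, FALSE, FALSE),
                        s = c(0.9, 0.8, 0.2, 0.1))
  curve <- pr_curve(sep, spec_s())
  expect_equal(auprc(curve), 1)
  expect_equal(rec_at_precision(curve, 0.9), 1)

  # all scores tied: single point at (recall 1, precision = prevalence)
  tied <- tibble::tibble(disease_associated = c(TRUE, TRUE, FALSE, FALSE),
                         s = rep(0.5, 4))
  tc <- pr_curve(tied, spec_s())
  expect_equal(nrow(tc), 1)
  expect_equal(tc$recall, 1)
  expect_equal(tc$precision, 0.5)

  expect_error(pr_curve(dplyr::filter(sep, disease_associated), spec_s()),
               "positive and one negative")

  # curve statistics are invariant to row order
  v <- table2_variants()
  shuf <- withr::with_seed(9, v[sample(nrow(v)), ])
  expect_equal(auprc(pr_curve(v, "fc")), auprc(pr_curve(shuf, "fc")))
})

test_that("Davis-Goadrich AUPRC matches fine-grid integration", {
  withr::with_seed(21, {
    for (rep in 1:15) {
      tbl <- random_score_table(30, prevalence = 0.4, ties = rep %% 2 == 0)
      got <- auprc(pr_curve(tbl, spec_s()))
      want <- oracle_auprc_grid(tbl$disease_associated, tbl$s)
      expect_equal(got, want, tolerance = 1e-3)
    }
  })
})

test_that("AUROC is the tie-aware rank statistic", {
  sep <- tibble::tibble(disease_associated = c(TRUE, TRUE, FALSE, FALSE),
                        s = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(auroc(sep, spec_s()), 1)

  # 2 positives {0.8, 0.4}, 2 negatives {0.6, 0.4}: 2.5 wins of 4 pairs
  quad <- tibble::tibble(disease_associated = c(TRUE, TRUE, FALSE, FALSE),
                         s = c(0.8, 0.4, 0.6, 0.4))
  expect_equal(auroc(quad, spec_s()), 0.625)

  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      tbl <- random_score_table(n, prevalence = 0.5, ties = TRUE)
      if (length(unique(tbl$disease_associated)) < 2) next
      expect_equal(auroc(tbl, spec_s()),
                   oracle_auroc_pairs(tbl$disease_associated, tbl$s))
    }
  })

  # labels independent of scores: mean near one half
  withr::with_seed(13, {
    vals <- replicate(400, auroc(random_score_table(20), spec_s()))
    expect_lt(abs(mean(vals) - 0.5), 0.02)
  })
})

test_that("prevalence-normalised AUPRC scales and guards its domain", {
  expect_equal(auprc_norm(0.5, 0.5), 1)
  expect_equal(auprc_norm(1, 0.25), 4)
  expect_error(auprc_norm(0.5, 0), "strictly between")
  expect_error(auprc_norm(0.5, 1), "strictly between")

  # random scores: AUPRC near prevalence, normalised area near 1
  withr::with_seed(17, {
    vals <- replicate(400, auprc(pr_curve(random_score_table(40), spec_s())))
    expect_lt(abs(mean(vals) - 0.5), 0.05)
    expect_lt(abs(mean(vals) / 0.5 - 1), 0.1)
  })
})

test_that("perf_summary bundles the metrics with broom-style accessors", {
  v <- table2_variants()
  ps <- perf_summary(v, "pph2")
  g <- glance(ps)
  expect_equal(g$mcc, mcc(ps$confusion))
  expect_equal(g$prevalence, 19 / 35)
  expect_equal(g$auprc_norm, g$auprc / g$prevalence)
  td <- tidy(ps)
  expect_true(all(c("threshold", "recall", "precision") %in% names(td)))
  expect_s3_class(autoplot(ps), "ggplot")
})

test_that("rank-sum and Fisher wrappers match enumeration oracles", {
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- sample(3:6, 1); m <- sample(3:6, 1)
      z <- sample(seq(0.01, 0.99, 0.01), n + m)  # tie-free
      x <- z[seq_len(n)]; y <- z[-seq_len(n)]
      got <- wilcoxon_rank_sum(x, y)
      want <- oracle_wilcoxon_exact(x, y)
      expect_equal(got$statistic, want$u)
      expect_equal(got$p_value, want$p)
    }
  })
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")

  expect_equal(fisher_exact(2, 0, 0, 2)$p_value, 1 / 3)
  expect_equal(fisher_exact(1, 1, 1, 1)$p_value, 1)
  # complementing vs non-complementing kinases mapping to signal transduction
  expect_gt(fisher_exact(5, 2, 22, 9)$p_value, 0.05)
  withr::with_seed(43, {
    for (rep in 1:10) {
      cells <- sample(0:8, 4, replace = TRUE)
      if (sum(cells) == 0) next
      expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value,
                   oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-10)
    }
  })
  expect_error(fisher_exact(0, 0, 0, 0), "All-zero")
})

test_that("stratified performance splits by aligned region and compares scores", {
  v <- table2_variants()
  strat <- stratified_performance(v, "fc")
  expect_equal(nrow(strat), 2)
  expect_true(all(is.finite(strat$auprc_norm)))
  expect_s3_class(attr(strat, "wilcoxon"), "tbl_df")

  # constant stratum reduces to the unstratified summary
  v2 <- dplyr::mutate(v, in_aligned_region = TRUE)
  one <- stratified_performance(v2, "fc")
  expect_equal(nrow(one), 1)
  expect_equal(one$auprc, glance(perf_summary(v, "fc"))$auprc)

  # degenerate strata (all-disease / all-benign) are reported but skipped
  v3 <- dplyr::mutate(v, stratum2 = disease_associated)
  w <- testthat::capture_warnings(
    res <- stratified_performance(v3, "fc", stratum = "stratum2")
  )
  expect_true(any(grepl("single class", w)))
  expect_equal(nrow(res), 2)
  expect_false("mcc" %in% names(res))
})

test_that("stratum AUPRCs agree when no stratum effect is planted", {
  withr::with_seed(55, {
    diffs <- replicate(200, {
      tbl <- random_score_table(60, prevalence = 0.5)
      tbl$s <- tbl$s + ifelse(tbl$disease_associated, 0.4, 0)
      tbl$in_aligned_region <- sample(c(TRUE, FALSE), 60, replace = TRUE)
      res <- suppressWarnings(stratified_performance(tbl, spec_s()))
      if (nrow(res) < 2 || !"auprc" %in% names(res) || any(is.na(res$auprc))) NA
      else diff(res$auprc)
    })
    expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.03)
  })
})
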