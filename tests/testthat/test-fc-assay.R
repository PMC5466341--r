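panel <- c(24, 28, 30, 32, 33, 34, 35, 36, 38)

test_that("control plasmids calibrate the score endpoints at every temperature", {
  # wild-type against itself scores 0 wherever the assay is evaluable
  wt <- rep(5L, length(panel))
  gfp <- c(5L, 5L, rep(1L, length(panel) - 2))  # permissive at 24/28
  wt_calls <- call_conditions(wt, gfp, wt, panel)
  expect_equal(fc_score(wt_calls), 0)
  expect_true(all(wt_calls$category[gfp < wt] == "wildtype_like"))
  expect_true(all(wt_calls$category[gfp >= wt] == "not_evaluable"))

  # GFP against itself scores 1
  gfp_calls <- call_conditions(gfp, gfp, wt, panel)
  expect_equal(fc_score(gfp_calls), 1)
  expect_true(all(gfp_calls$category[gfp < wt] == "no_complementation"))
})

test_that("per-condition categories follow the rescued-spot arithmetic", {
  # the classic example: test and wild type saturate, GFP barely grows
  calls <- call_conditions(test = rep(5, 5), gfp = c(1, 0, 0, 0, 0),
                           wt = rep(5, 5), temperatures = panel[1:5])
  expect_equal(unique(calls$category), "wildtype_like")
  expect_equal(fc_score(calls), 0)

  # wt rescues 4 spots, test rescues 1: below half, severely reduced (0.8)
  one <- call_conditions(test = 1, gfp = 0, wt = 4, temperatures = 36)
  expect_equal(one$category, "severely_reduced")
  expect_equal(one$category_score, 0.8)

  # boundary cases of the g vs G/2, G rule
  expect_equal(call_conditions(2, 0, 4, 36)$category, "reduced")
  expect_equal(call_conditions(4, 0, 4, 36)$category, "wildtype_like")
  expect_equal(call_conditions(0, 0, 4, 36)$category, "no_complementation")

  expect_error(call_conditions(6, 0, 4, 36), "\\[0, 5\\]")
  expect_error(call_conditions(c(1, 2), 0, 4, 36), "equal length")
})

test_that("FC scores are the mean of evaluable condition levels, to one decimal", {
  calls <- tibble::tibble(category_score = c(0, 0, 0.6))
  expect_equal(fc_score(calls), 0.2)
  expect_equal(fc_score(tibble::tibble(category_score = c(0, 0, 0))), 0)
  expect_equal(fc_score(tibble::tibble(category_score = c(0.8, 0.8))), 0.8)
  # permissive (NA) conditions are excluded from the mean
  expect_equal(fc_score(tibble::tibble(category_score = c(NA, 1, 1))), 1)
  expect_error(fc_score(tibble::tibble(category_score = NA_real_)),
               "No evaluable")
})

test_that("score_assay wires grids, and increasing growth never raises the score", {
  grids <- withr::with_seed(1, simulate_assay(0.6, sim_config(assay_noise = 0)))
  res <- score_assay(grids$test, grids$gfp_control, grids$wildtype_control)
  expect_s3_class(res, "assay_result")
  expect_true(res$fc_score >= 0 && res$fc_score <= 1)

  # pointwise-increasing test growth cannot increase the score
  base_growth <- c(0, 1, 2, 3, 4)
  gfp <- rep(0, 5); wt <- rep(4, 5)
  fc_of <- function(tg) fc_score(call_conditions(tg, gfp, wt, panel[1:5]))
  scores <- sapply(0:4, function(k) fc_of(pmin(base_growth + k, 5)))
  expect_true(all(diff(scores) <= 0))

  expect_error(
    score_assay(tibble::tibble(temperature = 30, growth = 1),
                tibble::tibble(temperature = 38, growth = 0),
                tibble::tibble(temperature = 30, growth = 4)),
    "same temperatures"
  )
})

test_that("screen decisions follow the two-replicate-plus-confirmation design", {
  expect_equal(screen_decision(c(FALSE, FALSE)), "negative")
  expect_equal(screen_decision(c(TRUE, FALSE)), "candidate")
  expect_equal(screen_decision(c(TRUE, FALSE), confirmation = TRUE), "confirmed")
  # a candidate failing its confirmation assay is demoted
  expect_equal(screen_decision(c(TRUE, TRUE), confirmation = FALSE), "negative")
  expect_error(screen_decision(c(FALSE, FALSE), confirmation = TRUE),
               "negative pair")
  expect_error(screen_decision(TRUE), "two")
})

test_that("the deleterious call uses a strict 0.5 threshold", {
  expect_true(classify_deleterious(0.6))
  expect_false(classify_deleterious(0.4))
  expect_false(classify_deleterious(0.5))
  expect_error(classify_deleterious(1.2), "\\[0, 1\\]")
})
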