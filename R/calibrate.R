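#' Cross-validated precision calibration of a scoring system
#'
#' Maps raw scores onto the \[0, 1\] precision scale by 10-fold (by
#' default) cross-validation: variants are split into `n_groups` seeded
#' random groups, and each variant's calibrated score is the precision —
#' the fraction disease-associated — among the *other* groups' variants
#' whose score is at least as damaging as its own. Within each fold the
#' mapping is then isotonically smoothed so that a more damaging raw score
#' never receives a lower calibrated score.
#'
#' A variant more damaging than every training variant inherits the
#' precision at the single most damaging training score. If the training
#' complement of some fold contains a single class, that fold is merged
#' with its neighbour with a warning.
#'
#' @inheritParams classify_variants
#' @param n_groups Number of cross-validation groups (default 10, >= 2).
#' @param seed Integer seed for the random group assignment; `NULL` uses
#'   the session RNG stream.
#' @return The variant table with columns `.calibration_group` and
#'   `.calibrated` (in \[0, 1\]) added.
#' @export
calibrate_scores <- function(variants, spec, n_groups = 10, seed = NULL) {
  spec <- as_score_spec(spec)
  if (n_groups < 2) abort("`n_groups` must be >= 2.")
  cls <- classify_variants(variants, spec)
  n <- nrow(cls)
  if (n < n_groups) abort("Need at least `n_groups` variants with scores.")
  if (length(unique(cls$disease_associated)) < 2) {
    abort("Calibration needs both classes present.")
  }

  assign_groups <- function() {
    sample(rep(seq_len(n_groups), length.out = n))
  }
  groups <- if (is.null(seed)) assign_groups()
            else withr::with_seed(seed, assign_groups())

  # merge folds whose training complement is single-class
  repeat {
    bad <- NULL
    for (g in unique(groups)) {
      train_lab <- cls$disease_associated[groups != g]
      if (length(unique(train_lab)) < 2) { bad <- g; break }
    }
    if (is.null(bad) || length(unique(groups)) <= 2) break
    warn(sprintf("Calibration group %d had a single-class training set; merged with a neighbour.", bad))
    others <- setdiff(unique(groups), bad)
    groups[groups == bad] <- others[1]
  }

  dmg <- damaging_direction(cls$.score, spec)
  truth <- cls$disease_associated
  calibrated <- rep(NA_real_, n)
  for (g in unique(groups)) {
    test_idx <- which(groups == g)
    train_idx <- which(groups != g)
    td <- dmg[train_idx]
    tl <- truth[train_idx]
    cal <- vapply(test_idx, function(i) {
      at_least <- td >= dmg[i]
      if (!any(at_least)) at_least <- td == max(td)
      mean(tl[at_least])
    }, numeric(1))
    # isotone in damaging-direction score within the fold
    ord <- order(dmg[test_idx])
    if (length(ord) > 1) {
      fit <- stats::isoreg(seq_along(ord), cal[ord])
      cal[ord] <- fit$yf
    }
    calibrated[test_idx] <- pmin(pmax(cal, 0), 1)  # guard isoreg round-off
  }
  cls$.calibration_group <- groups
  cls$.calibrated <- calibrated
  cls
}

#' Combine calibrated FC and PolyPhen-2 scores
#'
#' Combination rules for two calibrated scores: `min`, `max`, `mean`, and
#' the weighted means `w1`-`w4`, defined as
#' `alpha * cal_fc + (1 - alpha) * cal_pph2` with alpha = 0.9, 0.8, 0.7
#' and 0.6 respectively.
#'
#' @param cal_fc,cal_pph2 Calibrated scores in \[0, 1\] (vectorised).
#' @param method One of `"min"`, `"max"`, `"mean"`, `"w1"`, `"w2"`,
#'   `"w3"`, `"w4"`.
#' @return Numeric vector of combined scores; pairs with a missing input
#'   are dropped to `NA` with a warning.
#' @export
#' @examples
#' combine_scores(1, 0, "w1")
combine_scores <- function(cal_fc, cal_pph2,
                           method = c("min", "max", "mean",
                                      "w1", "w2", "w3", "w4")) {
  method <- match.arg(method)
  if (length(cal_fc) != length(cal_pph2)) {
    abort("`cal_fc` and `cal_pph2` must have equal length.")
  }
  ok <- !is.na(cal_fc) & !is.na(cal_pph2)
  if (any(!ok)) {
    warn(sprintf("%d variant(s) dropped: missing calibrated score.", sum(!ok)))
  }
  rng_ok <- ok & cal_fc >= 0 & cal_fc <= 1 & cal_pph2 >= 0 & cal_pph2 <= 1
  if (any(ok & !rng_ok)) abort("Calibrated scores must lie in [0, 1].")
  alphas <- c(w1 = 0.9, w2 = 0.8, w3 = 0.7, w4 = 0.6)
  out <- switch(method,
    min = pmin(cal_fc, cal_pph2),
    max = pmax(cal_fc, cal_pph2),
    mean = (cal_fc + cal_pph2) / 2,
    {
      a <- alphas[[method]]
      a * cal_fc + (1 - a) * cal_pph2
    }
  )
  out[!ok] <- NA_real_
  out
}
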