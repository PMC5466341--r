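#' Scoring-system specifications
#'
#' Describes how a score column is turned into a Damaging/Neutral call.
#' Built-in systems: `"fc"` (failure-to-complement, damaging when
#' score > 0.5), `"pph2"` (PolyPhen-2, damaging when score > 0.5) and
#' `"provean"` (damaging when score <= -2.5; lower is more damaging).
#' The PolyPhen-2 and PROVEAN rules are the unique thresholds concordant
#' with all 35 published Damaging/Neutral calls in the packaged benchmark
#' table.
#'
#' @param name One of `"fc"`, `"pph2"`, `"provean"`, or any name when the
#'   other arguments are given explicitly.
#' @param score_col Column of the variant table holding the score.
#' @param direction `"higher_is_damaging"` (call is `score > threshold`) or
#'   `"lower_is_damaging"` (call is `score <= threshold`).
#' @param threshold Decision threshold.
#' @return A list of class `score_spec`.
#' @export
#' @examples
#' score_spec("provean")
score_spec <- function(name, score_col = NULL, direction = NULL,
                       threshold = NULL) {
  builtin <- list(
    fc = list(score_col = "fc_score", direction = "higher_is_damaging",
              threshold = 0.5),
    pph2 = list(score_col = "pph2_score", direction = "higher_is_damaging",
                threshold = 0.5),
    provean = list(score_col = "provean_score",
                   direction = "lower_is_damaging", threshold = -2.5)
  )
  base <- builtin[[tolower(name)]] %||%
    list(score_col = score_col, direction = direction, threshold = threshold)
  spec <- list(
    name = name,
    score_col = score_col %||% base$score_col,
    direction = direction %||% base$direction,
    threshold = threshold %||% base$threshold
  )
  if (is.null(spec$score_col) || is.null(spec$direction) || is.null(spec$threshold)) {
    abort("Custom score_spec() needs score_col, direction and threshold.")
  }
  spec$direction <- match.arg(spec$direction,
                              c("higher_is_damaging", "lower_is_damaging"))
  structure(spec, class = "score_spec")
}

as_score_spec <- function(spec) {
  if (inherits(spec, "score_spec")) spec else score_spec(spec)
}

# damaging-direction version of a score: larger = more damaging
damaging_direction <- function(score, spec) {
  if (spec$direction == "higher_is_damaging") score else -score
}

predict_damaging <- function(score, spec, threshold = spec$threshold) {
  if (spec$direction == "higher_is_damaging") score > threshold
  else score <= threshold
}

#' Threshold classification of a variant table
#'
#' Applies a scoring system's decision rule to every variant and tallies
#' the confusion against the disease annotation. Variants with a missing
#' score are excluded with a warning.
#'
#' @param variants A variant tibble (see [read_variant_table()]).
#' @param spec A [score_spec()] or its name (`"fc"`, `"pph2"`,
#'   `"provean"`).
#' @param threshold Optional override of the spec's threshold.
#' @return The evaluated variants with columns `.score`, `.damaging`
#'   (prediction) added, and attribute `confusion` (see
#'   [confusion_matrix()]); `n_excluded` records missing-score drops.
#' @export
classify_variants <- function(variants, spec, threshold = NULL) {
  spec <- as_score_spec(spec)
  check_columns(variants, c(spec$score_col, "disease_associated"),
                "Variant table")
  score <- variants[[spec$score_col]]
  drop <- is.na(score) | is.na(variants$disease_associated)
  if (any(drop)) {
    warn(sprintf("%d variant(s) excluded: missing %s or disease annotation.",
                 sum(drop), spec$score_col))
  }
  out <- variants[!drop, , drop = FALSE]
  thr <- threshold %||% spec$threshold
  out$.score <- out[[spec$score_col]]
  out$.damaging <- predict_damaging(out$.score, spec, thr)
  attr(out, "confusion") <- confusion_matrix(out$disease_associated, out$.damaging)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Confusion matrix of predicted vs annotated pathogenicity
#'
#' @param truth Logical: disease-associated?
#' @param prediction Logical: called damaging?
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, prediction) {
  if (length(truth) != length(prediction)) {
    abort("`truth` and `prediction` must have equal length.")
  }
  tibble::tibble(
    tp = sum(truth & prediction),
    fp = sum(!truth & prediction),
    fn = sum(truth & !prediction),
    tn = sum(!truth & !prediction)
  )
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. All four
#' margins must be positive, otherwise the coefficient is undefined and an
#' error is raised.
#'
#' @param cm A confusion matrix tibble (`tp`, `fp`, `fn`, `tn`).
#' @return The MCC, a number in \[-1, 1\].
#' @export
mcc <- function(cm) {
  check_columns(cm, c("tp", "fp", "fn", "tn"), "Confusion matrix")
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  margins <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(margins == 0)) {
    abort("MCC undefined: a confusion-matrix margin is zero.")
  }
  (tp * tn - fp * fn) / sqrt(prod(margins))
}

#' Precision and recall at a threshold
#'
#' @inheritParams classify_variants
#' @param threshold Decision threshold (defaults to the spec's).
#' @return One-row tibble with `threshold`, `precision`, `recall`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
precision_recall_at <- function(variants, spec, threshold = NULL) {
  spec <- as_score_spec(spec)
  cls <- classify_variants(variants, spec, threshold)
  cm <- attr(cls, "confusion")
  if (cm$tp + cm$fp == 0) {
    abort("Precision undefined: no variant predicted damaging at this threshold.")
  }
  tibble::tibble(
    threshold = threshold %||% spec$threshold,
    precision = cm$tp / (cm$tp + cm$fp),
    recall = cm$tp / (cm$tp + cm$fn),
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact interval for a proportion from the binomial tail inversion, as
#' used for precision estimates on small variant panels.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble with `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' clopper_pearson(15, 18)
clopper_pearson <- function(k, n, level = 0.95) {
  if (n <= 0 || k < 0 || k > n || k != round(k) || n != round(n)) {
    abort("Require integers 0 <= k <= n with n > 0.")
  }
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  tibble::tibble(estimate = k / n, lower = ci[1], upper = ci[2])
}

#' Precision-recall curve with atomic tie blocks
#'
#' Builds the PR curve of a scoring system over a labelled variant table.
#' One point is produced per distinct score value (all ties enter the
#' predicted-positive set together), ordered from the most to the least
#' damaging threshold, so every curve statistic is invariant to input
#' ordering.
#'
#' @inheritParams classify_variants
#' @return A tibble of class `pr_curve` with columns `threshold` (score at
#'   which the block enters), `tp`, `fp`, `recall`, `precision`, and
#'   attributes `n_pos`, `n_neg`.
#' @export
pr_curve <- function(variants, spec) {
  spec <- as_score_spec(spec)
  cls <- suppressWarnings(classify_variants(variants, spec))
  truth <- cls$disease_associated
  score <- damaging_direction(cls$.score, spec)
  if (all(truth) || !any(truth)) {
    abort("PR curve needs at least one positive and one negative label.")
  }
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  blocks <- split(seq_along(score), factor(-score, levels = unique(-score)))
  tp <- unname(cumsum(vapply(blocks, function(i) sum(truth[i]), numeric(1))))
  fp <- unname(cumsum(vapply(blocks, function(i) sum(!truth[i]), numeric(1))))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  out <- tibble::tibble(
    threshold = unname(vapply(blocks, function(i) {
      s <- score[i[1]]
      if (spec$direction == "higher_is_damaging") s else -s
    }, numeric(1))),
    tp = tp, fp = fp,
    recall = tp / n_pos,
    precision = tp / (tp + fp)
  )
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("pr_curve", class(out))
  out
}

# Davis-Goadrich segments: between achievable points, fp is linear in tp and
# precision = tp / ((1+s) tp + c). Closed-form area of each segment.
dg_segment_area <- function(tp0, fp0, tp1, fp1, n_pos) {
  dtp <- tp1 - tp0
  if (dtp <= 0) return(0)
  s <- (fp1 - fp0) / dtp
  a <- 1 + s
  c0 <- fp0 - s * tp0
  if (abs(c0) < 1e-12) {
    # precision constant = 1/a along the segment
    return((dtp / n_pos) * (1 / a))
  }
  # integral of tp / (a tp + c0) dtp from tp0 to tp1, scaled by 1/n_pos
  f <- function(tp) tp / a - (c0 / a^2) * log(a * tp + c0)
  (f(tp1) - f(tp0)) / n_pos
}

#' Area under the precision-recall curve
#'
#' Integrates the PR curve with the Davis-Goadrich nonlinear interpolation
#' between achievable points (precision is not linear in recall between
#' confusion-matrix states); `interpolation = "step"` gives a conservative
#' step-function integration instead, for cross-checking.
#'
#' @param curve A [pr_curve()] result.
#' @param interpolation `"davis_goadrich"` (default) or `"step"`.
#' @return The area, in \[0, 1\].
#' @export
auprc <- function(curve, interpolation = c("davis_goadrich", "step")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(curve, "pr_curve")) abort("`curve` must come from pr_curve().")
  n_pos <- attr(curve, "n_pos")
  tp <- c(0, curve$tp)
  fp <- c(0, curve$fp)
  if (interpolation == "davis_goadrich") {
    sum(vapply(seq_len(length(tp) - 1), function(i) {
      dg_segment_area(tp[i], fp[i], tp[i + 1], fp[i + 1], n_pos)
    }, numeric(1)))
  } else {
    rec <- tp / n_pos
    prec <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
    sum(diff(rec) * prec[-1])
  }
}

#' Recall at a precision floor
#'
#' Maximum recall achievable on the (Davis-Goadrich interpolated) PR curve
#' while keeping precision at or above `precision`; 0 when no part of the
#' curve reaches the floor. `rec_at_precision(curve, 0.9)` is the REC90
#' statistic.
#'
#' @param curve A [pr_curve()] result.
#' @param precision Precision floor in (0, 1\].
#' @return A recall in \[0, 1\].
#' @export
rec_at_precision <- function(curve, precision = 0.9) {
  if (!inherits(curve, "pr_curve")) abort("`curve` must come from pr_curve().")
  check_prob(precision, "precision")
  n_pos <- attr(curve, "n_pos")
  tp <- c(0, curve$tp)
  fp <- c(0, curve$fp)
  best <- 0
  for (i in seq_len(length(tp) - 1)) {
    tp0 <- tp[i]; fp0 <- fp[i]; tp1 <- tp[i + 1]; fp1 <- fp[i + 1]
    dtp <- tp1 - tp0
    p1 <- tp1 / (tp1 + fp1)
    if (p1 >= precision) {
      best <- max(best, tp1 / n_pos)
      next
    }
    if (dtp <= 0) next
    # precision decreases or increases monotonically along the segment;
    # find the largest tp* in (tp0, tp1] with precision(tp*) >= floor
    s <- (fp1 - fp0) / dtp
    a <- 1 + s
    c0 <- fp0 - s * tp0
    if (abs(c0) < 1e-12) next  # constant precision below the floor
    tp_star <- precision * c0 / (1 - precision * a)
    if (is.finite(tp_star) && tp_star > tp0 && tp_star <= tp1 &&
        tp_star / (a * tp_star + c0) >= precision - 1e-12) {
      best <- max(best, tp_star / n_pos)
    }
  }
  best
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random disease variant carries a more damaging
#' score than a random non-disease variant, counting ties as one half
#' (equivalent to the Mann-Whitney U statistic scaled by the number of
#' pairs).
#'
#' @inheritParams classify_variants
#' @return The AUROC in \[0, 1\].
#' @export
auroc <- function(variants, spec) {
  spec <- as_score_spec(spec)
  cls <- suppressWarnings(classify_variants(variants, spec))
  truth <- cls$disease_associated
  score <- damaging_direction(cls$.score, spec)
  if (all(truth) || !any(truth)) {
    abort("AUROC needs at least one positive and one negative label.")
  }
  r <- rank(score)  # midranks
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Prevalence-normalised AUPRC
#'
#' AUPRC divided by the positive-class prevalence (the baseline precision
#' of a random classifier), making areas comparable across strata with
#' different priors.
#'
#' @param auprc AUPRC value in \[0, 1\].
#' @param prevalence Positive-class prevalence in (0, 1).
#' @return `auprc / prevalence`.
#' @export
auprc_norm <- function(auprc, prevalence) {
  stop_if_not_scalar_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  auprc / prevalence
}

#' Full performance summary of a scoring system
#'
#' Computes the confusion matrix at the decision threshold plus the
#' threshold-free statistics: MCC, AUPRC (Davis-Goadrich), AUROC, recall at
#' 90% precision, and prevalence-normalised AUPRC.
#'
#' @inheritParams classify_variants
#' @return An object of class `perf_summary` with the metrics, the
#'   confusion matrix and the PR curve. Use [glance()] for a one-row
#'   metric tibble, [tidy()] for the per-threshold PR points, and
#'   [autoplot()] for the PR curve.
#' @export
#' @examples
#' glance(perf_summary(table2_variants(), "pph2"))
perf_summary <- function(variants, spec, threshold = NULL) {
  spec <- as_score_spec(spec)
  cls <- classify_variants(variants, spec, threshold)
  cm <- attr(cls, "confusion")
  curve <- pr_curve(cls, spec)
  n_pos <- attr(curve, "n_pos")
  n_neg <- attr(curve, "n_neg")
  prevalence <- n_pos / (n_pos + n_neg)
  area <- auprc(curve)
  structure(
    list(
      spec = spec,
      confusion = cm,
      curve = curve,
      mcc = mcc(cm),
      auprc = area,
      auroc = auroc(cls, spec),
      rec90 = rec_at_precision(curve, 0.9),
      auprc_norm = auprc_norm(area, prevalence),
      prevalence = prevalence,
      n = n_pos + n_neg
    ),
    class = "perf_summary"
  )
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf("Performance of %s on %d variants (prevalence %.2f)\n",
              x$spec$name, x$n, x$prevalence))
  print(glance(x))
  invisible(x)
}

#' @export
glance.perf_summary <- function(x, ...) {
  tibble::tibble(
    system = x$spec$name,
    n = x$n,
    prevalence = x$prevalence,
    tp = x$confusion$tp, fp = x$confusion$fp,
    fn = x$confusion$fn, tn = x$confusion$tn,
    mcc = x$mcc,
    auprc = x$auprc,
    auroc = x$auroc,
    rec90 = x$rec90,
    auprc_norm = x$auprc_norm
  )
}

#' @export
tidy.perf_summary <- function(x, ...) {
  tibble::as_tibble(x$curve)
}

#' @export
autoplot.perf_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$prevalence, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = paste("Precision-recall:", object$spec$name),
                  x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum comparison of two score samples
#'
#' Two-sided Mann-Whitney/Wilcoxon test with midrank tie handling: exact
#' enumeration for small tie-free samples, otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble with `statistic` (the U statistic for `x`) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test by hypergeometric enumeration (tables with
#' probability no greater than the observed one contribute to p).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return One-row tibble with `p_value` and the conditional odds-ratio
#'   estimate.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("All-zero table.")
  ht <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  tibble::tibble(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Performance stratified by a variant attribute
#'
#' Evaluates a scoring system separately within each level of a stratum
#' (by default whether the variant lies in the human-yeast aligned region)
#' and compares the score distributions across strata with a Wilcoxon
#' test. Strata missing a class (all-disease or all-benign) cannot support
#' curve statistics and are reported but skipped.
#'
#' @inheritParams classify_variants
#' @param stratum Column name holding the stratum label (default
#'   `"in_aligned_region"`).
#' @return A tibble with one row per stratum (the [glance()] metrics plus
#'   a `stratum` column; skipped strata carry `NA` metrics), with the
#'   across-strata Wilcoxon comparison in attribute `wilcoxon`.
#' @export
stratified_performance <- function(variants, spec,
                                   stratum = "in_aligned_region") {
  spec <- as_score_spec(spec)
  check_columns(variants, stratum, "Variant table")
  cls <- suppressWarnings(classify_variants(variants, spec))
  levels <- unique(cls[[stratum]])
  rows <- purrr::map(levels, function(lv) {
    sub <- cls[!is.na(cls[[stratum]]) & cls[[stratum]] == lv, , drop = FALSE]
    if (length(unique(sub$disease_associated)) < 2) {
      warn(sprintf("Stratum %s = %s has a single class; metrics skipped.",
                   stratum, lv))
      return(tibble::tibble(stratum = lv, n = nrow(sub)))
    }
    dplyr::bind_cols(tibble::tibble(stratum = lv),
                     glance(perf_summary(sub, spec)) |>
                       dplyr::select(-"system"))
  })
  out <- dplyr::bind_rows(rows)
  if (length(levels) >= 2) {
    s1 <- damaging_direction(cls$.score[cls[[stratum]] == levels[1]], spec)
    s2 <- damaging_direction(cls$.score[cls[[stratum]] == levels[2]], spec)
    attr(out, "wilcoxon") <- wilcoxon_rank_sum(s1, s2)
  }
  out
}
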