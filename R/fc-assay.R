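# Per-condition complementation categories and their score levels.
# 0 = wild-type-like rescue ... 1 = complete loss of complementation.
CATEGORY_SCORES <- c(
  wildtype_like = 0,
  reduced = 0.6,
  severely_reduced = 0.8,
  no_complementation = 1
)

#' Call per-temperature complementation categories from a spot assay
#'
#' Interprets a spot-dilution growth readout by comparing the strain
#' expressing the human gene against the wild-type (positive) and GFP
#' (negative) controls at each temperature. Growth is the number of
#' dilution spots with visible growth, an integer in `[0, dilution_steps]`.
#'
#' At a given temperature let `g = test - gfp` and `G = wt - gfp` be the
#' numbers of spots rescued by the test and wild-type plasmids over the GFP
#' background. The call is `wildtype_like` (score 0) when `g >= G`,
#' `reduced` (0.6) when `G/2 <= g < G`, `severely_reduced` (0.8) when
#' `0 < g < G/2`, and `no_complementation` (1) when `g <= 0`. Temperatures
#' where the GFP control grows at least as well as the wild-type control
#' are permissive — there is no selective signal — and are called
#' `not_evaluable` (score `NA`).
#'
#' @param test,gfp,wt Integer vectors of growth counts, one entry per
#'   temperature, all from grids with the same number of dilution steps.
#' @param temperatures Temperatures (degrees C) labelling the entries.
#' @param dilution_steps Number of spots per dilution series (default 5).
#' @return A tibble with columns `temperature`, `category`,
#'   `category_score`.
#' @export
#' @examples
#' call_conditions(test = c(5, 1), gfp = c(5, 0), wt = c(5, 4),
#'                 temperatures = c(24, 36))
call_conditions <- function(test, gfp, wt, temperatures = seq_along(test),
                            dilution_steps = 5) {
  n <- length(test)
  if (length(gfp) != n || length(wt) != n || length(temperatures) != n) {
    abort("`test`, `gfp`, `wt` and `temperatures` must have equal length.")
  }
  for (v in list(test, gfp, wt)) {
    if (any(is.na(v)) || any(v < 0) || any(v > dilution_steps)) {
      abort(sprintf("Growth counts must be integers in [0, %d].", dilution_steps))
    }
  }
  g <- test - gfp
  G <- wt - gfp
  category <- dplyr::case_when(
    G <= 0 ~ "not_evaluable",
    g >= G ~ "wildtype_like",
    g >= G / 2 ~ "reduced",
    g > 0 ~ "severely_reduced",
    TRUE ~ "no_complementation"
  )
  tibble::tibble(
    temperature = temperatures,
    category = category,
    category_score = unname(CATEGORY_SCORES[category])
  )
}

#' Aggregate condition calls into a failure-to-complement score
#'
#' The FC score is the arithmetic mean of the per-condition category scores
#' over evaluable temperatures, rounded to one decimal. By construction the
#' wild-type positive control scores 0 and the GFP negative control scores
#' 1.
#'
#' @param calls A tibble from [call_conditions()] (needs a `category_score`
#'   column).
#' @return A single FC score in \[0, 1\].
#' @export
fc_score <- function(calls) {
  check_columns(calls, "category_score", "Condition calls")
  s <- calls$category_score[!is.na(calls$category_score)]
  if (length(s) == 0) {
    abort("No evaluable condition: every temperature was permissive.")
  }
  round_half_up(mean(s), 1L)
}

#' Score a complete assay (test + controls) in one call
#'
#' @param test,gfp,wt Grid tibbles with columns `temperature`, `growth`
#'   (and optionally `strain_id`, `plasmid`); rows matched on temperature.
#' @param dilution_steps Spots per dilution series.
#' @return A list of class `assay_result` with elements `fc_score` and
#'   `condition_calls`.
#' @export
score_assay <- function(test, gfp, wt, dilution_steps = 5) {
  for (g in list(test, gfp, wt)) check_columns(g, c("temperature", "growth"),
                                               "Assay grid")
  temps <- sort(unique(test$temperature))
  if (!setequal(temps, gfp$temperature) || !setequal(temps, wt$temperature)) {
    abort("Test and control grids must cover the same temperatures.")
  }
  idx <- function(df) df$growth[match(temps, df$temperature)]
  calls <- call_conditions(idx(test), idx(gfp), idx(wt), temps, dilution_steps)
  structure(list(fc_score = fc_score(calls), condition_calls = calls),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat("FC score:", x$fc_score, "over",
      sum(!is.na(x$condition_calls$category_score)), "evaluable condition(s)\n")
  invisible(x)
}

#' Screening decision from replicate complementation outcomes
#'
#' The screen tests every pair twice; pairs complementing in at least one
#' replicate are candidates, and candidates are confirmed only by a third,
#' independent assay. A candidate whose confirmation assay fails is demoted
#' to a negative outcome.
#'
#' @param replicates Logical vector of length 2: did each initial replicate
#'   complement?
#' @param confirmation Logical scalar or `NA`: outcome of the confirmation
#'   assay (only meaningful for candidates).
#' @return `"negative"`, `"candidate"` (complemented at least once,
#'   confirmation pending) or `"confirmed"`.
#' @export
screen_decision <- function(replicates, confirmation = NA) {
  if (length(replicates) != 2 || any(is.na(replicates))) {
    abort("Exactly two non-missing initial replicates are required.")
  }
  candidate <- any(replicates)
  if (!candidate) {
    if (!is.na(confirmation)) {
      abort("A confirmation outcome was supplied for a negative pair.")
    }
    return("negative")
  }
  if (is.na(confirmation)) return("candidate")
  if (confirmation) "confirmed" else "negative"
}

#' Classify an FC score as deleterious
#'
#' @param fc FC score(s) in \[0, 1\].
#' @param threshold Scores strictly greater than this are deleterious
#'   (default 0.5).
#' @return Logical vector.
#' @export
classify_deleterious <- function(fc, threshold = 0.5) {
  if (any(fc < 0 | fc > 1, na.rm = TRUE)) abort("FC scores must lie in [0, 1].")
  fc > threshold
}
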