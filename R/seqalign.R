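AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

default_submat <- function() {
  # 20x20 slice of BLOSUM62 shipped with Biostrings
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
}

#' Global protein alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch global alignment of two protein sequences under
#' an affine gap model (a gap of length *k* costs
#' `gap_open + (k - 1) * gap_extend`). Traceback ties are resolved
#' deterministically, preferring a residue pairing over a gap in the second
#' sequence over a gap in the first, so identical inputs always give
#' identical alignments.
#'
#' @param a,b Protein sequences (non-empty strings over the 20 standard
#'   amino acids). By convention `a` is the human protein and `b` the yeast
#'   protein in aligned-region analyses.
#' @param submat A 20x20 (or larger) named substitution matrix; default
#'   BLOSUM62 from Biostrings.
#' @param gap_open,gap_extend Positive gap penalties; `gap_open` must be at
#'   least `gap_extend`. Defaults 11 and 1, the ubiquitous protein
#'   defaults.
#' @return An object of class `protein_alignment`: a list with `gapped_a`,
#'   `gapped_b` (equal-length strings over residues and `-`), the alignment
#'   `score`, and `columns`, a tibble with 1-based residue coordinates
#'   `a_pos`, `b_pos` (`NA` where a sequence is gapped; no column is
#'   gap/gap).
#' @export
#' @examples
#' aln <- align_global("ACDEFG", "ACDKFG")
#' aln$columns
align_global <- function(a, b, submat = NULL, gap_open = 11, gap_extend = 1) {
  check_protein(a, "a")
  check_protein(b, "b")
  stop_if_not_scalar_number(gap_open, "gap_open")
  stop_if_not_scalar_number(gap_extend, "gap_extend")
  if (gap_open <= 0 || gap_extend <= 0) abort("Gap penalties must be positive.")
  if (gap_open < gap_extend) abort("`gap_open` must be >= `gap_extend`.")
  if (is.null(submat)) submat <- default_submat()

  alpha <- rownames(submat)
  a_chr <- strsplit(a, "")[[1]]
  b_chr <- strsplit(b, "")[[1]]
  a_idx <- match(a_chr, alpha) - 1L
  b_idx <- match(b_chr, alpha) - 1L

  res <- nw_align_cpp(a_idx, b_idx, submat, gap_open, gap_extend)
  a_pos <- ifelse(res$a_pos == 0L, NA_integer_, res$a_pos)
  b_pos <- ifelse(res$b_pos == 0L, NA_integer_, res$b_pos)

  structure(
    list(
      gapped_a = paste(ifelse(is.na(a_pos), "-", a_chr[a_pos]), collapse = ""),
      gapped_b = paste(ifelse(is.na(b_pos), "-", b_chr[b_pos]), collapse = ""),
      score = res$score,
      columns = tibble::tibble(a_pos = a_pos, b_pos = b_pos),
      a = a, b = b
    ),
    class = "protein_alignment"
  )
}

check_protein <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0) {
    abort(sprintf("`%s` must be a single non-empty protein string.", name))
  }
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)) {
    abort(sprintf("`%s` contains characters outside the amino-acid alphabet.", name))
  }
  invisible(x)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Global protein alignment (score ", x$score, ")\n", sep = "")
  cat(" a: ", x$gapped_a, "\n b: ", x$gapped_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Computes percent sequence identity (PID) under one of four denominators.
#' `aligned_columns` (the default) is the percentage of gap-free alignment
#' columns carrying identical residues; `alignment_length` divides by all
#' columns including gaps, and is therefore substantially lower when the
#' aligned region is much shorter than the full alignment;
#' `shorter_sequence` divides by the length of the shorter input;
#' `mean_length` divides by the rounded mean of the two input lengths.
#'
#' @param alignment A [align_global()] result.
#' @param method One of `"aligned_columns"`, `"alignment_length"`,
#'   `"shorter_sequence"`, `"mean_length"`; may be a vector to get several
#'   definitions at once.
#' @return A tibble with one row per requested method and columns `method`,
#'   `identities`, `denominator`, `pid` (a percentage in \[0, 100\]).
#' @export
percent_identity <- function(alignment, method = "aligned_columns") {
  if (!inherits(alignment, "protein_alignment")) {
    abort("`alignment` must come from align_global().")
  }
  choices <- c("aligned_columns", "alignment_length", "shorter_sequence",
               "mean_length")
  method <- match.arg(method, choices, several.ok = TRUE)
  cols <- alignment$columns
  paired <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  a_chr <- strsplit(alignment$a, "")[[1]]
  b_chr <- strsplit(alignment$b, "")[[1]]
  identities <- sum(a_chr[cols$a_pos[paired]] == b_chr[cols$b_pos[paired]])

  denom_of <- c(
    aligned_columns = sum(paired),
    alignment_length = nrow(cols),
    shorter_sequence = min(nchar(alignment$a), nchar(alignment$b)),
    mean_length = round((nchar(alignment$a) + nchar(alignment$b)) / 2)
  )
  denominator <- unname(denom_of[method])
  if (any(denominator == 0)) abort("PID denominator is zero.")
  tibble::tibble(
    method = method,
    identities = identities,
    denominator = as.integer(denominator),
    pid = 100 * identities / denominator
  )
}

#' Does a variant position fall in the aligned region?
#'
#' A human residue is "in the aligned region" when its alignment column
#' pairs it with a yeast residue. With `region = "gap_free"` (default) a
#' residue opposite a gap is outside the region even when flanked by
#' aligned columns; `region = "span"` instead counts every human position
#' between the first and last paired column as aligned.
#'
#' @param alignment A [align_global()] result with `a` the human and `b`
#'   the yeast protein.
#' @param positions 1-based positions in the human protein (vectorised).
#' @param region `"gap_free"` or `"span"`.
#' @return Logical vector, one entry per position.
#' @export
in_aligned_region <- function(alignment, positions,
                              region = c("gap_free", "span")) {
  if (!inherits(alignment, "protein_alignment")) {
    abort("`alignment` must come from align_global().")
  }
  region <- match.arg(region)
  n <- nchar(alignment$a)
  if (any(is.na(positions)) || any(positions < 1) || any(positions > n)) {
    abort(sprintf("Positions must lie in [1, %d].", n))
  }
  cols <- alignment$columns
  paired_a <- cols$a_pos[!is.na(cols$a_pos) & !is.na(cols$b_pos)]
  if (region == "gap_free") {
    positions %in% paired_a
  } else {
    if (length(paired_a) == 0) rep(FALSE, length(positions))
    else positions >= min(paired_a) & positions <= max(paired_a)
  }
}

#' Histogram of percent identity by complementation class
#'
#' Bins pair-level PID values separately for complementing and
#' non-complementing pairs on half-open bins `[lo, lo + width)` (the final
#' bin closes at 100), as used to relate sequence similarity to
#' complementation outcome.
#'
#' @param pairs A tibble with numeric `pid` in \[0, 100\] and logical
#'   `complements`.
#' @param bin_width Bin width in percentage points (default 10).
#' @return An object of class `pid_histogram`: a tibble with `complements`,
#'   `bin_lo`, `bin_hi`, `count` (all bins present for both classes, zero
#'   counts included).
#' @export
pid_histogram <- function(pairs, bin_width = 10) {
  check_columns(pairs, c("pid", "complements"), "Pair table")
  stop_if_not_scalar_number(bin_width, "bin_width")
  if (bin_width <= 0 || bin_width > 100) abort("`bin_width` must be in (0, 100].")
  if (nrow(pairs) > 0 && (any(pairs$pid < 0) || any(pairs$pid > 100))) {
    abort("PID values must lie in [0, 100].")
  }
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  lo <- utils::head(breaks, -1)
  lo <- lo[lo < 100]
  cap <- max(lo)  # PID exactly 100 falls in the top bin
  grid <- tidyr::expand_grid(complements = c(TRUE, FALSE), bin_lo = lo)
  counts <- pairs |>
    dplyr::mutate(bin_lo = pmin(bin_width * floor(.data$pid / bin_width), cap)) |>
    dplyr::count(.data$complements, .data$bin_lo, name = "count")
  out <- grid |>
    dplyr::left_join(counts, by = c("complements", "bin_lo")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  bin_hi = .data$bin_lo + bin_width) |>
    dplyr::filter(.data$bin_lo < 100) |>
    dplyr::select("complements", "bin_lo", "bin_hi", "count")
  class(out) <- c("pid_histogram", class(out))
  out
}

#' @export
autoplot.pid_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
                               y = .data$count,
                               fill = .data$complements)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Percent identity", y = "Pairs",
                  fill = "Complements") +
    ggplot2::theme_minimal()
}

#' Percent identity for a table of homolog pairs
#'
#' Convenience wrapper: aligns each (human, yeast) pair from a sequence map
#' and returns one PID row per pair.
#'
#' @param pairs Tibble with `human_gene`, `yeast_gene`.
#' @param sequences Named character vector of protein sequences covering
#'   every gene referenced.
#' @param method PID definition passed to [percent_identity()].
#' @inheritParams align_global
#' @return `pairs` with columns `identities`, `denominator`, `pid` added.
#' @export
pair_pid <- function(pairs, sequences, method = "aligned_columns",
                     submat = NULL, gap_open = 11, gap_extend = 1) {
  check_columns(pairs, c("human_gene", "yeast_gene"), "Pair table")
  need <- unique(c(pairs$human_gene, pairs$yeast_gene))
  absent <- setdiff(need, names(sequences))
  if (length(absent) > 0) {
    abort(sprintf("No sequence supplied for: %s.", paste(absent, collapse = ", ")))
  }
  if (is.null(submat)) submat <- default_submat()
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    aln <- align_global(sequences[[pairs$human_gene[i]]],
                        sequences[[pairs$yeast_gene[i]]],
                        submat = submat, gap_open = gap_open,
                        gap_extend = gap_extend)
    percent_identity(aln, method)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res) |>
                     dplyr::select("identities", "denominator", "pid"))
}
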