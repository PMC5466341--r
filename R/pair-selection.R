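#' Significant domain accessions per gene
#'
#' Filters domain hits at an E-value cutoff and collapses repeated hits to
#' the same accession, giving the set of domain types significantly present
#' in each protein. The default cutoff of 0.001 is the conventional
#' threshold for calling a Pfam domain present.
#'
#' @param domains A tibble of domain hits with columns `gene_id`,
#'   `accession`, `e_value` (see [read_domain_table()]).
#' @param e_value_cutoff Maximum E-value for a hit to count (default 0.001).
#' @return A tibble with columns `gene_id`, `accession`, one row per
#'   (gene, accession) with at least one hit at or below the cutoff.
#' @export
#' @examples
#' hits <- tibble::tibble(gene_id = "RPS6KL1",
#'                        accession = c("PF00069", "PF04212"),
#'                        e_value = c(1e-30, 1e-5))
#' significant_domains(hits)
significant_domains <- function(domains, e_value_cutoff = 0.001) {
  check_columns(domains, c("gene_id", "accession", "e_value"), "Domain table")
  stop_if_not_scalar_number(e_value_cutoff, "e_value_cutoff")
  if (e_value_cutoff <= 0) abort("`e_value_cutoff` must be > 0.")
  if (any(is.na(domains$e_value)) || any(domains$e_value < 0)) {
    abort("Domain E-values must be non-negative and non-missing.")
  }
  domains |>
    dplyr::filter(.data$e_value <= e_value_cutoff) |>
    dplyr::distinct(.data$gene_id, .data$accession) |>
    dplyr::arrange(.data$gene_id, .data$accession)
}

#' Is every yeast domain covered by the human protein?
#'
#' A human-yeast pair is eligible for complementation testing when all
#' domain types in the yeast protein are also found in the human protein
#' (coverage is by accession set membership; copy number and position are
#' ignored).
#'
#' @param yeast_domains,human_domains Character vectors of domain
#'   accessions.
#' @return `TRUE` iff `yeast_domains` is a subset of `human_domains`; the
#'   empty yeast set is covered by anything.
#' @export
domain_covered <- function(yeast_domains, human_domains) {
  all(yeast_domains %in% human_domains)
}

#' Select human-yeast paralog pairs eligible for complementation testing
#'
#' Reconstructs the assay search space: a pair is retained when it is a
#' paralog (not annotated as an ortholog), the human gene is a disease gene
#' with an available expression clone, the yeast gene is essential with an
#' available temperature-sensitive allele, and every significant domain of
#' the yeast protein is covered by the human protein.
#'
#' @param pairs Homolog pair tibble (`human_gene`, `yeast_gene`,
#'   `annotated_ortholog`, optionally more columns, kept).
#' @param genes Gene attribute tibble (see [read_gene_table()]).
#' @param domains Domain hit tibble (see [read_domain_table()]).
#' @param e_value_cutoff E-value cutoff for [significant_domains()].
#' @return The retained pairs, sorted by human then yeast gene id, with
#'   attributes `n_human_genes` and `n_yeast_genes` giving the number of
#'   distinct genes retained.
#' @export
select_pairs <- function(pairs, genes, domains, e_value_cutoff = 0.001) {
  check_columns(pairs, c("human_gene", "yeast_gene", "annotated_ortholog"),
                "Homolog pair table")
  check_columns(genes, c("gene_id", "species"), "Gene table")

  known <- genes$gene_id
  unknown <- !(pairs$human_gene %in% known) | !(pairs$yeast_gene %in% known)
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(sprintf("Pair (%s, %s) references a gene with no gene record.",
                  pairs$human_gene[i], pairs$yeast_gene[i]))
  }

  sig <- significant_domains(domains, e_value_cutoff)
  dom_sets <- split(sig$accession, sig$gene_id)

  human <- genes[match(pairs$human_gene, genes$gene_id), ]
  yeast <- genes[match(pairs$yeast_gene, genes$gene_id), ]
  covered <- vapply(seq_len(nrow(pairs)), function(i) {
    domain_covered(dom_sets[[pairs$yeast_gene[i]]] %||% character(),
                   dom_sets[[pairs$human_gene[i]]] %||% character())
  }, logical(1))

  keep <- !pairs$annotated_ortholog &
    isTRUE_vec(human$is_disease_gene) &
    isTRUE_vec(human$clone_available) &
    isTRUE_vec(yeast$is_essential) &
    isTRUE_vec(yeast$ts_allele_available) &
    covered

  out <- pairs[keep, , drop = FALSE] |>
    dplyr::arrange(.data$human_gene, .data$yeast_gene)
  attr(out, "n_human_genes") <- dplyr::n_distinct(out$human_gene)
  attr(out, "n_yeast_genes") <- dplyr::n_distinct(out$yeast_gene)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a
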