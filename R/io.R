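#' Read a missense variant table
#'
#' Parses a tab-separated table of human missense variants annotated with
#' disease status, a failure-to-complement (FC) score from a yeast assay, and
#' computational pathogenicity scores (PolyPhen-2, PROVEAN). Substitution
#' strings such as `"R159C"` are split into reference residue, 1-based protein
#' position and alternate residue. Empty cells in numeric columns are read as
#' missing; extra columns (for example printed Prediction calls) are kept
#' as-is.
#'
#' @param path Path to a UTF-8 TSV file with a header row. Required columns:
#'   `gene_symbol`, `entrez_id`, `substitution`, `disease_associated`
#'   (Yes/No or TRUE/FALSE), `fc_score`; optional: `pph2_score`,
#'   `provean_score`, `in_aligned_region`.
#' @param sequences Optional named character vector of protein sequences
#'   (as returned by [read_fasta()]). When supplied, each variant's reference
#'   residue is checked against the sequence; a mismatch raises a warning,
#'   not an error.
#'
#' @return A tibble with one row per variant, in file order, with columns
#'   `gene_symbol`, `entrez_id`, `substitution`, `ref_aa`, `position`,
#'   `alt_aa`, `disease_associated`, `fc_score`, `pph2_score`,
#'   `provean_score`, `in_aligned_region`, plus any extra input columns.
#' @export
#' @examples
#' read_variant_table(system.file("extdata", "table2_variants.tsv",
#'                                package = "paracomp"))
read_variant_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  check_columns(raw, c("gene_symbol", "entrez_id", "substitution",
                       "disease_associated", "fc_score"), "Variant table")
  n <- nrow(raw)
  if (n == 0) {
    return(empty_variant_table(raw))
  }

  sub <- parse_substitutions(raw$substitution)

  key <- paste(raw$gene_symbol, raw$substitution)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (gene, substitution) entries: %s.",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }

  out <- tibble::tibble(
    gene_symbol = raw$gene_symbol,
    entrez_id = parse_numeric_col(raw$entrez_id, "entrez_id", integer = TRUE),
    substitution = raw$substitution,
    ref_aa = sub$ref_aa,
    position = sub$position,
    alt_aa = sub$alt_aa,
    disease_associated = parse_logical_col(raw$disease_associated, "disease_associated"),
    fc_score = parse_numeric_col(raw$fc_score, "fc_score"),
    pph2_score = if ("pph2_score" %in% names(raw))
      parse_numeric_col(raw$pph2_score, "pph2_score") else NA_real_,
    provean_score = if ("provean_score" %in% names(raw))
      parse_numeric_col(raw$provean_score, "provean_score") else NA_real_,
    in_aligned_region = if ("in_aligned_region" %in% names(raw))
      parse_logical_col(raw$in_aligned_region, "in_aligned_region") else NA
  )
  extra <- setdiff(names(raw), names(out))
  for (col in extra) out[[col]] <- raw[[col]]

  bad_fc <- which(!is.na(out$fc_score) & (out$fc_score < 0 | out$fc_score > 1))
  if (length(bad_fc) > 0) {
    abort(sprintf("fc_score outside [0, 1] in row(s) %s.",
                  paste(bad_fc, collapse = ", ")))
  }

  if (!is.null(sequences)) check_reference_residues(out, sequences)
  out
}

empty_variant_table <- function(raw) {
  out <- tibble::tibble(
    gene_symbol = character(), entrez_id = integer(),
    substitution = character(), ref_aa = character(),
    position = integer(), alt_aa = character(),
    disease_associated = logical(), fc_score = double(),
    pph2_score = double(), provean_score = double(),
    in_aligned_region = logical()
  )
  for (col in setdiff(names(raw), names(out))) out[[col]] <- character()
  out
}

parse_substitutions <- function(x) {
  m <- stringr::str_match(x, "^([ACDEFGHIKLMNPQRSTVWY])([0-9]+)([ACDEFGHIKLMNPQRSTVWY])$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed substitution string in row(s) %s: %s.",
                  paste(bad, collapse = ", "),
                  paste(unique(x[bad]), collapse = "; ")))
  }
  pos <- as.integer(m[, 3])
  same <- which(m[, 2] == m[, 4])
  if (length(same) > 0) {
    abort(sprintf("Substitution with identical reference and alternate residue in row(s) %s.",
                  paste(same, collapse = ", ")))
  }
  if (any(pos < 1)) abort("Substitution positions must be >= 1.")
  list(ref_aa = m[, 2], position = pos, alt_aa = m[, 4])
}

parse_numeric_col <- function(x, name, integer = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric value in column %s, row(s) %s: %s.",
                  name, paste(bad, collapse = ", "),
                  paste(unique(x[bad]), collapse = "; ")))
  }
  out[x == ""] <- NA
  if (integer) as.integer(out) else out
}

parse_logical_col <- function(x, name) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("YES", "TRUE", "1")] <- TRUE
  out[up %in% c("NO", "FALSE", "0")] <- FALSE
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Column %s has non Yes/No value in row(s) %s.",
                  name, paste(bad, collapse = ", ")))
  }
  out
}

check_reference_residues <- function(tbl, sequences) {
  for (i in seq_len(nrow(tbl))) {
    seq <- sequences[[tbl$gene_symbol[i]]]
    if (is.null(seq) || is.na(seq)) next
    pos <- tbl$position[i]
    if (pos > nchar(seq) || substr(seq, pos, pos) != tbl$ref_aa[i]) {
      warn(sprintf("Reference residue mismatch for %s %s against supplied sequence.",
                   tbl$gene_symbol[i], tbl$substitution[i]))
    }
  }
  invisible(tbl)
}

# md5 of the shipped benchmark table, frozen at packaging time
TABLE2_MD5 <- "c27c8e0ba43bdd335faff383e7312d5b"

#' Load the packaged 35-variant benchmark table
#'
#' Returns the packaged table of 35 human missense variants across 7 genes
#' (19 disease-associated, 16 not), each with its failure-to-complement (FC)
#' score from a paralog-based yeast complementation assay, PolyPhen-2 and
#' PROVEAN scores, the published Damaging/Neutral calls for all three
#' systems, and a flag for whether the variant lies in the human-yeast
#' aligned region. The file's checksum is verified on load so the provenance
#' of the benchmark is auditable.
#'
#' @return A tibble of 35 variant records (see [read_variant_table()]).
#' @export
#' @examples
#' v <- table2_variants()
#' dplyr::count(v, disease_associated)
table2_variants <- function() {
  path <- system.file("extdata", "table2_variants.tsv", package = "paracomp")
  if (path == "" || !file.exists(path)) {
    abort("Packaged variant table is missing; reinstall the package.")
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE2_MD5)) {
    abort("Packaged variant table is corrupt (checksum mismatch).")
  }
  read_variant_table(path)
}

#' Read a protein FASTA file
#'
#' Reads amino-acid sequences, folding the body to upper case and stripping a
#' single terminal stop (`*`). Any other non amino-acid character is an
#' error.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping sequence id (first whitespace
#'   token of the header) to its amino-acid string.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  # read as raw byte strings: the AA reader silently drops invalid codes,
  # which must be a hard error here
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- sub("\\*$", "", seqs)
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seqs)
  if (any(bad)) {
    abort(sprintf("Non amino-acid characters in sequence(s): %s.",
                  paste(names(seqs)[bad], collapse = ", ")))
  }
  seqs
}

#' Read a homolog pair table
#'
#' @param path TSV with columns `human_gene`, `yeast_gene`,
#'   `annotated_ortholog`; optional `complements`, `pid`.
#' @return A tibble, one row per (human, yeast) pair.
#' @export
read_homolog_pairs <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  check_columns(raw, c("human_gene", "yeast_gene", "annotated_ortholog"),
                "Homolog pair table")
  key <- paste(raw$human_gene, raw$yeast_gene)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate homolog pair(s): %s.",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  out <- tibble::tibble(
    human_gene = raw$human_gene,
    yeast_gene = raw$yeast_gene,
    annotated_ortholog = parse_logical_col(raw$annotated_ortholog, "annotated_ortholog")
  )
  if ("complements" %in% names(raw)) {
    out$complements <- parse_logical_col(raw$complements, "complements")
  }
  if ("pid" %in% names(raw)) out$pid <- parse_numeric_col(raw$pid, "pid")
  out
}

#' Read a gene attribute table
#'
#' @param path TSV with columns `gene_id`, `species` (human/yeast) and the
#'   attribute flags `is_disease_gene`, `clone_available` (human) and
#'   `is_essential`, `ts_allele_available` (yeast); attributes that do not
#'   apply to a species may be empty.
#' @return A tibble, one row per gene.
#' @export
read_gene_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  check_columns(raw, c("gene_id", "species"), "Gene table")
  if (!all(raw$species %in% c("human", "yeast"))) {
    abort("Gene table `species` must be 'human' or 'yeast'.")
  }
  flags <- c("is_disease_gene", "clone_available", "is_essential",
             "ts_allele_available")
  out <- tibble::tibble(gene_id = raw$gene_id, species = raw$species)
  for (f in flags) {
    out[[f]] <- if (f %in% names(raw)) parse_logical_col(raw[[f]], f) else NA
  }
  out
}

#' Read a protein domain hit table
#'
#' @param path TSV with columns `gene_id`, `accession`, `e_value`; optional
#'   `start`, `end` (1-based inclusive protein coordinates).
#' @return A tibble, one row per domain hit.
#' @export
read_domain_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  check_columns(raw, c("gene_id", "accession", "e_value"), "Domain table")
  out <- tibble::tibble(
    gene_id = raw$gene_id,
    accession = raw$accession,
    e_value = parse_numeric_col(raw$e_value, "e_value")
  )
  if (any(out$e_value < 0, na.rm = TRUE)) abort("Domain E-values must be >= 0.")
  out$start <- if ("start" %in% names(raw))
    as.integer(parse_numeric_col(raw$start, "start")) else NA_integer_
  out$end <- if ("end" %in% names(raw))
    as.integer(parse_numeric_col(raw$end, "end")) else NA_integer_
  bad <- which(!is.na(out$start) & !is.na(out$end) & out$start > out$end)
  if (length(bad) > 0) {
    abort(sprintf("Domain hit with start > end in row(s) %s.",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Write and read analysis reports
#'
#' `write_report()` serialises a data frame (TSV) or an arbitrary list
#' (JSON) losslessly; `read_report()` reads it back.
#'
#' @param x A data frame (for TSV) or list (for JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed object (tibble for TSV, list for JSON).
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(x)) abort("TSV reports require a data frame.")
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
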