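#' Read a reference gene catalogue
#'
#' The catalogue anchors classification: each row gives a gene symbol, the
#' canonical protein length in amino acids, and (optionally) the
#' transmembrane (TM) spans of the canonical protein as 1-based inclusive
#' residue intervals, written `"start-end"` and separated by semicolons
#' (e.g. `"5-25;40-60"`). TM spans must be sorted, non-overlapping, and lie
#' within `[1, ref_length]`.
#'
#' @param path Path to a tab-separated file with header columns `symbol`,
#'   `ref_length`, and optionally `tm_spans`.
#' @return A tibble with columns `symbol` (character), `ref_length`
#'   (integer), and `tm_spans` (list column of two-column integer matrices
#'   with columns `start`, `end`; a 0-row matrix when the gene has no
#'   annotated spans).
#' @export
#' @examples
#' path <- system.file("extdata", "example_catalog.tsv", package = "avipurge")
#' read_catalog(path)
read_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("symbol", "ref_length") %in% names(raw))) {
    abort("catalogue must have 'symbol' and 'ref_length' columns")
  }
  if (anyDuplicated(raw$symbol)) {
    dup <- raw$symbol[duplicated(raw$symbol)][1]
    line <- which(raw$symbol == dup)[2] + 1L
    abort(paste0("duplicate symbol '", dup, "' at line ", line))
  }
  len <- suppressWarnings(as.integer(raw$ref_length))
  bad <- which(is.na(len) | len < 1L)
  if (length(bad)) {
    abort(paste0("ref_length must be a positive integer; offending line ", bad[1] + 1L))
  }
  spans_raw <- if ("tm_spans" %in% names(raw)) raw$tm_spans else rep(NA_character_, nrow(raw))
  spans <- purrr::pmap(list(spans_raw, len, seq_along(len)), parse_tm_spans)
  tibble(symbol = raw$symbol, ref_length = len, tm_spans = spans)
}

parse_tm_spans <- function(txt, ref_length, row) {
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (is.na(txt) || !nzchar(trimws(txt))) return(empty)
  parts <- strsplit(trimws(txt), ";", fixed = TRUE)[[1]]
  m <- stringr::str_match(trimws(parts), "^(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("malformed TM interval '", parts[which(is.na(m[, 1]))[1]],
                 "' at line ", row + 1L))
  }
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  ok <- all(start >= 1L) && all(end <= ref_length) && all(start <= end) &&
    (length(start) < 2 || all(diff(start) > 0 & utils::head(end, -1) < start[-1]))
  if (!ok) {
    abort(paste0("TM spans must be sorted, non-overlapping and within [1, ref_length]",
                 " at line ", row + 1L))
  }
  cbind(start = start, end = end)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one module per line, tab-separated fields
#' `name`, `description`, then member gene symbols. Duplicate members
#' within a module are collapsed; a module with zero members is kept
#' (empty) with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (module id -> member symbols),
#'   of class `module_set`. The nonredundant union of members is available
#'   via [module_union()].
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- purrr::map_chr(fields, 1)
  members <- purrr::map(fields, function(f) {
    mem <- if (length(f) > 2) f[-(1:2)] else character()
    unique(mem[nzchar(mem)])
  })
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(paste0("module(s) with zero members kept empty: ",
                paste(ids[empty], collapse = ", ")))
  }
  structure(setNames(members, ids), class = "module_set")
}

#' Nonredundant union of module members
#'
#' @param modules A `module_set` (named list of member symbol vectors),
#'   e.g. from [read_gmt()].
#' @return Integer count of distinct gene symbols across all modules.
#' @export
module_union <- function(modules) length(unique(unlist(modules, use.names = FALSE)))

#' Read and write species hit tables
#'
#' A hit table has one row per species x gene observation (an explicit
#' no-hit row has `hit_length` `NA`): columns `species`, `clade` (one of
#' [clade_levels()]), `gene`, `hit_length` (amino acids, `NA` when the gene
#' has no detectable hit), `paralog_index` (integer >= 1), and optionally
#' `sequence` (amino-acid string whose length must equal `hit_length`).
#' `write_hits()` followed by `read_hits()` is an identity.
#'
#' @param path Path to a tab-separated hit table.
#' @return `read_hits()` returns a tibble; `write_hits()` returns `path`
#'   invisibly.
#' @export
read_hits <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    clade = readr::col_character(),
    gene = readr::col_character(),
    hit_length = readr::col_integer(),
    paralog_index = readr::col_integer(),
    .default = readr::col_character()
  ))
  validate_hits(tab)
}

#' @rdname read_hits
#' @param hits A hit-table tibble (as produced by [simulate_panel()] or
#'   [read_hits()]).
#' @export
write_hits <- function(hits, path) {
  hits <- validate_hits(hits)
  readr::write_tsv(hits, path, na = "NA")
  invisible(path)
}

validate_hits <- function(hits) {
  hits <- as_tibble(hits)
  need <- c("species", "clade", "gene", "hit_length")
  if (!all(need %in% names(hits))) {
    abort(paste0("hit table needs columns: ", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(hits$clade), CLADE_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown clade label(s) ", paste(sQuote(bad), collapse = ", "),
                 "; allowed: ", paste(CLADE_LEVELS, collapse = ", ")))
  }
  if (!"paralog_index" %in% names(hits)) hits$paralog_index <- 1L
  if ("sequence" %in% names(hits)) {
    has_seq <- !is.na(hits$sequence)
    mismatch <- has_seq & (is.na(hits$hit_length) | nchar(hits$sequence) != hits$hit_length)
    if (any(mismatch)) {
      abort(paste0("sequence length differs from hit_length for ",
                   sum(mismatch), " row(s), e.g. ",
                   hits$species[which(mismatch)[1]], "/", hits$gene[which(mismatch)[1]]))
    }
  }
  hits
}

#' Write hit sequences as FASTA
#'
#' Headers follow the `species|gene|paralog_index` convention. Rows without
#' a sequence are skipped.
#'
#' @param hits A hit-table tibble with a `sequence` column.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_hit_fasta <- function(hits, path) {
  hits <- validate_hits(hits)
  if (!"sequence" %in% names(hits)) abort("hit table has no 'sequence' column")
  keep <- hits[!is.na(hits$sequence), ]
  seqs <- Biostrings::AAStringSet(keep$sequence)
  names(seqs) <- paste(keep$species, keep$gene, keep$paralog_index, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an amino-acid FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_aa_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Read a long-format metabolite table
#'
#' Expected CSV columns: `metabolite`, `genotype` (`WT`/`KO`), `replicate`,
#' `intensity`, and optionally `isotopologue` (the mass shift `i` of M+i).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_metab <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    metabolite = readr::col_character(),
    genotype = readr::col_character(),
    intensity = readr::col_double(),
    .default = readr::col_guess()
  ))
  if (any(tab$intensity < 0, na.rm = TRUE)) abort("intensities must be >= 0")
  tab
}
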