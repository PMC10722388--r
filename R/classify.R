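#' Classify per-species hits as present, truncated, or absent
#'
#' A hit is `absent` when the species has no detectable hit
#' (`hit_length` `NA`), `present` when its length fraction
#' `hit_length / ref_length` reaches `present_threshold`, and `truncated`
#' otherwise. Hits longer than the reference (isoform or annotation slack)
#' classify as present. For genes with annotated transmembrane spans the
#' number of fully removed TM domains is reported, interpreting truncation
#' as N-terminal loss by default (see [count_tm_removed()]).
#'
#' @param hits A hit-table tibble (see [read_hits()]).
#' @param catalog Reference catalogue tibble from [read_catalog()]; every
#'   gene in `hits` must appear in it.
#' @param present_threshold Fraction of the reference length at or above
#'   which a hit is full-length; in `(0, 1]`, default `0.70`.
#' @param terminal Which end truncation removes; affects only `tm_removed`.
#' @return A tibble with columns `species`, `clade`, `gene`, `status`
#'   (factor: present/truncated/absent), `length_fraction`, `tm_removed`.
#'   One row per species x gene; paralog rows collapse to the longest hit.
#' @export
#' @examples
#' catalog <- tibble::tibble(symbol = "SLC3A2", ref_length = 529L,
#'                           tm_spans = list(cbind(start = 105L, end = 125L)))
#' hits <- tibble::tibble(species = c("kakapo", "zebra_finch", "swift"),
#'                        clade = "neoaves", gene = "SLC3A2",
#'                        hit_length = c(529L, 138L, NA), paralog_index = 1L)
#' classify_status(hits, catalog)
classify_status <- function(hits, catalog,
                            present_threshold = 0.70,
                            terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  if (!is.numeric(present_threshold) || length(present_threshold) != 1 ||
      present_threshold <= 0 || present_threshold > 1) {
    abort("'present_threshold' must be in (0, 1]")
  }
  hits <- validate_hits(hits)
  missing <- setdiff(unique(hits$gene), catalog$symbol)
  if (length(missing)) {
    abort(paste0("gene(s) not in catalogue: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }

  ## several paralog rows for one species x gene are one observation:
  ## keep the longest hit (a duplicated gene is certainly not absent)
  if (anyDuplicated(hits[c("species", "gene")])) {
    one <- hits |>
      dplyr::arrange(.data$species, .data$gene,
                     dplyr::desc(!is.na(.data$hit_length)),
                     dplyr::desc(.data$hit_length)) |>
      dplyr::distinct(.data$species, .data$gene, .keep_all = TRUE) |>
      dplyr::select("species", "clade", "gene", "hit_length")
  } else {
    one <- dplyr::select(hits, "species", "clade", "gene", "hit_length")
  }

  idx <- match(one$gene, catalog$symbol)
  ref_len <- catalog$ref_length[idx]
  frac <- one$hit_length / ref_len
  status <- dplyr::case_when(
    is.na(one$hit_length) ~ "absent",
    frac >= present_threshold ~ "present",
    TRUE ~ "truncated"
  )
  tm <- purrr::pmap_int(
    list(idx, one$hit_length, status),
    function(i, len, st) {
      spans <- catalog$tm_spans[[i]]
      if (st == "absent" || nrow(spans) == 0) return(NA_integer_)
      count_tm_removed(spans, catalog$ref_length[i], len, terminal = terminal)
    }
  )
  one |>
    dplyr::mutate(
      status = factor(status, levels = c("present", "truncated", "absent")),
      length_fraction = frac,
      tm_removed = tm
    )
}

#' Count transmembrane domains removed by a truncation
#'
#' With truncation modeled as N-terminal loss, the retained region of a
#' hit of length `hit_length` is residues
#' `[ref_length - hit_length + 1, ref_length]`; a TM span counts as
#' removed when it lies entirely outside the retained region. Under
#' `terminal = "C"` the retained region is `[1, hit_length]` instead.
#'
#' @param tm_spans Two-column integer matrix of 1-based inclusive residue
#'   intervals (columns `start`, `end`), sorted and non-overlapping.
#' @param ref_length Reference protein length (aa).
#' @param hit_length Observed hit length (aa). Values above `ref_length`
#'   return 0 with a warning (no removal inferable).
#' @param terminal `"N"` (default) or `"C"`.
#' @return Integer count of fully removed TM spans.
#' @export
#' @examples
#' spans <- cbind(start = c(5L, 40L, 80L), end = c(25L, 60L, 100L))
#' count_tm_removed(spans, ref_length = 120, hit_length = 50)  # 2
count_tm_removed <- function(tm_spans, ref_length, hit_length,
                             terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  if (hit_length > ref_length) {
    warn("hit longer than reference; no TM removal inferable")
    return(0L)
  }
  if (nrow(tm_spans) == 0) return(0L)
  if (terminal == "N") {
    cut <- ref_length - hit_length  # residues 1..cut removed
    sum(tm_spans[, "end"] <= cut)
  } else {
    sum(tm_spans[, "start"] > hit_length)
  }
}
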