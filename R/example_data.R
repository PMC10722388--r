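#' Synthetic worked-example panel of transporter and channel families
#'
#' Builds a small synthetic species x gene hit panel (10 Neoave and 4
#' outgroup species, all placeholder names) for four gene families whose
#' clade-wide retention patterns encode the family tallies reported for
#' Neoaves: 16/42 ATP-dependent ABC transporters, 9/14 SLC9A Na+/H+
#' exchangers, and 9/11 SCN voltage-gated Na+ channels lost, and 6/7 P2RX
#' purinoreceptors lost with only P2RX5 conserved. SCN members use real
#' symbols (SCN2A and SCN5A are retained, in duplicate); the ABC and SLC9A
#' families use placeholder symbols because only the tallies, not the
#' member-level outcomes, are published. Lost genes are absent in every
#' Neoave species and full length in every outgroup species.
#'
#' @return A list with `hits` (hit-table tibble), `catalog` (reference
#'   tibble), and `families` (named list of member symbol vectors).
#' @export
#' @examples
#' panel <- example_family_hits()
#' status <- classify_status(panel$hits, panel$catalog)
#' calls <- call_purge(status)
#' family_loss_percent(calls, panel$families$SLC9A)  # 64
example_family_hits <- function() {
  families <- list(
    ABC = sprintf("ABC_%02d", 1:42),
    SLC9A = sprintf("SLC9A_%02d", 1:14),
    SCN = paste0("SCN", 1:11, "A"),
    P2RX = paste0("P2RX", 1:7)
  )
  lost <- c(families$ABC[1:16], families$SLC9A[1:9],
            setdiff(families$SCN, c("SCN2A", "SCN5A")),
            setdiff(families$P2RX, "P2RX5"))
  duplicated_genes <- c("SCN2A", "SCN5A")
  genes <- unlist(families, use.names = FALSE)

  neo <- sprintf("neoave_%02d", 1:10)
  out <- sprintf("outgroup_%02d", 1:4)
  grid <- tidyr::expand_grid(
    species = c(neo, out),
    gene = genes
  ) |>
    dplyr::mutate(
      clade = ifelse(.data$species %in% neo, "neoaves",
                     ifelse(match(.data$species, out) %% 2 == 1,
                            "galloanserae", "palaeognathae")),
      hit_length = ifelse(.data$clade == "neoaves" & .data$gene %in% lost,
                          NA_integer_, 500L),
      paralog_index = 1L
    )
  dup_rows <- grid |>
    dplyr::filter(.data$clade == "neoaves", .data$gene %in% duplicated_genes) |>
    dplyr::mutate(paralog_index = 2L)
  hits <- dplyr::bind_rows(grid, dup_rows) |>
    dplyr::select("species", "clade", "gene", "hit_length", "paralog_index")

  catalog <- tibble(
    symbol = genes, ref_length = 500L,
    tm_spans = rep(list(matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("start", "end")))),
                   length(genes))
  )
  list(hits = hits, catalog = catalog, families = families)
}

#' Synthetic 45-module gene-set collection
#'
#' Builds a synthetic KEGG-style module collection: 45 modules over a
#' universe of 3730 placeholder human gene symbols, with overlapping
#' membership, so the nonredundant union across modules equals the
#' 3730-gene universe by construction. Useful for exercising GMT
#' round-trips and union counting at the published collection size; it is
#' not the published appendix gene list.
#'
#' @param n_modules Number of modules (default 45).
#' @param universe_size Number of distinct genes across all modules
#'   (default 3730).
#' @param overlap Members each module shares with the next module's block
#'   (default 10).
#' @return A `module_set` (named list of member symbol vectors).
#' @export
#' @examples
#' mods <- synthetic_module_gmt()
#' module_union(mods)  # 3730
synthetic_module_gmt <- function(n_modules = 45L, universe_size = 3730L,
                                 overlap = 10L) {
  check_count(n_modules, "n_modules"); check_count(universe_size, "universe_size")
  check_count(overlap, "overlap", min = 0L)
  universe <- sprintf("H%04d", seq_len(universe_size))
  block <- split(universe, cut(seq_len(universe_size), n_modules, labels = FALSE))
  members <- lapply(seq_len(n_modules), function(i) {
    nxt <- block[[if (i == n_modules) 1L else i + 1L]]
    unique(c(block[[i]], utils::head(nxt, overlap)))
  })
  structure(setNames(members, sprintf("MOD%02d", seq_len(n_modules))),
            class = "module_set")
}

#' Write a module set as GMT
#'
#' @param modules A `module_set` (named list of member symbol vectors).
#' @param path Output path.
#' @param description Description field written for every module.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path, description = "na") {
  lines <- purrr::imap_chr(modules, function(members, id) {
    paste(c(id, description, members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
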