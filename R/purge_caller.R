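#' Aggregate species status calls into clade-level purge calls
#'
#' Implements the clade-level decision rule of a Neoave purging screen.
#' Writing "lost" for a species status of absent or truncated, a gene is
#' called:
#'
#' * `purged` when it is found (present or truncated) in no Aves species
#'   at all, or when it is largely present in the extant-Aves outgroups
#'   (full-length in at least `outgroup_present_min` of outgroup species)
#'   while lost in a strict majority `> neoave_majority` of Neoave
#'   species;
#' * `retained` when it is found somewhere in Aves and its Neoave lost
#'   fraction does not exceed `neoave_majority`;
#' * `ambiguous` otherwise (found in Aves and lost in most Neoaves, but
#'   with outgroup presence below the minimum, so the outgroup gives no
#'   retention reference).
#'
#' Fractions are computed over the species that have a row for the gene in
#' the relevant clade, so unsampled species are never counted as absences.
#'
#' @param status A status tibble from [classify_status()] (columns
#'   `species`, `clade`, `gene`, `status`).
#' @param neoave_majority Neoave lost-fraction threshold, compared with a
#'   strict `>`; default `0.70`.
#' @param outgroup_present_min Minimum fraction of outgroup species
#'   (galloanserae + palaeognathae) with a full-length hit for the gene to
#'   count as "present largely in extant Aves"; default `0.50`.
#' @return A tibble with one row per gene: `gene`, `call` (factor:
#'   purged/retained/ambiguous), `neoave_lost_fraction`,
#'   `outgroup_present_fraction` (`NA` when no outgroup species has a row),
#'   `n_neoaves`, `n_outgroup`.
#' @export
#' @examples
#' sim <- simulate_panel(n_neoaves = 10, n_outgroup = 4, n_genes = 5,
#'                       p_gene_loss = 0.5, seed = 2)
#' status <- classify_status(sim$hits, sim$catalog)
#' call_purge(status)
call_purge <- function(status,
                       neoave_majority = 0.70,
                       outgroup_present_min = 0.50) {
  for (p in c(neoave_majority, outgroup_present_min)) {
    if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
      abort("thresholds must be in (0, 1]")
    }
  }
  status <- as_tibble(status)
  if (!all(c("species", "clade", "gene", "status") %in% names(status))) {
    abort("status table needs columns species, clade, gene, status")
  }
  no_neo <- setdiff(unique(status$gene),
                    unique(status$gene[status$clade == "neoaves"]))
  if (length(no_neo)) {
    abort(paste0("no Neoave species row for gene(s): ",
                 paste(utils::head(no_neo, 5), collapse = ", ")))
  }

  status |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_neoaves = sum(.data$clade == "neoaves"),
      n_outgroup = sum(.data$clade %in% OUTGROUP_CLADES),
      neoave_lost_fraction =
        sum(.data$clade == "neoaves" & .data$status != "present") / .data$n_neoaves,
      outgroup_present_fraction = ifelse(
        .data$n_outgroup == 0, NA_real_,
        sum(.data$clade %in% OUTGROUP_CLADES & .data$status == "present") /
          .data$n_outgroup),
      found_in_aves = any(.data$status != "absent"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      call = factor(dplyr::case_when(
        !.data$found_in_aves ~ "purged",
        !is.na(.data$outgroup_present_fraction) &
          .data$outgroup_present_fraction >= outgroup_present_min &
          .data$neoave_lost_fraction > neoave_majority ~ "purged",
        .data$neoave_lost_fraction <= neoave_majority ~ "retained",
        TRUE ~ "ambiguous"
      ), levels = c("purged", "retained", "ambiguous"))
    ) |>
    dplyr::select("gene", "call", "neoave_lost_fraction",
                  "outgroup_present_fraction", "n_neoaves", "n_outgroup")
}
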