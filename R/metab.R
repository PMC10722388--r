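#' KO/WT metabolite ratio summaries
#'
#' For each metabolite, per-replicate ratios are formed against the WT
#' mean, `r_j = KO_j / mean(WT)`, and summarised as their mean and sample
#' standard deviation — so `n` is the number of KO replicates, matching
#' the "mean ± SD (n = replicates)" convention of knockout metabolomics
#' panels. The alternative ratio-of-means definition (with no replicate
#' SD of its own) is available via `method = "ratio_of_means"`.
#' Metabolites whose WT mean is zero get an `NA` ratio and are flagged.
#'
#' @param table Long-format tibble with columns `metabolite`, `genotype`
#'   (`"WT"`/`"KO"`), `intensity` (see [read_metab()] /
#'   [simulate_metab()]).
#' @param method `"per_replicate"` (default) or `"ratio_of_means"`.
#' @return A tibble with one row per metabolite: `metabolite`,
#'   `ratio_mean`, `ratio_sd`, `n`, `undefined` (WT mean was zero).
#' @export
#' @examples
#' tab <- tibble::tibble(metabolite = "F6P",
#'                       genotype = rep(c("WT", "KO"), each = 3),
#'                       intensity = c(2, 2, 2, 8, 8, 8))
#' ko_wt_ratio(tab)  # ratio 4, SD 0
ko_wt_ratio <- function(table, method = c("per_replicate", "ratio_of_means")) {
  method <- match.arg(method)
  table <- as_tibble(table)
  need <- c("metabolite", "genotype", "intensity")
  if (!all(need %in% names(table))) {
    abort(paste0("metabolite table needs columns: ", paste(need, collapse = ", ")))
  }
  bad <- table |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(ok = all(c("WT", "KO") %in% .data$genotype), .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste0("both genotypes required for every metabolite; missing for: ",
                 paste(bad$metabolite[!bad$ok], collapse = ", ")))
  }

  table |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      wt_mean = mean(.data$intensity[.data$genotype == "WT"]),
      ko = list(.data$intensity[.data$genotype == "KO"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = lengths(.data$ko),
      undefined = .data$wt_mean == 0,
      ratio_mean = purrr::map2_dbl(.data$ko, .data$wt_mean, function(ko, wt) {
        if (wt == 0) return(NA_real_)
        if (method == "per_replicate") mean(ko / wt) else mean(ko) / wt
      }),
      ratio_sd = purrr::map2_dbl(.data$ko, .data$wt_mean, function(ko, wt) {
        if (wt == 0 || method == "ratio_of_means") return(NA_real_)
        sd(ko / wt)
      })
    ) |>
    dplyr::select("metabolite", "ratio_mean", "ratio_sd", "n", "undefined")
}

#' Fractional distribution of isotopologue intensities
#'
#' Normalises mass-isotopomer (M+i) intensities of each metabolite to
#' fractions summing to one — the fractional distribution of heavy-carbon
#' label after a [U-13C] tracing experiment. No natural-abundance
#' correction is applied.
#'
#' @param table Tibble with columns `metabolite`, `isotopologue` (the
#'   integer mass shift `i`), `intensity` (>= 0). A plain named or
#'   unnamed nonnegative numeric vector is also accepted and treated as
#'   one metabolite's isotopologue intensities.
#' @return A tibble `metabolite`, `isotopologue`, `fraction`, with
#'   fractions summing to 1 within each metabolite.
#' @export
#' @examples
#' fractional_labeling(c(M0 = 3, M6 = 1))
fractional_labeling <- function(table) {
  if (is.numeric(table)) {
    labs <- if (is.null(names(table))) paste0("M", seq_along(table) - 1L)
            else names(table)
    table <- tibble(metabolite = "metabolite", isotopologue = labs,
                    intensity = as.numeric(table))
  }
  table <- as_tibble(table)
  need <- c("metabolite", "isotopologue", "intensity")
  if (!all(need %in% names(table))) {
    abort(paste0("isotopologue table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(table$intensity < 0)) abort("intensities must be >= 0")
  zero <- table |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  if (any(zero$total == 0)) {
    abort(paste0("all-zero isotopologue vector for: ",
                 paste(zero$metabolite[zero$total == 0], collapse = ", ")))
  }
  table |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::mutate(fraction = .data$intensity / sum(.data$intensity)) |>
    dplyr::ungroup() |>
    dplyr::select("metabolite", "isotopologue", "fraction")
}
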