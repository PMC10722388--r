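#' Per-module gene-loss fractions with 3-SD outlier flags
#'
#' For each module, counts members with a clade-level `purged` call and
#' expresses the loss as a percentage of module members that have a call.
#' Across modules it reports the mean and sample standard deviation
#' (n - 1) of the loss percentages and flags modules lying more than
#' 3 SD from the mean, the dashed-line convention of module-loss bar
#' charts. Module members missing from the call table are dropped from the
#' denominator with a warning. Genes belonging to several modules count in
#' each module independently; the nonredundant union across modules is
#' reported separately.
#'
#' @param calls Clade-call tibble from [call_purge()].
#' @param modules A `module_set` (named list of member symbol vectors),
#'   e.g. from [read_gmt()].
#' @return An object of class `module_loss_summary`: a list with
#'   `modules` (tibble: `module`, `n_members`, `n_lost`, `loss_percent`,
#'   `outlier`), `mean_percent`, `sd_percent`, `lower_3sd`, `upper_3sd`,
#'   and `nonredundant_union`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] / [autoplot()][ggplot2::autoplot].
#' @export
#' @examples
#' calls <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                         call = factor(c("purged", "retained", "retained"),
#'                                       c("purged", "retained", "ambiguous")))
#' mods <- structure(list(M1 = c("g1", "g2"), M2 = c("g2", "g3")),
#'                   class = "module_set")
#' glance(module_loss(calls, mods))
module_loss <- function(calls, modules) {
  if (length(modules) == 0) abort("empty module set")
  calls <- as_tibble(calls)
  purged <- calls$gene[calls$call == "purged"]
  called <- calls$gene

  per_module <- purrr::imap(modules, function(members, id) {
    known <- intersect(members, called)
    dropped <- setdiff(members, called)
    tibble(module = id,
           n_members = length(known),
           n_lost = length(intersect(known, purged)),
           n_no_call = length(dropped))
  }) |> dplyr::bind_rows()

  if (any(per_module$n_no_call > 0)) {
    warn(paste0(sum(per_module$n_no_call),
                " module member(s) without a clade call were excluded from denominators"))
  }
  per_module <- per_module |>
    dplyr::filter(.data$n_members >= 1) |>
    dplyr::mutate(loss_percent = 100 * .data$n_lost / .data$n_members)
  if (nrow(per_module) == 0) abort("no module has any called member")

  mean_pct <- mean(per_module$loss_percent)
  sd_pct <- if (nrow(per_module) > 1) sd(per_module$loss_percent) else 0
  per_module <- per_module |>
    dplyr::mutate(outlier = abs(.data$loss_percent - mean_pct) > 3 * sd_pct) |>
    dplyr::select("module", "n_members", "n_lost", "loss_percent", "outlier")

  structure(list(
    modules = per_module,
    mean_percent = mean_pct,
    sd_percent = sd_pct,
    lower_3sd = mean_pct - 3 * sd_pct,
    upper_3sd = mean_pct + 3 * sd_pct,
    nonredundant_union = module_union(modules)
  ), class = "module_loss_summary")
}

#' @export
print.module_loss_summary <- function(x, ...) {
  cat(sprintf("Module loss over %d modules (%d nonredundant genes)\n",
              nrow(x$modules), x$nonredundant_union))
  cat(sprintf("  mean %.1f%% ± %.2f SD; 3-SD band [%.1f, %.1f]; %d outlier(s)\n",
              x$mean_percent, x$sd_percent,
              max(x$lower_3sd, 0), min(x$upper_3sd, 100), sum(x$modules$outlier)))
  print(x$modules, ...)
  invisible(x)
}

#' Loss percentage of an explicit gene family
#'
#' Counts family members lost clade-wide in Neoaves and returns the
#' integer percentage, rounding half away from zero — the convention that
#' prints 64 for 9/14 and 38 for 16/42. The numerator counts members whose
#' clade call is `purged` and, by default, `ambiguous` members too: an
#' ambiguous call still means the gene is absent or truncated in a
#' majority of Neoaves (only the outgroup reference is missing), matching
#' the "absent or severely truncated" reading of family tallies.
#'
#' @param calls Clade-call tibble from [call_purge()].
#' @param family Character vector of member gene symbols.
#' @param count_ambiguous Count `ambiguous` calls in the numerator
#'   (default `TRUE`).
#' @return A one-row tibble: `n_lost`, `n_members`, `loss_percent`
#'   (integer).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   gene = paste0("SLC9A_", 1:14),
#'   call = factor(rep(c("purged", "retained"), c(9, 5)),
#'                 c("purged", "retained", "ambiguous")))
#' family_loss_percent(calls, paste0("SLC9A_", 1:14))
family_loss_percent <- function(calls, family, count_ambiguous = TRUE) {
  family <- unique(family)
  if (length(family) == 0) abort("empty family")
  calls <- as_tibble(calls)
  known <- calls |> dplyr::filter(.data$gene %in% family)
  missing <- setdiff(family, known$gene)
  if (length(missing)) {
    warn(paste0("family member(s) without a call excluded: ",
                paste(missing, collapse = ", ")))
  }
  if (nrow(known) == 0) abort("no family member has a clade call")
  lost_calls <- if (count_ambiguous) c("purged", "ambiguous") else "purged"
  k <- sum(known$call %in% lost_calls)
  n <- nrow(known)
  tibble(n_lost = k, n_members = n,
         loss_percent = as.integer(round_half_away(100 * k / n)))
}
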