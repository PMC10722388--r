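#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a module-loss summary
#'
#' @param x A `module_loss_summary` from [module_loss()].
#' @param ... Unused.
#' @return `tidy()`: the per-module tibble (`module`, `n_members`,
#'   `n_lost`, `loss_percent`, `outlier`); `glance()`: a one-row tibble
#'   with `n_modules`, `mean_percent`, `sd_percent`, `lower_3sd`,
#'   `upper_3sd`, `n_outliers`, `nonredundant_union`.
#' @exportS3Method generics::tidy
tidy.module_loss_summary <- function(x, ...) x$modules

#' @rdname tidy.module_loss_summary
#' @exportS3Method generics::glance
glance.module_loss_summary <- function(x, ...) {
  tibble(
    n_modules = nrow(x$modules),
    mean_percent = x$mean_percent,
    sd_percent = x$sd_percent,
    lower_3sd = x$lower_3sd,
    upper_3sd = x$upper_3sd,
    n_outliers = sum(x$modules$outlier),
    nonredundant_union = x$nonredundant_union
  )
}

#' Tidy a paralogue cluster
#'
#' @param x A `paralog_cluster` from [build_phylogram()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble of pairwise identities (`seq_a`,
#'   `seq_b`, `identity`, `same_cluster`) over unordered pairs;
#'   `glance()`: one row with `n_sequences`, `n_clusters`,
#'   `within_identity`.
#' @exportS3Method generics::tidy
tidy.paralog_cluster <- function(x, ...) {
  nm <- rownames(x$identity)
  pairs <- which(upper.tri(x$identity), arr.ind = TRUE)
  tibble(
    seq_a = nm[pairs[, 1]],
    seq_b = nm[pairs[, 2]],
    identity = x$identity[pairs],
    same_cluster = x$clusters[nm[pairs[, 1]]] == x$clusters[nm[pairs[, 2]]]
  )
}

#' @rdname tidy.paralog_cluster
#' @exportS3Method generics::glance
glance.paralog_cluster <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$identity),
    n_clusters = length(unique(x$clusters)),
    within_identity = x$within_identity
  )
}
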