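aa_unit_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(AA20, "B", "J", "O", "U", "X", "Z")
      m <<- matrix(0L, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(m) <<- 1L
    }
    m
  }
})

#' Percent identity of two amino-acid sequences
#'
#' Global (Needleman-Wunsch) alignment with unit scoring — match +1,
#' mismatch 0, linear gap -1 — and identity defined as
#' `100 * matches / alignment columns`, gaps included in the denominator.
#' This fixes one auditable definition of "approximate percent identity".
#'
#' @param a,b Nonempty amino-acid strings.
#' @return Percent identity in `[0, 100]`; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 90
#' pairwise_identity("A", "AA")                   # 50
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be nonempty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_unit_matrix(), gapOpening = 0, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Pairwise percent-identity matrix for a set of sequences
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @return Symmetric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
identity_matrix <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("'seqs' must have unique names")
  }
  n <- length(seqs)
  m <- diag(100, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' Detect per-species gene duplications
#'
#' Summarises paralog counts per gene and flags genes duplicated in
#' Neoaves: the flag is set when the median Neoave species carries at
#' least two paralogs of the gene.
#'
#' @param hits A hit-table tibble with `paralog_index` populated.
#' @return A tibble with one row per gene: `gene`,
#'   `median_neoave_paralogs`, `max_paralogs`, `duplicated_in_neoaves`.
#' @export
detect_duplications <- function(hits) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) {
    return(tibble(gene = character(), median_neoave_paralogs = double(),
                  max_paralogs = integer(), duplicated_in_neoaves = logical()))
  }
  per_species <- hits |>
    dplyr::filter(!is.na(.data$hit_length)) |>
    dplyr::group_by(.data$gene, .data$species, .data$clade) |>
    dplyr::summarise(n_paralogs = dplyr::n_distinct(.data$paralog_index),
                     .groups = "drop")
  per_species |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      median_neoave_paralogs =
        median(.data$n_paralogs[.data$clade == "neoaves"]),
      max_paralogs = max(.data$n_paralogs),
      .groups = "drop"
    ) |>
    dplyr::mutate(duplicated_in_neoaves =
                    !is.na(.data$median_neoave_paralogs) &
                    .data$median_neoave_paralogs >= 2)
}

#' Build a neighbour-joining phylogram from percent identities
#'
#' Sequences are ordered alphabetically by name and truncated to
#' `max_sequences` (the deterministic "first 100 sequences" rule for
#' figure-style output); pairwise identities are computed with
#' [pairwise_identity()]; the tree is neighbour joining on distances
#' `100 - identity`, with negative branch lengths clamped to zero;
#' clusters are single linkage cut at `cluster_cutoff` percent identity.
#'
#' @param seqs Named character vector of amino-acid sequences (>= 3 after
#'   truncation).
#' @param max_sequences Keep at most this many sequences (>= 3; default
#'   100).
#' @param cluster_cutoff Percent identity for single-linkage clusters
#'   (default 80).
#' @return An object of class `paralog_cluster`: list with `tree`
#'   (an [ape::phylo]), `identity` (percent-identity matrix), `clusters`
#'   (named integer vector partitioning the sequences), and
#'   `within_identity` (mean within-cluster pairwise identity, `NA` when
#'   all clusters are singletons). Write the tree with
#'   [ape::write.tree()].
#' @export
#' @examples
#' seqs <- c(sp1 = "ACDEFGHIKLMNPQRSTVWY", sp2 = "ACDEFGHIKLMNPQRSTVWF",
#'           sp3 = "AYYYFGHIKLMNPQRSYYWY")
#' pc <- build_phylogram(seqs)
#' ape::write.tree(pc$tree)
build_phylogram <- function(seqs, max_sequences = 100L, cluster_cutoff = 80) {
  if (!is.numeric(max_sequences) || max_sequences < 3) {
    abort("'max_sequences' must be >= 3")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("'seqs' must have unique names")
  }
  seqs <- seqs[order(names(seqs))]
  seqs <- utils::head(seqs, max_sequences)
  if (length(seqs) < 3) {
    abort("need at least 3 sequences; use pairwise_identity() for fewer")
  }
  idm <- identity_matrix(seqs)
  d <- as.dist(100 - idm)
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  cl <- cutree(hclust(d, method = "single"), h = 100 - cluster_cutoff)
  within <- within_cluster_identity(idm, cl)
  structure(list(tree = tree, identity = idm, clusters = cl,
                 within_identity = within),
            class = "paralog_cluster")
}

within_cluster_identity <- function(idm, clusters) {
  vals <- unlist(lapply(split(names(clusters), clusters), function(members) {
    if (length(members) < 2) return(NULL)
    sub <- idm[members, members, drop = FALSE]
    sub[upper.tri(sub)]
  }))
  if (is.null(vals)) NA_real_ else mean(vals)
}

#' @export
print.paralog_cluster <- function(x, ...) {
  cat(sprintf("Paralogue cluster: %d sequences, %d cluster(s)\n",
              nrow(x$identity), length(unique(x$clusters))))
  if (!is.na(x$within_identity)) {
    cat(sprintf("  mean within-cluster identity %.1f%%\n", x$within_identity))
  }
  cat("  tree:", ape::write.tree(x$tree), "\n")
  invisible(x)
}
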