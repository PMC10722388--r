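# Independent oracles and fixture builders shared across tests.

# Literal transliteration of the clade-level purge rule, evaluated directly
# on per-species status vectors (independent of the table pipeline).
oracle_clade_call <- function(neo, out, maj = 0.70, out_min = 0.50) {
  lost_frac <- mean(neo != "present")
  out_pres <- if (length(out) == 0) NA_real_ else mean(out == "present")
  found <- any(c(neo, out) != "absent")
  if (!found) return("purged")
  if (!is.na(out_pres) && out_pres >= out_min && lost_frac > maj) return("purged")
  if (lost_frac <= maj) return("retained")
  "ambiguous"
}

# Status tibble for one gene from explicit per-species status vectors.
status_table <- function(neo, out, gene = "g1") {
  n <- length(neo); m <- length(out)
  tibble::tibble(
    species = c(sprintf("n%02d", seq_len(n)), sprintf("o%02d", seq_len(m))),
    clade = c(rep("neoaves", n), rep(c("galloanserae", "palaeognathae"),
                                     length.out = m)),
    gene = gene,
    status = factor(c(neo, out), levels = c("present", "truncated", "absent"))
  )
}

empty_spans <- function() {
  matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

make_catalog <- function(symbols, ref_length, tm = NULL) {
  tibble::tibble(
    symbol = symbols,
    ref_length = as.integer(rep_len(ref_length, length(symbols))),
    tm_spans = if (is.null(tm)) rep(list(empty_spans()), length(symbols))
               else rep(list(tm), length(symbols))
  )
}

# Realize an additive distance matrix as gap-free sequences: every edge of
# `tree` (a rooted ape::phylo with integer branch lengths) gets its own
# disjoint set of sites, mutated in all tips descending from that edge, so
# pairwise sequence differences equal patristic distances exactly.
seqs_from_tree <- function(tree, total_length = 200L) {
  stopifnot(sum(tree$edge.length) <= total_length)
  ntip <- length(tree$tip.label)
  base <- matrix("A", nrow = ntip, ncol = total_length,
                 dimnames = list(tree$tip.label, NULL))
  site <- 1L
  for (e in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[e]
    if (len == 0) next
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) child else {
      unlist(phangorn::Descendants(tree, child, "tips"))
    }
    base[tips, site:(site + len - 1L)] <- "C"
    site <- site + len
  }
  apply(base, 1, paste, collapse = "")
}

# Brute-force minimum-evolution tree: enumerate every unrooted topology,
# fit OLS branch lengths, return the topology with the smallest tree length.
brute_force_me <- function(dm) {
  labels <- attr(dm, "Labels")
  trees <- phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
  fits <- lapply(trees, function(tr) phangorn::nnls.tree(dm, tr, method = "unrooted",
                                                         trace = 0))
  lens <- vapply(fits, function(tr) sum(tr$edge.length), 0)
  fits[[which.min(lens)]]
}
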