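AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

## Evaluate `expr` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("'", field, "' must be a single probability in [0, 1]"))
  }
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(paste0("'", field, "' must be an integer >= ", min))
  }
}

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

## Per-site substitution at `rate`; replacement drawn from the 19 other
## residues, so expected identity to the input is exactly 1 - rate.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a two-clade gene retention/loss/duplication panel
#'
#' Forward simulator of the species x gene observations produced by a
#' comparative protein screen over a focal clade (Neoaves) and extant-Aves
#' outgroup species. Each Neoave species x gene receives exactly one event:
#' `lose` (no-hit row), `truncate` (a C-terminal fragment whose retained
#' fraction is drawn uniformly from `trunc_range`; truncation is modeled as
#' N-terminal loss), `duplicate` (`dup_copies` full-length paralogs whose
#' pairwise identity is near `paralog_identity`), or `retain` (one
#' full-length hit). Outgroup species always retain the full-length gene,
#' providing the presence reference the clade caller needs. In addition to
#' the per-species event probabilities, `p_gene_loss` draws clade-wide
#' losses per gene (absent in every Neoave species), the regime a purge
#' screen is designed to detect.
#'
#' Event draws use one stream per species, derived from `seed`, so earlier
#' species' draws are unchanged when the panel grows. Gene-level quantities
#' (reference lengths and sequences, clade-wide losses, paralog ancestor
#' sequences) are drawn once from the master seed.
#'
#' @param n_neoaves,n_outgroup,n_genes Panel dimensions (integers >= 1).
#' @param p_loss Per-species gene loss probability in Neoaves.
#' @param p_trunc Per-species truncation probability (applied to genes not
#'   lost in that species).
#' @param trunc_range Length-2 numeric, the retained-fraction range
#'   `(low, high)` with `0 < low < high < 1`.
#' @param p_dup Per-species duplication probability (applied to genes
#'   neither lost nor truncated).
#' @param dup_copies Number of paralogs a duplication produces (>= 2).
#' @param paralog_identity Expected percent identity between distinct
#'   paralogs of a gene (0-100).
#' @param species_divergence Per-site substitution rate separating each
#'   species' copy from the gene (or paralog) ancestor sequence; gives the
#'   within-paralog cluster divergence.
#' @param p_gene_loss Probability that a gene is lost clade-wide in
#'   Neoaves.
#' @param ref_length_range Range reference protein lengths are drawn from.
#' @param sequences If `TRUE`, amino-acid sequences are attached to every
#'   hit row; slower for large panels.
#' @param seed Integer RNG seed; identical configuration and seed give
#'   byte-identical output.
#' @return A list of class `purge_sim` with elements `hits` (a hit-table
#'   tibble, see [read_hits()]), `truth` (per species x gene event log with
#'   columns `species`, `clade`, `gene`, `event`, `frac`, `k`), and
#'   `catalog` (reference tibble as from [read_catalog()]).
#' @export
#' @examples
#' sim <- simulate_panel(n_neoaves = 6, n_outgroup = 3, n_genes = 10,
#'                       p_loss = 0.3, seed = 1)
#' head(sim$hits)
simulate_panel <- function(n_neoaves,
                           n_outgroup,
                           n_genes,
                           p_loss = 0,
                           p_trunc = 0,
                           trunc_range = c(0.10, 0.65),
                           p_dup = 0,
                           dup_copies = 2L,
                           paralog_identity = 70,
                           species_divergence = 0.02,
                           p_gene_loss = 0,
                           ref_length_range = c(200L, 800L),
                           sequences = TRUE,
                           seed = 1L) {
  check_count(n_neoaves, "n_neoaves"); check_count(n_outgroup, "n_outgroup")
  check_count(n_genes, "n_genes"); check_count(dup_copies, "dup_copies", min = 2L)
  check_prob(p_loss, "p_loss"); check_prob(p_trunc, "p_trunc")
  check_prob(p_dup, "p_dup"); check_prob(p_gene_loss, "p_gene_loss")
  check_prob(species_divergence, "species_divergence")
  if (!is.numeric(trunc_range) || length(trunc_range) != 2 ||
      trunc_range[1] <= 0 || trunc_range[2] >= 1 || trunc_range[1] >= trunc_range[2]) {
    abort("'trunc_range' must be (low, high) with 0 < low < high < 1")
  }
  if (!is.numeric(paralog_identity) || paralog_identity < 0 || paralog_identity > 100) {
    abort("'paralog_identity' must be a percent in [0, 100]")
  }
  check_count(seed, "seed", min = 0L)

  genes <- sprintf("G%04d", seq_len(n_genes))
  species <- c(sprintf("neoave_%03d", seq_len(n_neoaves)),
               sprintf("outgroup_%03d", seq_len(n_outgroup)))
  clade <- c(rep("neoaves", n_neoaves),
             rep(OUTGROUP_CLADES, length.out = n_outgroup))

  ## gene-level draws under the master seed
  gene_level <- with_seed(seed, {
    len <- sample(seq(ref_length_range[1], ref_length_range[2]), n_genes, replace = TRUE)
    refs <- if (sequences) vapply(len, rand_aa, "") else rep(NA_character_, n_genes)
    lost <- stats::runif(n_genes) < p_gene_loss
    anc <- if (sequences && p_dup > 0) {
      sub_rate <- 1 - paralog_identity / 100
      lapply(seq_len(n_genes), function(g) {
        c(refs[g], vapply(seq_len(dup_copies - 1L),
                          function(j) mutate_seq(refs[g], sub_rate), ""))
      })
    } else NULL
    list(len = len, refs = refs, lost = lost, anc = anc)
  })
  ref_len <- gene_level$len

  sim_species <- function(i) {
    sp <- species[i]
    is_neo <- clade[i] == "neoaves"
    with_seed((seed + 7919L * i) %% .Machine$integer.max, {
      if (is_neo) {
        u1 <- stats::runif(n_genes); u2 <- stats::runif(n_genes); u3 <- stats::runif(n_genes)
        event <- ifelse(gene_level$lost | u1 < p_loss, "lose",
                 ifelse(u2 < p_trunc, "truncate",
                 ifelse(u3 < p_dup, "duplicate", "retain")))
        frac <- stats::runif(n_genes, trunc_range[1], trunc_range[2])
      } else {
        event <- rep("retain", n_genes)
        frac <- rep(NA_real_, n_genes)
      }
      frac[event != "truncate"] <- NA_real_
      k <- ifelse(event == "duplicate", dup_copies, NA_integer_)

      n_par <- ifelse(event == "duplicate", dup_copies, 1L)
      idx <- rep(seq_len(n_genes), n_par)
      paralog_index <- unlist(lapply(n_par, seq_len), use.names = FALSE)
      ev <- event[idx]
      hit_length <- ifelse(ev == "lose", NA_integer_,
                    ifelse(ev == "truncate",
                           as.integer(round(frac[idx] * ref_len[idx])),
                           ref_len[idx]))
      seq_col <- rep(NA_character_, length(idx))
      if (sequences) {
        for (r in which(ev != "lose")) {
          g <- idx[r]
          base <- if (ev[r] == "duplicate") gene_level$anc[[g]][paralog_index[r]]
                  else gene_level$refs[g]
          if (ev[r] == "truncate") {
            base <- substr(base, gene_level$len[g] - hit_length[r] + 1L, gene_level$len[g])
          }
          seq_col[r] <- mutate_seq(base, species_divergence)
        }
      }
      list(
        hits = tibble(species = sp, clade = clade[i], gene = genes[idx],
                      hit_length = hit_length, paralog_index = paralog_index,
                      sequence = seq_col),
        truth = tibble(species = sp, clade = clade[i], gene = genes,
                       event = event, frac = frac, k = k)
      )
    })
  }

  parts <- lapply(seq_along(species), sim_species)
  hits <- dplyr::bind_rows(lapply(parts, `[[`, "hits"))
  if (!sequences) hits$sequence <- NULL
  truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  catalog <- tibble(
    symbol = genes, ref_length = as.integer(ref_len),
    tm_spans = rep(list(matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("start", "end")))), n_genes)
  )
  structure(list(hits = hits, truth = truth, catalog = catalog), class = "purge_sim")
}

#' Simulate a replicated KO/WT metabolite intensity table
#'
#' Generates a long-format intensity table for two genotypes with
#' multiplicative log-normal replicate noise and known per-metabolite
#' fold changes (KO relative to WT), the layout of an LC-MS/MS knockout
#' screen with `n_replicates` biological replicates per genotype.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_replicates Replicates per genotype (>= 2; default 6).
#' @param fold_change True KO/WT fold change(s), recycled to
#'   `n_metabolites`; must be > 0.
#' @param sigma Log-normal noise standard deviation (on the natural-log
#'   scale); `0` gives noiseless intensities.
#' @param baseline WT mean intensity (arbitrary units).
#' @param seed Integer RNG seed.
#' @return A list of class `metab_sim` with `table` (tibble: `metabolite`,
#'   `genotype`, `replicate`, `intensity`) and `truth` (tibble:
#'   `metabolite`, `fold_change`).
#' @export
#' @examples
#' sim <- simulate_metab(n_metabolites = 2, fold_change = c(4, 0.125),
#'                       sigma = 0, seed = 1)
#' ko_wt_ratio(sim$table)
simulate_metab <- function(n_metabolites,
                           n_replicates = 6L,
                           fold_change = 1,
                           sigma = 0.25,
                           baseline = 1e6,
                           seed = 1L) {
  check_count(n_metabolites, "n_metabolites")
  check_count(n_replicates, "n_replicates", min = 2L)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    abort("'sigma' must be a single number >= 0")
  }
  if (!is.numeric(fold_change) || any(is.na(fold_change)) || any(fold_change <= 0)) {
    abort("'fold_change' must be positive")
  }
  if (!is.numeric(baseline) || baseline <= 0) abort("'baseline' must be > 0")
  check_count(seed, "seed", min = 0L)

  fold <- rep_len(fold_change, n_metabolites)
  mets <- sprintf("M%03d", seq_len(n_metabolites))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      metabolite = mets,
      genotype = c("WT", "KO"),
      replicate = seq_len(n_replicates)
    )
    mu <- baseline * ifelse(grid$genotype == "KO",
                            fold[match(grid$metabolite, mets)], 1)
    grid$intensity <- mu * exp(stats::rnorm(nrow(grid), 0, sigma))
    list(table = grid, truth = tibble(metabolite = mets, fold_change = fold)) |>
      structure(class = "metab_sim")
  })
}
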