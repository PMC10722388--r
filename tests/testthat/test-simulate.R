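test_that("invalid simulator configurations are rejected naming the field", {
  expect_error(simulate_panel(0, 2, 5), "n_neoaves")
  expect_error(simulate_panel(2, 2, 5, p_loss = 1.2), "p_loss")
  expect_error(simulate_panel(2, 2, 5, p_trunc = -0.1), "p_trunc")
  expect_error(simulate_panel(2, 2, 5, trunc_range = c(0.6, 0.4)), "trunc_range")
  expect_error(simulate_panel(2, 2, 5, dup_copies = 1), "dup_copies")
  expect_error(simulate_metab(3, n_replicates = 1), "n_replicates")
  expect_error(simulate_metab(3, sigma = -1), "sigma")
  expect_error(simulate_metab(3, fold_change = 0), "fold_change")
})

test_that("identical configuration and seed give byte-identical output", {
  a <- simulate_panel(5, 3, 8, p_loss = 0.3, p_trunc = 0.2, p_dup = 0.2, seed = 11)
  b <- simulate_panel(5, 3, 8, p_loss = 0.3, p_trunc = 0.2, p_dup = 0.2, seed = 11)
  expect_identical(a, b)
  c <- simulate_panel(5, 3, 8, p_loss = 0.3, p_trunc = 0.2, p_dup = 0.2, seed = 12)
  expect_false(identical(a$hits, c$hits))
  m1 <- simulate_metab(4, sigma = 0.3, seed = 7)
  m2 <- simulate_metab(4, sigma = 0.3, seed = 7)
  expect_identical(m1, m2)
})

test_that("per-species RNG streams survive panel growth", {
  small <- simulate_panel(5, 2, 10, p_loss = 0.4, p_trunc = 0.3, seed = 9)
  big <- simulate_panel(8, 2, 10, p_loss = 0.4, p_trunc = 0.3, seed = 9)
  neo5 <- function(x) dplyr::filter(x, species %in% sprintf("neoave_%03d", 1:5))
  expect_identical(neo5(small$truth), neo5(big$truth))
})

test_that("event-free panels classify present everywhere and forced loss purges every gene", {
  quiet <- simulate_panel(6, 3, 10, p_loss = 0, p_trunc = 0, p_dup = 0, seed = 1)
  st <- classify_status(quiet$hits, quiet$catalog)
  expect_true(all(st$status == "present"))

  gone <- simulate_panel(10, 4, 10, p_loss = 1, seed = 2)
  calls <- call_purge(classify_status(gone$hits, gone$catalog))
  expect_true(all(calls$call == "purged"))
})

test_that("simulated events carry their configured structure", {
  sim <- simulate_panel(6, 2, 12, p_trunc = 0.5, p_dup = 0.4, dup_copies = 3,
                        trunc_range = c(0.2, 0.5), seed = 21)
  joined <- dplyr::inner_join(sim$hits, sim$truth,
                              by = c("species", "clade", "gene"))
  trunc <- dplyr::filter(joined, event == "truncate")
  ref <- sim$catalog$ref_length[match(trunc$gene, sim$catalog$symbol)]
  expect_identical(trunc$hit_length, as.integer(round(trunc$frac * ref)))
  expect_true(all(trunc$frac >= 0.2 & trunc$frac <= 0.5))

  dup <- dplyr::filter(joined, event == "duplicate")
  counts <- dplyr::count(dup, species, gene)
  expect_true(all(counts$n == 3))
  expect_true(all(dplyr::filter(joined, event == "lose") |>
                    dplyr::pull(hit_length) |> is.na()))
  # exactly one event per species x gene in the truth log
  expect_false(anyDuplicated(sim$truth[c("species", "gene")]) > 0)
})

test_that("paralog sequence divergence tracks the configured identity", {
  sim <- simulate_panel(4, 2, 3, p_dup = 1, dup_copies = 2,
                        paralog_identity = 70, species_divergence = 0, seed = 31)
  seqs <- dplyr::filter(sim$hits, gene == "G0001", clade == "neoaves")
  ids <- vapply(split(seqs$sequence, seqs$species),
                function(s) pairwise_identity(s[1], s[2]), 0)
  expect_true(all(abs(ids - 70) < 10))
})

test_that("per-gene absence frequency converges to p_loss (binomial oracle)", {
  p <- 0.17; n <- 200
  sim <- simulate_panel(n, 2, 40, p_loss = p, sequences = FALSE, seed = 101)
  absent <- sim$truth |>
    dplyr::filter(clade == "neoaves") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(frac = mean(event == "lose"))
  se <- sqrt(p * (1 - p) / n)
  # each gene is a Bin(200, 0.17) draw: essentially all genes sit within
  # 3 SE, and the across-gene mean is sqrt(40) tighter
  expect_lte(sum(abs(absent$frac - p) > 3 * se), 2)
  expect_lt(abs(mean(absent$frac) - p), 3 * se / sqrt(40))
})

test_that("noiseless metabolite tables give exact fold changes", {
  sim <- simulate_metab(3, fold_change = c(4, 1, 0.125), sigma = 0, seed = 1)
  rs <- ko_wt_ratio(sim$table)
  expect_equal(rs$ratio_mean, c(4, 1, 0.125))
  expect_equal(rs$ratio_sd, c(0, 0, 0))
  expect_true(all(sim$table$intensity > 0))
})

test_that("noisy fold changes are recovered on average (Monte-Carlo oracle)", {
  means <- vapply(1:400, function(s) {
    sim <- simulate_metab(1, n_replicates = 6, fold_change = 8, sigma = 0.1,
                          seed = s)
    ko_wt_ratio(sim$table)$ratio_mean
  }, 0)
  expect_lt(abs(mean(means) - 8) / 8, 0.05)
})

test_that("truncated fragments stay below the classifier threshold (closure)", {
  sim <- simulate_panel(8, 3, 15, p_trunc = 0.6, seed = 51)
  st <- classify_status(sim$hits, sim$catalog)
  joined <- dplyr::inner_join(st, sim$truth, by = c("species", "clade", "gene"))
  expect_true(all(joined$status[joined$event == "truncate"] == "truncated"))
  expect_true(all(joined$status[joined$event == "lose"] == "absent"))
  expect_true(all(joined$status[joined$event == "retain"] == "present"))
})
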