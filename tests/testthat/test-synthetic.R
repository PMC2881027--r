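test_that("training sets have the configured sizes and labels", {
  sets <- generate_training_sets(generator_config(seed = 3))
  expect_equal(nrow(sets$A), 30)
  expect_equal(nrow(sets$P), 59)
  expect_true(all(sets$A$truth_label == "A"))
  expect_true(all(sets$P$truth_label == "P"))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$",
                        c(sets$A$sequence, sets$P$sequence))))
})

test_that("generation is deterministic per seed, down to the FASTA bytes", {
  cfg <- tiny_config(seed = 7, divergence = 2)
  s1 <- generate_training_sets(cfg)
  s2 <- generate_training_sets(cfg)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(dplyr::bind_rows(s1), f1)
  write_fasta(dplyr::bind_rows(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(s1, generate_training_sets(tiny_config(seed = 8,
                                                                divergence = 2))))
})

test_that("every generated signal peptide satisfies the n/h/c architecture", {
  cfg <- generator_config(seed = 5, n_A = 25, n_P = 25)
  sets <- generate_training_sets(cfg)
  all_recs <- dplyr::bind_rows(sets)
  k <- all_recs$sp_truth
  # total SP length within the configured region ranges
  expect_true(all(k >= 2 + 7 + 3 & k <= 6 + 17 + 6))
  expect_true(all(k < nchar(all_recs$sequence)))
  # A-x-A cleavage box
  expect_true(all(substr(all_recs$sequence, k - 2, k - 2) == "A"))
  expect_true(all(substr(all_recs$sequence, k, k) == "A"))
  # a hydrophobic h-region is recoverable from every SP
  ann <- annotate_signal_peptides(all_recs)
  expect_equal(nrow(ann), nrow(all_recs))
  expect_true(all(ann$h_end - ann$h_start + 1 >= 6))
})

test_that("divergence zero is an exact compositional null", {
  cfg <- generator_config(seed = 2, n_A = 40, n_P = 40, divergence = 0,
                          length_range = c(100, 200))
  sets <- generate_training_sets(cfg)
  fa <- composition_matrix(sets$A, region = "mature", order = 2)
  fp <- composition_matrix(sets$P, region = "mature", order = 2)
  # per-feature two-sample tests should look uniform under the null:
  # the rejection fraction at alpha = 0.05 stays near 0.05
  pvals <- purrr::map_dbl(names(fa)[-1], function(f) {
    a <- fa[[f]]; p <- fp[[f]]
    if (stats::sd(c(a, p)) == 0) return(NA_real_)
    stats::t.test(a, p)$p.value
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 300)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("class separation of dipeptide composition grows with divergence", {
  dist_at <- function(delta, seed) {
    cfg <- generator_config(seed = seed, n_A = 15, n_P = 15,
                            divergence = delta, length_range = c(80, 150))
    sets <- generate_training_sets(cfg)
    fa <- colMeans(composition_matrix(sets$A, region = "mature", order = 2)[, -1])
    fp <- colMeans(composition_matrix(sets$P, region = "mature", order = 2)[, -1])
    sqrt(sum((fa - fp)^2))
  }
  deltas <- c(0, 1, 2, 3)
  d_mean <- purrr::map_dbl(deltas, function(d) {
    mean(purrr::map_dbl(1:3, function(s) dist_at(d, s)))
  })
  expect_true(all(diff(d_mean) > 0))
  # and the A class is the more hydrophobic one for delta > 0
  sets <- generate_training_sets(generator_config(seed = 9, divergence = 2))
  expect_gt(mean(purrr::map_dbl(mature_of(sets$A), gravy)),
            mean(purrr::map_dbl(mature_of(sets$P), gravy)))
})

test_that("the synthetic proteome covers all four subcellular categories", {
  cfg <- generator_config(seed = 4, n_A = 5, n_P = 5, n_tm = 6, n_cyt = 5)
  pro <- generate_proteome(cfg)
  expect_equal(nrow(pro), 21)
  expect_setequal(unique(pro$truth_label), c("A", "P", "TM", "CYT"))
  # SP-bearing records all carry the A-x-A box at the true cleavage site
  sp <- pro[!is.na(pro$sp_truth), ]
  expect_true(all(substr(sp$sequence, sp$sp_truth - 2, sp$sp_truth - 2) == "A"))
  expect_true(all(substr(sp$sequence, sp$sp_truth, sp$sp_truth) == "A"))
  # membrane proteins come both with and without signal peptides
  tm <- pro[pro$truth_label == "TM", ]
  expect_true(any(is.na(tm$sp_truth)) && any(!is.na(tm$sp_truth)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(divergence = -1), "nonnegative")
  expect_error(generator_config(n_A = -3), "nonnegative")
  expect_error(generator_config(length_range = c(200, 100)), "length_range")
  expect_error(generator_config(sp_h_len = c(3, 5)), "sp_h_len")
})

test_that("simulated predictor votes follow the truth at zero noise", {
  pro <- generate_proteome(tiny_config(seed = 6))
  votes <- simulate_predictor_votes(pro, seed = 6)
  expect_equal(nrow(votes), nrow(pro) * 15)
  calls <- majority_vote(votes, n_predictors = 15)
  merged <- dplyr::left_join(pro, calls, by = "id")
  expect_equal(merged$sp_call, !is.na(merged$sp_truth))
  with_sp <- merged[!is.na(merged$sp_truth), ]
  expect_equal(with_sp$cleavage, with_sp$sp_truth)
})
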