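make_votes <- function(n_pos, n_total, id = "prot1", cleavage = 20L) {
  tibble::tibble(
    protein_id = id,
    predictor = sprintf("pred_%02d", seq_len(n_total)),
    call = seq_len(n_total) <= n_pos,
    cleavage_pos = ifelse(seq_len(n_total) <= n_pos, cleavage, NA_integer_)
  )
}

test_that("majority vote requires a strict majority of the panel", {
  expect_true(majority_vote(make_votes(8, 15), 15)$sp_call)
  expect_false(majority_vote(make_votes(7, 15), 15)$sp_call)
  # even panel, exact half: negative
  expect_false(majority_vote(make_votes(2, 4), 4)$sp_call)
  # missing rows count as negatives
  v <- make_votes(8, 15)[1:10, ]
  expect_true(majority_vote(v, 15)$sp_call)
  expect_false(majority_vote(v[1:7, ], 15)$sp_call)
  expect_error(majority_vote(make_votes(1, 1), 0), "n_predictors")
  expect_error(majority_vote(dplyr::bind_rows(make_votes(2, 3),
                                              make_votes(1, 1)), 3),
               "duplicate")
})

test_that("adding a positive vote never flips a positive protein negative", {
  set.seed(5)
  for (i in 1:20) {
    n_pos <- sample(0:14, 1)
    v <- make_votes(n_pos, 15)
    before <- majority_vote(v, 15)$sp_call
    v$call[n_pos + 1] <- TRUE
    after <- majority_vote(v, 15)$sp_call
    expect_true(!before || after)
  }
})

test_that("consensus cleavage is the floored median of positive callers", {
  v <- make_votes(9, 15)
  v$cleavage_pos[v$call] <- c(18L, 19L, 20L, 20L, 20L, 21L, 22L, 23L, 24L)
  expect_equal(majority_vote(v, 15)$cleavage, 20L)
  # even count of reported positions: floor of the midpoint
  v2 <- make_votes(8, 15)
  v2$cleavage_pos[v2$call] <- c(18L, 19L, 20L, 21L, 22L, 23L, 24L, 25L)
  expect_equal(majority_vote(v2, 15)$cleavage, 21L)
})

test_that("region parsing finds the hydrophobic core as specified", {
  seq <- paste0("M", "KK", "LLLLLLLLLL", "SVAQA")  # k = 18
  ann <- parse_regions(seq, k = 18)
  expect_equal(ann$n_start, 1); expect_equal(ann$n_end, 3)
  expect_equal(ann$h_start, 4); expect_equal(ann$h_end, 13)
  expect_equal(ann$c_start, 14); expect_equal(ann$c_end, 18)
  # idempotent
  expect_identical(ann, parse_regions(seq, k = 18))
  # hydrophilic stretch: no h-region
  expect_error(parse_regions(strrep("D", 40), k = 15),
               class = "proteosort_no_h_region")
  expect_error(parse_regions(seq, k = 2), "cleavage index")
})

test_that("region partition tiles 1..k exactly on generated signal peptides", {
  sets <- generate_training_sets(tiny_config(seed = 12))
  ann <- annotate_signal_peptides(dplyr::bind_rows(sets))
  expect_equal(ann$n_start, rep(1L, nrow(ann)))
  expect_equal(ann$h_start, ann$n_end + 1L)
  expect_equal(ann$c_start, ann$h_end + 1L)
  expect_equal(ann$c_end, ann$k)
})

test_that("segmental alignments join back into the original signal peptides", {
  sets <- generate_training_sets(tiny_config(seed = 13))
  recs <- dplyr::bind_rows(sets)
  ann <- annotate_signal_peptides(recs)
  anchors <- c("n_terminus", "h_start", "c_start", "cleavage_site")
  aligned <- lapply(anchors, function(a) segmental_align(ann, a))
  joined <- do.call(cbind, aligned)
  rebuilt <- apply(joined, 1, function(row) paste(row[row != "-"], collapse = ""))
  expect_equal(unname(rebuilt), substr(ann$sequence, 1, ann$k))
  # anchor columns: cleavage-site segment is the fixed-width A-x-A box
  box <- aligned[[4]]
  expect_equal(ncol(box), 3)
  expect_equal(colnames(box), c("-3", "-2", "-1"))
  expect_true(all(box[, "-1"] == "A"))
  expect_true(all(box[, "-3"] == "A"))
})

test_that("single-sequence alignment is the segment itself", {
  ann <- annotate_signal_peptides(
    tibble::tibble(id = "s1", sequence = "MKKLLLLLLLLSVAQAWWWW", cleavage = 16L))
  h <- segmental_align(ann, "h_start")
  expect_equal(paste(h[1, ], collapse = ""),
               substr("MKKLLLLLLLLSVAQA", ann$h_start, ann$h_end))
})

test_that("position frequency matrices are gap-excluded probability columns", {
  aln <- matrix(c("A", "A", "A",
                  "A", "A", "G",
                  "A", "G", "-"), nrow = 3, byrow = TRUE)
  pfm <- position_frequency_matrix(aln)
  expect_equal(unname(pfm["A", 1]), 1)
  expect_equal(unname(pfm["A", 3]), 0.5)
  expect_equal(unname(pfm["G", 3]), 0.5)
  expect_true(all(abs(colSums(pfm) - 1) < 1e-12))
  all_gap <- matrix(c("A", "-", "A", "-"), nrow = 2, byrow = TRUE)
  expect_equal(sum(position_frequency_matrix(all_gap)[, 2]), 0)
})

test_that("h-region phenylalanine counts average correctly", {
  ann <- tibble::tibble(id = c("a", "b"),
                        sequence = c("MFFFLLLAAA", "MFLLLLLAAA"),
                        h_start = c(2L, 2L), h_end = c(7L, 7L))
  expect_equal(h_region_phe_count(ann[1, ]), 3)
  expect_equal(h_region_phe_count(ann), 2)
  no_f <- tibble::tibble(id = "c", sequence = "MLLLLLLAAA",
                         h_start = 2L, h_end = 7L)
  expect_equal(h_region_phe_count(no_f), 0)
})

test_that("the Tat surrogate requires a placed RR motif with hydrophobic follow-up", {
  expect_true(tat_scan(paste0("MSRRQFLKG", strrep("L", 12), "AGDD")))
  expect_false(tat_scan(paste0("MSKQFLKG", strrep("L", 12), "AGDD")))  # no RR
  # RR too deep in the sequence
  expect_false(tat_scan(paste0(strrep("G", 58), "SRR", strrep("L", 15))))
  # RR without a downstream hydrophobic stretch
  expect_false(tat_scan("MSRRQDDDDDDDDDDDDDDDDDDD"))
})

test_that("the TMH surrogate finds hydrophobic windows greedily", {
  one <- tmh_scan(strrep("L", 20))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1, 20))
  expect_equal(nrow(tmh_scan(strrep("K", 40))), 0)
  two <- tmh_scan(paste0("KKKK", strrep("I", 19), "DDDD", strrep("I", 19), "KKKK"))
  expect_equal(nrow(two), 2)
})

test_that("nearly all generated SP proteins survive a noisy majority vote", {
  pro <- generate_proteome(generator_config(seed = 17, n_A = 20, n_P = 20,
                                            n_tm = 0, n_cyt = 0))
  votes <- simulate_predictor_votes(pro, sensitivity = 0.75, cleavage_sd = 1,
                                    seed = 17)
  calls <- majority_vote(votes, 15)
  expect_gte(mean(calls$sp_call), 0.95)
})
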