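# Shared fixtures: small generator configurations and a naive composition
# oracle used to cross-check the vectorised feature code.

tiny_config <- function(seed = 1, divergence = 1.1, ...) {
  generator_config(seed = seed, n_A = 10, n_P = 16, n_tm = 6, n_cyt = 8,
                   length_range = c(60, 120), divergence = divergence, ...)
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Independent oracle: composition by explicit double-loop enumeration.
naive_composition <- function(seq, order) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  if (order == 1) {
    feats <- AA_ALPHABET
  } else {
    feats <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  }
  counts <- stats::setNames(numeric(length(feats)), feats)
  for (i in seq_len(len - order + 1)) {
    key <- paste(chars[i:(i + order - 1)], collapse = "")
    counts[key] <- counts[key] + 1
  }
  counts / len
}

# Mature part of generated records (sequence after the signal peptide).
mature_of <- function(records) {
  substr(records$sequence, records$sp_truth + 1, nchar(records$sequence))
}

# Expected partition set of each synthetic proteome record, from its
# generator truth.
truth_partition_set <- function(proteome) {
  dplyr::case_when(
    proteome$truth_label %in% c("A", "P") ~ "set1",
    proteome$truth_label == "TM" & !is.na(proteome$sp_truth) ~ "set2",
    proteome$truth_label == "TM" ~ "set3",
    TRUE ~ "set4"
  )
}
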