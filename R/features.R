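# Composition features and physicochemical indices.
#
# All frequencies use the count / L convention (occurrences divided by the
# full sequence length), for dipeptides as well as single residues, so an
# order-2 vector without exclusions sums to (L - 1) / L.

#' Residue and dipeptide composition of a sequence
#'
#' Computes the frequency (occurrences divided by sequence length) of every
#' single residue (`order = 1`, 20 features) or every ordered pair of
#' adjacent residues (`order = 2`, 400 features).
#'
#' Two exclusion modes accommodate sequences whose cysteines and histidines
#' belong to heme c binding motifs and would otherwise dominate the
#' composition signal:
#' \describe{
#'   \item{`"drop_CH"`}{removes every feature whose name contains C or H
#'     from the feature space (18 or 324 features); counts of the remaining
#'     features are unchanged.}
#'   \item{`"mask_CxxCH"`}{masks residues lying inside CxxCH motif matches
#'     before counting (pairs touching a masked position are not counted);
#'     the full feature space is kept.}
#' }
#' The denominator is the full sequence length L in every mode.
#'
#' @param seq Single sequence string over the 20 standard residues.
#' @param order 1 (single residues) or 2 (adjacent residue pairs).
#' @param exclusion_mode One of `"none"`, `"drop_CH"`, `"mask_CxxCH"`.
#' @return A named numeric vector of frequencies with attributes `order`
#'   and `exclusion_mode`.
#' @examples
#' composition("AAAA", order = 1)[["A"]]
#' composition("ACAC", order = 2)[["AC"]]
#' @export
composition <- function(seq, order = 2, exclusion_mode = c("none", "drop_CH", "mask_CxxCH")) {
  exclusion_mode <- match.arg(exclusion_mode)
  if (!order %in% c(1L, 2L)) rlang::abort("`order` must be 1 or 2")
  chars <- aa_chars(seq)
  len <- length(chars)
  if (len < order) {
    rlang::abort(sprintf("sequence of length %d too short for order %d", len, order))
  }

  if (exclusion_mode == "mask_CxxCH") {
    m <- gregexpr("C..CH", paste(chars, collapse = ""))[[1]]
    if (m[1] != -1L) {
      for (s in as.integer(m)) chars[s:(s + 4L)] <- NA_character_
    }
  }

  if (order == 1L) {
    counts <- table(factor(chars, levels = AA_ALPHABET))
    values <- as.numeric(counts) / len
    names(values) <- AA_ALPHABET
  } else {
    pairs <- paste0(chars[-len], chars[-1L])
    pairs <- pairs[!is.na(chars[-len]) & !is.na(chars[-1L])]
    counts <- table(factor(pairs, levels = dipeptide_names()))
    values <- as.numeric(counts) / len
    names(values) <- dipeptide_names()
  }

  if (exclusion_mode == "drop_CH") {
    values <- values[!grepl("[CH]", names(values))]
  }
  structure(values, order = order, exclusion_mode = exclusion_mode)
}

# Extract the region of interest given a cleavage index k (SP = 1..k).
region_sequence <- function(seq, region, cleavage = NA) {
  if (region == "full") return(seq)
  if (is.na(cleavage)) {
    rlang::abort(sprintf("region '%s' requested but cleavage index is missing", region))
  }
  k <- as.integer(cleavage)
  n <- nchar(seq)
  if (k < 1L || k >= n) rlang::abort("cleavage index out of range")
  switch(region,
    sp     = substr(seq, 1L, k),
    mature = substr(seq, k + 1L, n),
    rlang::abort(sprintf("unknown region '%s'", region))
  )
}

#' Composition feature matrix for a set of proteins
#'
#' Featurizes every record of a protein tibble on a chosen region of the
#' sequence. Regions `"sp"` and `"mature"` require a `cleavage` column (or
#' `sp_truth` for synthetic records) giving the 1-based signal peptide end.
#'
#' @param proteins Tibble with columns `id`, `sequence` and, for non-full
#'   regions, `cleavage` or `sp_truth`.
#' @param region `"full"`, `"sp"` or `"mature"`.
#' @inheritParams composition
#' @return A tibble with `id` followed by one column per feature, carrying
#'   attributes `region`, `order`, `exclusion_mode`.
#' @export
composition_matrix <- function(proteins, region = c("full", "sp", "mature"),
                               order = 2, exclusion_mode = "none") {
  region <- match.arg(region)
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  cleavage <- proteins[["cleavage"]] %||% proteins[["sp_truth"]] %||%
    rep(NA_integer_, nrow(proteins))
  feats <- purrr::map2(proteins$sequence, cleavage, function(s, k) {
    composition(region_sequence(s, region, k), order = order,
                exclusion_mode = exclusion_mode)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(id = proteins$id),
    tibble::as_tibble(do.call(rbind, feats))
  )
  attr(out, "region") <- region
  attr(out, "order") <- order
  attr(out, "exclusion_mode") <- exclusion_mode
  out
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues of the sequence.
#'
#' @param seq Single sequence string.
#' @return Dimensionless GRAVY value.
#' @examples
#' gravy("I")  # 4.5, the scale value of isoleucine
#' @export
gravy <- function(seq) {
  mean(KYTE_DOOLITTLE[aa_chars(seq)])
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains (Ikai):
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in
#' mole-percent of the sequence.
#'
#' @param seq Single sequence string.
#' @return Aliphatic index in \[0, 390\].
#' @examples
#' aliphatic_index("AAAA")  # 100
#' @export
aliphatic_index <- function(seq) {
  chars <- aa_chars(seq)
  x <- function(aa) 100 * mean(chars == aa)
  x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L"))
}

#' Physicochemical profile of proteins
#'
#' GRAVY, aliphatic index and the prevalence (fraction of sequence length)
#' of 14 amino-acid classes (ILV, FWY, AILVMFWYC, AGS, ST, GNP, DE, DN, KR,
#' EQ, DENQ, HKR, DENQHKR, DENQHKRST) for each record.
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @return Tibble with one row per protein: `id`, `gravy`,
#'   `aliphatic_index`, then one column per residue class.
#' @export
physchem_profile <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  rows <- purrr::map(proteins$sequence, function(s) {
    chars <- aa_chars(s)
    prev <- purrr::map_dbl(AA_CLASSES, function(cls) mean(chars %in% cls))
    c(gravy = mean(KYTE_DOOLITTLE[chars]),
      aliphatic_index = 100 * mean(chars == "A") +
        290 * mean(chars == "V") + 390 * (mean(chars == "I") + mean(chars == "L")),
      prev)
  })
  dplyr::bind_cols(
    tibble::tibble(id = proteins$id),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

# Global-alignment fractional identity between two sequences:
# matches / alignment columns, Needleman-Wunsch with match = 1,
# mismatch = 0, gap = -1.
pairwise_identity <- function(a, b) {
  sub <- diag(1, length(AA_ALPHABET))
  dimnames(sub) <- list(AA_ALPHABET, AA_ALPHABET)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Remove redundant sequences by pairwise identity
#'
#' Computes global-alignment identity (matches divided by alignment
#' columns) for every pair and greedily removes the shorter member of each
#' pair whose identity exceeds the threshold, until no pair exceeds it.
#' On equal length the later record in input order is removed. The result
#' is deterministic given the input order.
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param identity_threshold Fractional identity above which a pair is
#'   considered redundant (default 0.85).
#' @return The filtered tibble, original row order preserved.
#' @export
redundancy_filter <- function(proteins, identity_threshold = 0.85) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 1)
  n <- nrow(proteins)
  if (n == 1L) return(proteins)
  id_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      id_mat[i, j] <- pairwise_identity(proteins$sequence[i], proteins$sequence[j])
    }
  }
  keep <- rep(TRUE, n)
  lens <- nchar(proteins$sequence)
  repeat {
    offending <- which(id_mat > identity_threshold & outer(keep, keep, "&"),
                       arr.ind = TRUE)
    if (nrow(offending) == 0L) break
    # first offending pair in input order (i, then j)
    ord <- order(offending[, 1L], offending[, 2L])
    i <- offending[ord[1L], 1L]; j <- offending[ord[1L], 2L]
    drop <- if (lens[i] < lens[j]) i else j  # equal length: drop later (j)
    keep[drop] <- FALSE
  }
  proteins[keep, , drop = FALSE]
}
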