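# Signal-peptide analysis: majority-vote combination of external
# predictor calls, n/h/c region parsing, anchored segmental alignments and
# position frequency matrices, and hydropathy-window surrogate scanners
# for twin-arginine (Tat) substrates and transmembrane helices.

#' Combine predictor calls by majority vote
#'
#' A protein is called signal-peptide-positive iff strictly more than half
#' of the predictor panel calls it positive (with 15 predictors the
#' threshold is >= 8). Missing rows count as negative calls; ties on even
#' panels are negative. The consensus cleavage position is the median of
#' the cleavage positions reported by the positive callers, rounded down.
#'
#' @param votes Vote table tibble: `protein_id`, `predictor`, `call`
#'   (logical or 0/1), optional `cleavage_pos`.
#' @param n_predictors Size of the predictor panel (>= 1).
#' @return Tibble: `id`, `n_positive`, `sp_call`, `cleavage` (NA for
#'   negative proteins or when no positive caller reported a position).
#' @export
majority_vote <- function(votes, n_predictors = 15L) {
  if (n_predictors < 1L) rlang::abort("n_predictors must be >= 1")
  stopifnot(all(c("protein_id", "predictor", "call") %in% names(votes)))
  dup <- votes |>
    dplyr::count(.data$protein_id, .data$predictor) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(sprintf("duplicate predictor rows for protein '%s'",
                         dup$protein_id[1]))
  }
  if (!"cleavage_pos" %in% names(votes)) votes$cleavage_pos <- NA_integer_
  votes |>
    dplyr::mutate(call = as.logical(.data$call)) |>
    dplyr::group_by(id = .data$protein_id) |>
    dplyr::summarise(
      n_positive = sum(.data$call),
      sp_call = sum(.data$call) > n_predictors / 2,
      cleavage = {
        pos <- .data$cleavage_pos[.data$call]
        pos <- pos[!is.na(pos)]
        if (sum(.data$call) > n_predictors / 2 && length(pos) > 0) {
          as.integer(floor(stats::median(pos)))
        } else NA_integer_
      },
      .groups = "drop"
    )
}

#' Parse the n/h/c architecture of a signal peptide
#'
#' Locates the hydrophobic h-region as the window of length >= 6 within
#' residues `2..(k-3)` with the highest mean Kyte-Doolittle hydropathy
#' (ties: longer, then leftmost window), requiring mean >= `h_floor`. The
#' n-region is everything before it (at least the initiator residue) and
#' the c-region everything after it up to the cleavage index `k`; the
#' window never encroaches on the last three residues, so the c-region
#' always holds at least the signal-peptidase recognition box (positions
#' -3..-1).
#'
#' @param seq Protein sequence (full-length; the signal peptide is
#'   residues `1..k`).
#' @param k Cleavage index, `4 <= k <= min(nchar(seq), 50)`.
#' @param h_floor Minimum mean hydropathy of the h-region window.
#' @param h_min_len Minimum h-region length.
#' @return One-row tibble: `k`, `n_start`, `n_end`, `h_start`, `h_end`,
#'   `c_start`, `c_end`.
#' @export
parse_regions <- function(seq, k, h_floor = 1.0, h_min_len = 6L) {
  chars <- aa_chars(seq)
  k <- as.integer(k)
  if (k < 4L || k > min(length(chars), 50L)) {
    rlang::abort("cleavage index k must satisfy 4 <= k <= min(length, 50)")
  }
  kd <- KYTE_DOOLITTLE[chars[seq_len(k)]]
  csum <- c(0, cumsum(kd))
  best <- NULL
  if (k - h_min_len < 4L) {
    rlang::abort("no h-region: signal peptide too short for the minimum window",
                 class = "proteosort_no_h_region")
  }
  # h-region constrained to 2..(k-3): the n-region keeps the initiator
  # residue and the c-region keeps at least the 3-residue cleavage box
  for (start in 2:(k - h_min_len - 2L)) {
    for (end in (start + h_min_len - 1L):(k - 3L)) {
      m <- (csum[end + 1L] - csum[start]) / (end - start + 1L)
      if (is.null(best) || m > best$mean + 1e-12 ||
          (abs(m - best$mean) <= 1e-12 && (end - start) > (best$end - best$start))) {
        best <- list(start = start, end = end, mean = m)
      }
    }
  }
  if (is.null(best) || best$mean < h_floor) {
    rlang::abort("no h-region: no hydrophobic window reaches the hydropathy floor",
                 class = "proteosort_no_h_region")
  }
  tibble::tibble(k = k, n_start = 1L, n_end = best$start - 1L,
                 h_start = best$start, h_end = best$end,
                 c_start = best$end + 1L, c_end = k)
}

#' Annotate signal-peptide regions for a set of proteins
#'
#' Applies [parse_regions()] to every record with a cleavage index,
#' returning one row per successfully parsed protein (failures are dropped
#' with a warning naming them).
#'
#' @param proteins Tibble with `id`, `sequence` and `cleavage` (or
#'   `sp_truth`).
#' @inheritParams parse_regions
#' @return Tibble: `id`, `sequence`, `k`, region boundary columns.
#' @export
annotate_signal_peptides <- function(proteins, h_floor = 1.0, h_min_len = 6L) {
  cleavage <- proteins[["cleavage"]] %||% proteins[["sp_truth"]]
  if (is.null(cleavage)) rlang::abort("proteins need a `cleavage` or `sp_truth` column")
  failed <- character(0)
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    if (is.na(cleavage[i])) return(NULL)
    ann <- tryCatch(
      parse_regions(proteins$sequence[i], cleavage[i], h_floor, h_min_len),
      error = function(e) NULL)
    if (is.null(ann)) {
      failed <<- c(failed, proteins$id[i])
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(id = proteins$id[i],
                                    sequence = proteins$sequence[i]), ann)
  })
  if (length(failed) > 0) {
    warning(sprintf("no h-region found for: %s", paste(failed, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

# The four joinable signal-peptide segments of an annotated protein:
# n-region, h-region, the c-region upstream of the cleavage box, and the
# 3-residue cleavage box (positions -3..-1).
sp_segment <- function(ann, anchor) {
  s <- ann$sequence
  switch(anchor,
    n_terminus = substr(s, ann$n_start, ann$n_end),
    h_start = substr(s, ann$h_start, ann$h_end),
    c_start = if (ann$c_end - 3L >= ann$c_start)
      substr(s, ann$c_start, ann$c_end - 3L) else "",
    cleavage_site = substr(s, ann$c_end - 2L, ann$c_end),
    rlang::abort(sprintf("unknown anchor '%s'", anchor))
  )
}

#' Ungapped segmental alignment at one architectural anchor
#'
#' Builds a character matrix of one signal-peptide segment per annotated
#' protein, anchored at one of the four architectural anchors: the
#' N-terminus (n-region), the h-region start, the c-region start (c-region
#' upstream of the cleavage box), or the cleavage site (the 3-residue
#' box at positions -3..-1). Segments are ungapped; ragged ends are padded
#' with the `-` sentinel (on the right for left-anchored segments, on the
#' left for the cleavage-site anchor). Joining the four alignments
#' row-wise and dropping sentinels reconstitutes each signal peptide.
#'
#' @param annotations Output of [annotate_signal_peptides()].
#' @param anchor One of `"n_terminus"`, `"h_start"`, `"c_start"`,
#'   `"cleavage_site"`.
#' @return Character matrix (rows = proteins, named), with attribute
#'   `anchor` and column names giving positions relative to the anchor
#'   (negative positions count back from the cleavage site, which is -1).
#' @export
segmental_align <- function(annotations, anchor = c("n_terminus", "h_start",
                                                    "c_start", "cleavage_site")) {
  anchor <- match.arg(anchor)
  if (nrow(annotations) < 1L) rlang::abort("need at least one annotated sequence")
  segs <- purrr::map_chr(seq_len(nrow(annotations)),
                         function(i) sp_segment(annotations[i, ], anchor))
  width <- max(nchar(segs))
  left_anchored <- anchor != "cleavage_site"
  mat <- t(vapply(segs, function(s) {
    chars <- if (nzchar(s)) strsplit(s, "")[[1]] else character(0)
    pad <- rep("-", width - length(chars))
    if (left_anchored) c(chars, pad) else c(pad, chars)
  }, character(width)))
  if (width == 1L) mat <- matrix(mat, ncol = 1L)  # vapply drops to vector
  rownames(mat) <- annotations$id
  colnames(mat) <- if (left_anchored) as.character(seq_len(width) - 1L)
                   else as.character(seq_len(width) - width - 1L)
  attr(mat, "anchor") <- anchor
  mat
}

#' Position frequency matrix of an alignment
#'
#' Per-column residue fractions with a gap-excluded denominator: each
#' column with at least one residue sums to 1; all-gap columns are zero.
#'
#' @param alignment Character matrix as produced by [segmental_align()]
#'   (`-` as the gap sentinel).
#' @return Numeric matrix, rows = the 20 residues, columns as in the
#'   alignment.
#' @export
position_frequency_matrix <- function(alignment) {
  if (length(alignment) == 0L) rlang::abort("empty alignment")
  pfm <- apply(alignment, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(stats::setNames(rep(0, 20), AA_ALPHABET))
    as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col)
  })
  rownames(pfm) <- AA_ALPHABET
  pfm
}

#' Mean phenylalanine count in h-regions
#'
#' @param annotations Output of [annotate_signal_peptides()].
#' @return Arithmetic mean number of F residues per h-region.
#' @export
h_region_phe_count <- function(annotations) {
  counts <- purrr::map_int(seq_len(nrow(annotations)), function(i) {
    h <- substr(annotations$sequence[i], annotations$h_start[i],
                annotations$h_end[i])
    sum(strsplit(h, "")[[1]] == "F")
  })
  mean(counts)
}

#' Surrogate twin-arginine (Tat) motif scan
#'
#' A simplified stand-in for a dedicated Tat-substrate predictor: positive
#' iff an RR pair starts at positions 2..35, the residue preceding it is
#' polar (S, T, G, N, Q, D, E), and a hydrophobic stretch (>= 10 residues
#' with mean Kyte-Doolittle hydropathy >= 1.0) begins within 6 residues
#' downstream of the pair. Externally computed Tat calls, when available,
#' should be preferred over this surrogate.
#'
#' @param seq Protein sequence.
#' @return Logical.
#' @export
tat_scan <- function(seq) {
  chars <- aa_chars(seq)
  len <- length(chars)
  kd <- KYTE_DOOLITTLE[chars]
  csum <- c(0, cumsum(kd))
  polar <- c("S", "T", "G", "N", "Q", "D", "E")
  rr_starts <- which(chars[-len] == "R" & chars[-1] == "R")
  rr_starts <- rr_starts[rr_starts >= 2L & rr_starts <= 35L]
  for (p in rr_starts) {
    if (!chars[p - 1L] %in% polar) next
    for (s in (p + 2L):min(p + 8L, len - 9L)) {
      if (s < p + 2L) next
      for (l in 10L:min(30L, len - s + 1L)) {
        if ((csum[s + l] - csum[s]) / l >= 1.0) return(TRUE)
      }
    }
  }
  FALSE
}

#' Surrogate transmembrane-helix scan
#'
#' Greedy left-to-right hydropathy-window scan: at the leftmost position
#' where some window of 18-25 residues has mean Kyte-Doolittle hydropathy
#' >= `min_hydropathy`, the longest such window is emitted as a helix and
#' scanning resumes after it. A stand-in for dedicated topology
#' predictors; externally computed TMH calls override it in pipelines.
#'
#' @param seq Protein sequence.
#' @param min_len,max_len Window length bounds (canonical helix span).
#' @param min_hydropathy Mean-hydropathy threshold.
#' @return Tibble of helix intervals: `start`, `end` (1-based inclusive);
#'   zero rows when no helix is found.
#' @export
tmh_scan <- function(seq, min_len = 18L, max_len = 25L, min_hydropathy = 1.6) {
  chars <- aa_chars(seq)
  len <- length(chars)
  kd <- KYTE_DOOLITTLE[chars]
  csum <- c(0, cumsum(kd))
  window_mean <- function(s, l) (csum[s + l] - csum[s]) / l
  out <- list()
  pos <- 1L
  while (pos <= len - min_len + 1L) {
    lens <- min_len:min(max_len, len - pos + 1L)
    ok <- lens[vapply(lens, function(l) window_mean(pos, l) >= min_hydropathy,
                      logical(1))]
    if (length(ok) > 0L) {
      l <- max(ok)
      out[[length(out) + 1L]] <- tibble::tibble(start = pos, end = pos + l - 1L)
      pos <- pos + l
    } else {
      pos <- pos + 1L
    }
  }
  if (length(out) == 0L) tibble::tibble(start = integer(), end = integer())
  else dplyr::bind_rows(out)
}
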