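# In-silico tryptic digestion and cleavage-site validation against
# observed peptide evidence.

#' In-silico tryptic digest
#'
#' Cleaves C-terminal to K or R except when the next residue is proline
#' (the standard trypsin convention). With `missed_cleavages > 0`, merged
#' fragments spanning up to that many internal cleavage sites are also
#' returned.
#'
#' @param seq Protein sequence.
#' @param missed_cleavages Maximum number of missed cleavage sites.
#' @return Tibble: `start`, `end` (1-based inclusive), `peptide`,
#'   `n_missed`, `mass` (monoisotopic, Da, including one water).
#' @examples
#' tryptic_digest("AKRP")$peptide  # "AK", "RP"
#' @export
tryptic_digest <- function(seq, missed_cleavages = 0L) {
  chars <- aa_chars(seq)
  len <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < len & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, len)
  n_frag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:min(missed_cleavages, n_frag - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + m]
      pep <- substr(seq, start, end)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = start, end = end, peptide = pep, n_missed = m,
        mass = sum(MONO_MASS[chars[start:end]]) + WATER_MONO
      )
    }
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$start, .data$n_missed)
}

# Is the boundary after position `pos` a tryptic boundary in `chars`?
# pos = 0 (protein N-terminus) and pos = length (C-terminus) are tryptic.
tryptic_boundary <- function(chars, pos) {
  len <- length(chars)
  if (pos == 0L || pos == len) return(TRUE)
  chars[pos] %in% c("K", "R") && chars[pos + 1L] != "P"
}

#' Validate a predicted cleavage site against peptide evidence
#'
#' Applies the three acceptance criteria for confirming a signal-peptide
#' cleavage site from mass-spectrometric peptide identifications:
#' \enumerate{
#'   \item the protein was identified with at least `min_peptides`
#'     peptides;
#'   \item an observed peptide starts exactly at `k + 1` and is
#'     semi-tryptic with the non-tryptic side at its N-terminus (the
#'     boundary after residue `k` is not a tryptic boundary, while the
#'     peptide's C-terminal boundary is);
#'   \item that peptide is the first detectable one: no in-silico tryptic
#'     peptide lying wholly upstream (ending at or before `k`) has a
#'     monoisotopic mass inside the detectability window.
#' }
#'
#' @param seq Full protein sequence.
#' @param k Predicted cleavage index (signal peptide = `1..k`),
#'   `1 <= k <= max_k`.
#' @param observed Tibble of observed peptides: `sequence`, optional
#'   `start` (1-based; located by exact substring match when absent).
#' @param detect_range Monoisotopic mass window (Da) of detectable
#'   peptides.
#' @param min_peptides Minimum identified peptides per protein.
#' @param max_k Upper bound on the cleavage index considered validatable.
#' @return One-row tibble: `confirmed` plus the per-criterion booleans
#'   `enough_peptides`, `semi_tryptic_at_site`, `first_detectable`, and
#'   `n_observed`.
#' @export
validate_cleavage <- function(seq, k, observed,
                              detect_range = c(600, 4000),
                              min_peptides = 3L, max_k = 50L) {
  chars <- aa_chars(seq)
  len <- length(chars)
  k <- as.integer(k)
  if (k < 1L || k > min(max_k, len - 1L)) {
    rlang::abort(sprintf("cleavage index k must lie in 1..min(%d, length - 1)", max_k))
  }
  stopifnot(is.data.frame(observed), "sequence" %in% names(observed))
  starts <- observed[["start"]]
  obs <- purrr::map2_int(observed$sequence,
                         starts %||% rep(NA_integer_, nrow(observed)),
                         function(pep, st) {
    if (is.na(st)) {
      st <- as.integer(regexpr(pep, seq, fixed = TRUE))
      if (st < 1L) rlang::abort(sprintf("observed peptide '%s' is not a substring", pep))
    } else if (substr(seq, st, st + nchar(pep) - 1L) != pep) {
      rlang::abort(sprintf("observed peptide '%s' does not match position %d", pep, st))
    }
    st
  })
  ends <- obs + nchar(observed$sequence) - 1L

  enough <- nrow(observed) >= min_peptides

  at_site <- which(obs == k + 1L)
  semi <- any(vapply(at_site, function(i) {
    !tryptic_boundary(chars, k) && tryptic_boundary(chars, ends[i])
  }, logical(1)))

  frags <- tryptic_digest(seq, missed_cleavages = 0L)
  upstream_detectable <- frags$end <= k &
    frags$mass >= detect_range[1] & frags$mass <= detect_range[2]
  first_detectable <- !any(upstream_detectable)

  tibble::tibble(
    confirmed = enough && semi && first_detectable,
    enough_peptides = enough,
    semi_tryptic_at_site = semi,
    first_detectable = first_detectable,
    n_observed = nrow(observed)
  )
}
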