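# Proteome partition into the four subcellular sets and the final
# organellar sub-proteome prediction.

#' Surrogate transmembrane-helix calls for a proteome
#'
#' Runs [tmh_scan()] over every protein; for signal-peptide-positive
#' proteins the N-terminal signal peptide (residues `1..k`) is masked
#' before scanning, mirroring a topology prediction constrained to treat
#' the N-terminus as a signal peptide.
#'
#' @param proteome Protein tibble (`id`, `sequence`).
#' @param sp_calls Tibble `id`, `sp_call`, `cleavage` as produced by
#'   [majority_vote()].
#' @param ... Passed to [tmh_scan()].
#' @return Tibble: `id`, `n_tmh`.
#' @export
compute_tmh_calls <- function(proteome, sp_calls, ...) {
  calls <- dplyr::left_join(proteome, sp_calls, by = "id")
  n_tmh <- purrr::map_int(seq_len(nrow(calls)), function(i) {
    s <- calls$sequence[i]
    sp <- isTRUE(calls$sp_call[i])
    k <- calls$cleavage[i]
    if (sp && !is.na(k) && k < nchar(s)) s <- substr(s, k + 1L, nchar(s))
    nrow(tmh_scan(s, ...))
  })
  tibble::tibble(id = proteome$id, n_tmh = n_tmh)
}

#' Partition a proteome into four subcellular sets
#'
#' Combines signal-peptide calls and transmembrane-helix calls into the
#' four-set partition:
#' \describe{
#'   \item{set1}{SP-positive, no TMH in the mature region (translocated
#'     soluble)}
#'   \item{set2}{SP-positive with mature-region TMH (translocated
#'     membrane)}
#'   \item{set3}{SP-negative with TMH (membrane, no SP)}
#'   \item{set4}{SP-negative, no TMH (cytoplasmic soluble)}
#' }
#' Missing `sp_calls` rows count as negative. If `tmh_calls` is `NULL` the
#' surrogate scan of [compute_tmh_calls()] is used.
#'
#' @param proteome Protein tibble (`id`, `sequence`).
#' @param sp_calls Tibble `id`, `sp_call`, optional `cleavage`.
#' @param tmh_calls Optional tibble `id`, `n_tmh` of externally computed
#'   helix counts (computed on the mature region for SP-positive
#'   proteins); overrides the surrogate.
#' @return Tibble: `id`, `sp_call`, `cleavage`, `n_tmh`, `set` (factor
#'   set1-set4), with attribute `set_sizes`.
#' @export
partition_proteome <- function(proteome, sp_calls, tmh_calls = NULL) {
  if (anyDuplicated(proteome$id)) rlang::abort("duplicate protein ids in proteome")
  if (!"cleavage" %in% names(sp_calls)) sp_calls$cleavage <- NA_integer_
  if (is.null(tmh_calls)) tmh_calls <- compute_tmh_calls(proteome, sp_calls)
  out <- proteome |>
    dplyr::select("id") |>
    dplyr::left_join(sp_calls[, c("id", "sp_call", "cleavage")], by = "id") |>
    dplyr::left_join(tmh_calls, by = "id") |>
    dplyr::mutate(
      sp_call = !is.na(.data$sp_call) & .data$sp_call,
      n_tmh = dplyr::coalesce(.data$n_tmh, 0L),
      set = factor(dplyr::case_when(
        .data$sp_call & .data$n_tmh == 0L ~ "set1",
        .data$sp_call & .data$n_tmh > 0L ~ "set2",
        !.data$sp_call & .data$n_tmh > 0L ~ "set3",
        TRUE ~ "set4"
      ), levels = paste0("set", 1:4))
    )
  attr(out, "set_sizes") <- table(out$set)
  out
}

#' Predict the organellar sub-proteome
#'
#' Classifies every translocated or membrane protein (sets 1-3) with the
#' selected forest of a protocol fit: out-of-tree votes for the two P
#' pseudo-classes are pooled and each protein is labelled `organellar`
#' when the A vote exceeds the pooled P vote (ties conservatively to
#' `cell_envelope`). Proteins flagged as type IV secretion substrates are
#' excluded before counting; set4 proteins are labelled
#' `not_translocated`.
#'
#' @param partition Output of [partition_proteome()].
#' @param proteome Protein tibble (`id`, `sequence`, cleavage columns as
#'   needed by the model's feature region).
#' @param model An `rf_protocol` fit; its feature configuration (region,
#'   order, exclusion mode) is reused for the proteome.
#' @param type_iv_ids Character ids of predicted type IV secretion
#'   substrates to exclude.
#' @return Tibble: `id`, `set`, `vote_A`, `vote_P`, `final_label` in
#'   \{organellar, cell_envelope, excluded_typeIV, not_translocated\},
#'   with attribute `summary` (counts and the organellar fraction among
#'   non-excluded translocated/membrane proteins).
#' @export
predict_organellar <- function(partition, proteome, model,
                               type_iv_ids = character(0)) {
  stopifnot(inherits(model, "rf_protocol"))
  cfg <- model$config
  translocated <- partition$id[partition$set != "set4"]
  if (length(translocated) == 0L) rlang::abort("sets 1-3 are empty")
  sub <- proteome[match(translocated, proteome$id), ]
  if (cfg$region == "sp") {
    rlang::abort("sp-region models cannot classify SP-less membrane proteins (set3)")
  }
  if (cfg$region == "mature") {
    # mature region for SP-positive proteins; SP-less proteins are their
    # own mature sequence
    cl <- partition$cleavage[match(translocated, partition$id)]
    sub$cleavage <- cl
    sub$sequence <- ifelse(is.na(cl), sub$sequence,
                           substr(sub$sequence, cl + 1L, nchar(sub$sequence)))
    sub$cleavage <- NA_integer_
  }
  feats <- composition_matrix(sub, region = "full", order = cfg$order,
                              exclusion_mode = cfg$exclusion_mode)
  x <- as.matrix(feats[, -1, drop = FALSE])
  rownames(x) <- feats$id
  votes <- stats::predict(model$forest, newdata = x, type = "vote")
  vote_tbl <- tibble::tibble(
    id = rownames(votes),
    vote_A = votes[, "A"],
    vote_P = votes[, "P1"] + votes[, "P2"]
  )
  out <- partition |>
    dplyr::select("id", "set") |>
    dplyr::left_join(vote_tbl, by = "id") |>
    dplyr::mutate(final_label = dplyr::case_when(
      .data$set == "set4" ~ "not_translocated",
      .data$id %in% type_iv_ids ~ "excluded_typeIV",
      .data$vote_A > .data$vote_P ~ "organellar",
      TRUE ~ "cell_envelope"
    ))
  n_translocated <- sum(out$set != "set4")
  n_excluded <- sum(out$final_label == "excluded_typeIV")
  n_org <- sum(out$final_label == "organellar")
  attr(out, "summary") <- list(
    set_sizes = as.list(table(partition$set)),
    n_translocated = n_translocated,
    n_excluded_typeIV = n_excluded,
    n_organellar = n_org,
    n_cell_envelope = sum(out$final_label == "cell_envelope"),
    fraction_organellar = n_org / (n_translocated - n_excluded)
  )
  out
}
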