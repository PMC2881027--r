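# FASTA / TSV input-output and the end-to-end pipeline driver.

#' Read protein records from FASTA
#'
#' Sequences are uppercased; record order and ids are preserved. Records
#' containing `X` are dropped with a warning when `tolerate_X = TRUE`
#' (rejected otherwise); any other symbol outside the 20-letter alphabet
#' raises an error naming the offending record.
#'
#' @param path FASTA file.
#' @param tolerate_X Drop records containing X instead of failing.
#' @return Tibble: `id`, `sequence`.
#' @export
read_fasta <- function(path, tolerate_X = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) rlang::abort(sprintf("empty FASTA file: %s", path))
  out <- tibble::tibble(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
  has_x <- grepl("X", out$sequence, fixed = TRUE)
  if (any(has_x)) {
    if (!tolerate_X) {
      rlang::abort(sprintf("record '%s' contains X", out$id[which(has_x)[1]]))
    }
    warning(sprintf("dropping %d record(s) containing X: %s", sum(has_x),
                    paste(out$id[has_x], collapse = ", ")))
    out <- out[!has_x, ]
  }
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), out$sequence)
  if (!all(ok)) {
    bad <- out[!ok, ]
    sym <- setdiff(unique(strsplit(bad$sequence[1], "")[[1]]), AA_ALPHABET)
    rlang::abort(sprintf("record '%s' contains non-standard symbol(s): %s",
                         bad$id[1], paste(sym, collapse = ", ")))
  }
  out
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- proteins$id
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Write the truth sidecar of a synthetic set
#'
#' @param proteins Synthetic record tibble.
#' @param path Output TSV (columns id, truth_label, cleavage_index).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(proteins, path) {
  readr::write_tsv(
    tibble::tibble(id = proteins$id, truth_label = proteins$truth_label,
                   cleavage_index = proteins$sp_truth),
    path)
  invisible(path)
}

#' Read an external predictor vote table
#'
#' Strict-format TSV reader for externally computed signal-peptide (or
#' other predictor) calls: required columns `protein_id`, `predictor`,
#' `call` (0/1), optional `cleavage_pos`.
#'
#' @param path TSV file.
#' @return Vote table tibble with logical `call`.
#' @export
read_vote_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("protein_id", "predictor", "call")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("vote table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(tbl), c(required, "cleavage_pos"))
  if (length(extra) > 0L) {
    rlang::abort(sprintf("vote table has unexpected column(s): %s",
                         paste(extra, collapse = ", ")))
  }
  if (!all(tbl$call %in% c(0, 1, TRUE, FALSE))) {
    rlang::abort("vote table `call` must be 0/1")
  }
  tbl$call <- as.logical(tbl$call)
  if (!"cleavage_pos" %in% names(tbl)) tbl$cleavage_pos <- NA_integer_
  tbl
}

default_config <- function() {
  list(
    seed = 1L,
    generator = list(n_A = 30L, n_P = 59L, n_tm = 20L, n_cyt = 50L,
                     divergence = 1.15, length_min = 120L, length_max = 400L),
    protocol = list(n_randomizations = 50L, n_trees = 200L,
                    region = "full", order = 2L, exclusion_mode = "none"),
    votes = list(n_predictors = 15L, sensitivity = 1, specificity = 1,
                 cleavage_sd = 0),
    sp = list(h_floor = 1.0, h_min_len = 6L),
    digest = list(detect_min = 600, detect_max = 4000, min_peptides = 3L,
                  max_k = 50L)
  )
}

#' Build a validated pipeline configuration
#'
#' Merges user overrides into the default configuration, rejecting unknown
#' keys at both levels so typos fail loudly. The configuration round-trips
#' losslessly through YAML ([read_pipeline_config()]).
#'
#' @param ... Named blocks (`seed`, `generator`, `protocol`, `votes`,
#'   `sp`, `digest`) whose entries override the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- default_config()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")))
  }
  for (blk in names(overrides)) {
    if (blk == "seed") { defaults$seed <- as.integer(overrides$seed); next }
    bad <- setdiff(names(overrides[[blk]]), names(defaults[[blk]]))
    if (length(bad) > 0L) {
      rlang::abort(sprintf("unknown key(s) in config block '%s': %s",
                           blk, paste(bad, collapse = ", ")))
    }
    defaults[[blk]][names(overrides[[blk]])] <- overrides[[blk]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [read_pipeline_config()] returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @return `write_pipeline_config()` returns `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic-to-prediction pipeline
#'
#' Executes every stage end-to-end on synthetic data: sequence generation,
#' feature construction, the randomized forest protocol, simulated
#' predictor votes and their majority-vote combination, the four-set
#' proteome partition, organellar prediction, signal-peptide architecture
#' analysis, physicochemical profiling, and digest-based cleavage-site
#' validation. All stage seeds derive deterministically from the single
#' configuration seed, so identical configurations give identical
#' summaries.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage tables (FASTA,
#'   TSV) and the JSON summary are written there.
#' @return A list of class `pipeline_result` with components `summary`
#'   (flat named list of headline numbers), `model`, `partition`,
#'   `prediction`, `training`, `proteome`, `sp_annotations`, `physchem`,
#'   and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- config$generator
  cfg <- generator_config(
    seed = config$seed, n_A = g$n_A, n_P = g$n_P, n_tm = g$n_tm,
    n_cyt = g$n_cyt, divergence = g$divergence,
    length_range = c(g$length_min, g$length_max))

  training <- generate_training_sets(cfg)
  proteome <- generate_proteome(cfg)

  p <- config$protocol
  model <- run_protocol(training$A, training$P,
                        n_randomizations = p$n_randomizations,
                        n_trees = p$n_trees, region = p$region,
                        order = p$order, exclusion_mode = p$exclusion_mode,
                        base_seed = config$seed, keep_votes = FALSE)

  v <- config$votes
  votes <- simulate_predictor_votes(proteome, n_predictors = v$n_predictors,
                                    sensitivity = v$sensitivity,
                                    specificity = v$specificity,
                                    cleavage_sd = v$cleavage_sd,
                                    seed = config$seed + 2L)
  sp_calls <- majority_vote(votes, n_predictors = v$n_predictors)
  partition <- partition_proteome(proteome, sp_calls)
  prediction <- predict_organellar(partition, proteome, model)

  both <- dplyr::bind_rows(training$A, training$P)
  ann <- annotate_signal_peptides(both, h_floor = config$sp$h_floor,
                                  h_min_len = config$sp$h_min_len)
  pfm_cleavage <- position_frequency_matrix(
    segmental_align(ann, anchor = "cleavage_site"))
  phe_mean <- h_region_phe_count(ann)

  mature <- dplyr::mutate(both,
    sequence = substr(.data$sequence, .data$sp_truth + 1L, nchar(.data$sequence)))
  physchem <- physchem_profile(mature) |>
    dplyr::mutate(truth_label = both$truth_label)
  physchem_means <- physchem |>
    dplyr::group_by(.data$truth_label) |>
    dplyr::summarise(gravy = mean(.data$gravy),
                     aliphatic_index = mean(.data$aliphatic_index),
                     .groups = "drop")

  # Cleavage-site validation on simulated peptide evidence: the first
  # three detectable fully-tryptic mature peptides plus the semi-tryptic
  # N-terminal peptide implied by the true cleavage site.
  d <- config$digest
  verdicts <- purrr::map(seq_len(nrow(both)), function(i) {
    s <- both$sequence[i]; k <- both$sp_truth[i]
    frags <- tryptic_digest(s)
    downstream <- frags[frags$start > k + 1L &
                        frags$mass >= d$detect_min & frags$mass <= d$detect_max, ]
    nterm_end <- min(frags$end[frags$end > k])
    observed <- tibble::tibble(
      sequence = c(substr(s, k + 1L, nterm_end),
                   utils::head(downstream$peptide, 2L)),
      start = c(k + 1L, utils::head(downstream$start, 2L)))
    validate_cleavage(s, k, observed,
                      detect_range = c(d$detect_min, d$detect_max),
                      min_peptides = d$min_peptides, max_k = d$max_k)
  }) |> dplyr::bind_rows()

  pred_summary <- attr(prediction, "summary")
  truth_org <- proteome$truth_label == "A"
  org_ids <- prediction$id[prediction$final_label == "organellar"]
  summary <- c(
    list(config_hash = rlang::hash(unclass(config)), seed = config$seed),
    pred_summary,
    list(
      best_accuracy = model$selection$accuracy,
      best_recall_A = model$selection$recall_A,
      oob_error_mean = model$selection$oob_error_mean,
      oob_error_sd = model$selection$oob_error_sd,
      organellar_recall = mean(proteome$id[truth_org] %in% org_ids),
      h_region_phe_mean = phe_mean,
      cleavage_confirmation_rate = mean(verdicts$confirmed),
      gravy_mean_A = physchem_means$gravy[physchem_means$truth_label == "A"],
      gravy_mean_P = physchem_means$gravy[physchem_means$truth_label == "P"],
      aliphatic_mean_A =
        physchem_means$aliphatic_index[physchem_means$truth_label == "A"],
      aliphatic_mean_P =
        physchem_means$aliphatic_index[physchem_means$truth_label == "P"]
    )
  )

  result <- structure(list(
    summary = summary, model = model, partition = partition,
    prediction = prediction, training = training, proteome = proteome,
    sp_annotations = ann, pfm_cleavage = pfm_cleavage, physchem = physchem,
    verdicts = verdicts, config = config,
    config_hash = summary$config_hash
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(dplyr::bind_rows(training$A, training$P),
                file.path(out_dir, "training.fasta"))
    write_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    write_truth_table(proteome, file.path(out_dir, "proteome_truth.tsv"))
    readr::write_tsv(model$runs, file.path(out_dir, "runs.tsv"))
    readr::write_tsv(partition, file.path(out_dir, "partition.tsv"))
    readr::write_tsv(prediction, file.path(out_dir, "prediction.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("End-to-end organellar sub-proteome pipeline\n")
  cat(sprintf("  partition: %s\n",
              paste(sprintf("%s=%d", names(s$set_sizes), unlist(s$set_sizes)),
                    collapse = ", ")))
  cat(sprintf("  best model: accuracy %.3f, recall(A) %.3f (OOB mean %.3f)\n",
              s$best_accuracy, s$best_recall_A, s$oob_error_mean))
  cat(sprintf("  organellar: %d of %d non-excluded translocated proteins (%.1f%%)\n",
              s$n_organellar, s$n_translocated - s$n_excluded_typeIV,
              100 * s$fraction_organellar))
  invisible(x)
}
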