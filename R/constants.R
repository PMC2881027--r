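# Residue-level constants shared across the package.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order; the canonical residue alphabet
#' used by every function in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used for GRAVY, h-region detection and the
#' hydropathy-window transmembrane-helix scan.
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Monoisotopic residue masses (Da); peptide mass = sum + one water.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO <- 18.010565

# Amino-acid classes whose prevalences are profiled alongside GRAVY and
# the aliphatic index.
AA_CLASSES <- list(
  ILV       = c("I", "L", "V"),
  FWY       = c("F", "W", "Y"),
  AILVMFWYC = c("A", "I", "L", "V", "M", "F", "W", "Y", "C"),
  AGS       = c("A", "G", "S"),
  ST        = c("S", "T"),
  GNP       = c("G", "N", "P"),
  DE        = c("D", "E"),
  DN        = c("D", "N"),
  KR        = c("K", "R"),
  EQ        = c("E", "Q"),
  DENQ      = c("D", "E", "N", "Q"),
  HKR       = c("H", "K", "R"),
  DENQHKR   = c("D", "E", "N", "Q", "H", "K", "R"),
  DENQHKRST = c("D", "E", "N", "Q", "H", "K", "R", "S", "T")
)

# Background residue frequencies (approximate UniProt/Swiss-Prot
# composition), used as the shared null model of the sequence generator.
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0136, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0598, K = 0.0580, L = 0.0972,
  M = 0.0241, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Split a sequence string into a residue vector, validating the alphabet.
# `what` names the offending input in error messages.
aa_chars <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    rlang::abort(sprintf("%s must be a single non-empty string", what))
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s contains non-standard residue symbol(s): %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  chars
}

# All 400 ordered dipeptide feature names, fixed column order.
dipeptide_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}
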