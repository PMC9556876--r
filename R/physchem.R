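# The seven physico-chemical sequence properties used by the sequence-based
# predictor, and the standardized property score. All seven are functions of
# amino-acid composition only (order-invariant). Constants: see constants.R.

aa_count <- function(seq, letters) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(chars %in% letters)
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill-von Hippel with the oxidized-cystine convention:
#' `5500 nTrp + 1490 nTyr + 125 floor(nCys / 2)` (units M^-1 cm^-1).
#'
#' @param seq amino-acid sequence.
#' @return extinction coefficient (>= 0).
#' @export
extinction_coefficient <- function(seq) {
  validate_sequence(seq)
  EXT_TRP * aa_count(seq, "W") + EXT_TYR * aa_count(seq, "Y") +
    EXT_CYSTINE * (aa_count(seq, "C") %/% 2L)
}

#' Molecular weight (Da)
#'
#' Sum of average residue masses plus one water (18.02 Da).
#' @param seq amino-acid sequence.
#' @return molecular weight in Dalton.
#' @export
molecular_weight <- function(seq) {
  validate_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

#' Absorbance (optical density) at 1 g/L, 1 cm path
#'
#' Extinction coefficient divided by molecular weight.
#' @param seq amino-acid sequence.
#' @return dimensionless absorbance.
#' @export
absorbance <- function(seq) {
  extinction_coefficient(seq) / molecular_weight(seq)
}

#' Charged-residue counts
#'
#' ProtParam convention: negative = Asp + Glu, positive = Arg + Lys
#' (histidine excluded).
#'
#' @param seq amino-acid sequence.
#' @return named integer vector `c(n_neg, n_pos)`.
#' @export
charge_counts <- function(seq) {
  validate_sequence(seq)
  c(n_neg = aa_count(seq, AA_NEGATIVE), n_pos = aa_count(seq, AA_POSITIVE))
}

#' Aliphatic index
#'
#' Ikai: `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with X in mole percent.
#' Ranges from 0 (no aliphatic side chains) to 390 (poly-Ile/Leu).
#'
#' @param seq amino-acid sequence.
#' @return aliphatic index.
#' @export
aliphatic_index <- function(seq) {
  validate_sequence(seq)
  n <- nchar(seq)
  100 * (aa_count(seq, "A") + ALIPHATIC_COEF_VAL * aa_count(seq, "V") +
           ALIPHATIC_COEF_ILE_LEU *
             (aa_count(seq, "I") + aa_count(seq, "L"))) / n
}

# Net charge at a given pH under the pinned pKa table.
net_charge_at_ph <- function(seq, ph) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos_pka <- c(PKA_NTERM, PKA_POSITIVE[chars[chars %in% names(PKA_POSITIVE)]])
  neg_pka <- c(PKA_CTERM, PKA_NEGATIVE[chars[chars %in% names(PKA_NEGATIVE)]])
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

#' Isoelectric point
#'
#' pH at which the net charge is zero under the pinned free-amino-acid pKa
#' table, found by bisection on `[0, 14]` to a tolerance of 1e-4 pH units.
#'
#' @param seq amino-acid sequence.
#' @return pI.
#' @export
isoelectric_point <- function(seq) {
  validate_sequence(seq)
  lo <- 0
  hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-4) return(mid)
    if (net_charge_at_ph(seq, mid) > 0) lo <- mid else hi <- mid
  }
  stopf("isoelectric_point: bisection did not converge")
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence.
#' @param seq amino-acid sequence.
#' @return GRAVY value.
#' @export
gravy <- function(seq) {
  validate_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(AA_KYTE_DOOLITTLE[chars])
}

#' The seven-property vector of a sequence
#'
#' Components: extinction coefficient, absorbance, negative / positive
#' residue counts, aliphatic index, pI divided by molecular weight in kDa,
#' and GRAVY.
#'
#' @param seq amino-acid sequence.
#' @return named numeric vector of length 7 (names [PROPERTY_NAMES]).
#' @export
property_vector <- function(seq) {
  cc <- charge_counts(seq)
  mw <- molecular_weight(seq)
  c(e_protein = extinction_coefficient(seq),
    absorbance = absorbance(seq),
    n_neg = unname(cc["n_neg"]),
    n_pos = unname(cc["n_pos"]),
    aliphatic_index = aliphatic_index(seq),
    ip_over_mw = isoelectric_point(seq) / (mw / 1000),
    gravy = gravy(seq))
}

#' Property matrix for a set of sequences
#' @param seqs named character vector of sequences.
#' @return numeric matrix, one row per sequence (row names = IDs), seven
#'   columns.
#' @export
property_matrix <- function(seqs) {
  m <- t(vapply(seqs, property_vector, numeric(length(PROPERTY_NAMES))))
  colnames(m) <- PROPERTY_NAMES
  m
}

# Column-wise z-scoring of a matrix against a reference population matrix;
# population standard deviation, zero-variance columns map to 0.
zscore_against <- function(m, population) {
  mu <- colMeans(population)
  sd <- apply(population, 2, pop_sd)
  z <- sweep(sweep(m, 2, mu, "-"), 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  z
}

#' Standardized property score of a sequence
#'
#' The seven raw properties span several orders of magnitude, so each
#' component is z-scored against a stated reference population (the target's
#' refined neighborhood in the pipeline) using the population standard
#' deviation; a zero-variance component maps to 0. The scalar score is the
#' arithmetic mean of the seven standardized components.
#'
#' @param seq amino-acid sequence (or a pre-computed 7-component vector).
#' @param population matrix of property vectors (>= 2 rows) defining the
#'   reference population.
#' @return object of class `property_score`: list with `vector` (z-scored
#'   7-vector) and `scalar`.
#' @export
property_score <- function(seq, population) {
  if (is.null(dim(population)) || nrow(population) < 2L) {
    stopf("property_score: reference population needs at least 2 vectors")
  }
  v <- if (is.character(seq)) property_vector(seq) else seq
  z <- zscore_against(matrix(v, nrow = 1), population)[1, ]
  names(z) <- PROPERTY_NAMES
  structure(list(vector = z, scalar = mean(z)), class = "property_score")
}
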