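# Pinned physico-chemical constant tables. All seven sequence properties are
# computed from these; they are deliberately kept in one place so the exact
# parameterization of the predictor is auditable and versioned with the code.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses (Da); peptide MW = sum + one water (18.02).
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.02

# Kyte-Doolittle hydropathy values; GRAVY is their mean over the sequence.
AA_KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Molar extinction coefficients at 280 nm (M^-1 cm^-1), oxidized-cystine
# convention: each cystine (pair of Cys) contributes 125.
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

# Aliphatic index relative-volume coefficients for Val and Ile/Leu.
ALIPHATIC_COEF_VAL <- 2.9
ALIPHATIC_COEF_ILE_LEU <- 3.9

# Classic free-amino-acid pKa table used for the isoelectric point:
# terminal groups 9.60 (alpha-amino) / 2.34 (alpha-carboxyl) and the seven
# ionizable side chains. One coherent published set, pinned.
PKA_NTERM <- 9.60
PKA_CTERM <- 2.34
PKA_POSITIVE <- c(K = 10.53, R = 12.48, H = 6.00)   # protonated = +1
PKA_NEGATIVE <- c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07)  # deprotonated = -1

# Charged-residue count convention (ProtParam): Asp/Glu negative, Arg/Lys
# positive; His excluded from the positive count.
AA_NEGATIVE <- c("D", "E")
AA_POSITIVE <- c("R", "K")

PROPERTY_NAMES <- c("e_protein", "absorbance", "n_neg", "n_pos",
                    "aliphatic_index", "ip_over_mw", "gravy")
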