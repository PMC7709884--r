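#' @title Physical constants and residue tables
#' @description Internal tables used across the package: IUPAC isotope masses
#'   and abundances, monoisotopic residue formulas, and the count of
#'   fast-exchanging (labile) side-chain hydrogens per residue.
#' @name constants
#' @keywords internal
NULL

## IUPAC 2013 isotopic masses (Da) and representative abundances.
## Only the five elements occurring in unmodified peptides are needed.
.ISOTOPES <- list(
  C = list(mass = c(12.0000000, 13.0033548378), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017780), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.9720706900, 32.9714585000, 33.9678668300, 35.9670808800),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

## Mass of the ionizing proton (Da): [M+H]+ = M + .PROTON_MASS.
.PROTON_MASS <- 1.007276

## Mass difference D - H (Da); one incorporated deuterium shifts the ion by this.
.DELTA_DH <- 1.006277

## Monoisotopic mass of protium; used for labile sites excluded from the
## natural-abundance convolution and re-added as fixed mass.
.H1_MASS <- 1.0078250319

## Residue (i.e. amino acid minus water) elemental compositions, columns C H N O S.
.RESIDUE_FORMULAS <- matrix(
  c(3,  5, 1, 1, 0,  # A
    6, 12, 4, 1, 0,  # R
    4,  6, 2, 2, 0,  # N
    4,  5, 1, 3, 0,  # D
    3,  5, 1, 1, 1,  # C
    5,  7, 1, 3, 0,  # E
    5,  8, 2, 2, 0,  # Q
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 11, 1, 1, 0,  # L
    6, 12, 2, 1, 0,  # K
    5,  9, 1, 1, 1,  # M
    9,  9, 1, 1, 0,  # F
    5,  7, 1, 1, 0,  # P
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0,  # Y
    5,  9, 1, 1, 0), # V
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("C", "H", "N", "O", "S"))
)

## Labile (fast-exchanging) side-chain hydrogens per residue, neutral forms.
## Residues not listed carry none. N-terminal amine contributes 2 and the
## C-terminal carboxyl 1; both are added per peptide, not per residue.
.LABILE_SIDECHAIN <- c(R = 4, K = 2, H = 1, D = 1, E = 1, S = 1, T = 1,
                       N = 2, Q = 2, Y = 1, W = 1, C = 1)
.LABILE_NTERM <- 2
.LABILE_CTERM <- 1

.AA_ALPHABET <- rownames(.RESIDUE_FORMULAS)
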