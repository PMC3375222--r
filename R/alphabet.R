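# Residue alphabet and per-residue physicochemical lookup tables shared by
# all encoders. The working alphabet has 21 letters: the 20 standard amino
# acids in alphabetical one-letter order, plus "O", an artificial padding
# symbol used to fill window positions that fall outside the protein.

#' The 21-letter fragment alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order followed by
#' the padding symbol `O`. Feature encoders index one-hot blocks and pair
#' counts in this order (`A` = 1, ..., `Y` = 20, `O` = 21).
#'
#' @format Character vector of length 21.
#' @export
FRAGMENT_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "O")

STANDARD_AA <- FRAGMENT_ALPHABET[1:20]

# letter -> 1-based index into FRAGMENT_ALPHABET
.ALPHA_INDEX <- stats::setNames(seq_along(FRAGMENT_ALPHABET), FRAGMENT_ALPHABET)

#' Look up alphabet indices for residue letters
#'
#' @param letters Character vector of single letters.
#' @return Integer vector of 1-based indices into [FRAGMENT_ALPHABET].
#' @keywords internal
alphabet_index <- function(letters) {
  idx <- .ALPHA_INDEX[letters]
  if (anyNA(idx)) {
    bad <- unique(letters[is.na(idx)])
    stop("letters outside the 21-letter alphabet: ", paste(bad, collapse = ", "))
  }
  unname(idx)
}

# Side-chain hydrophobicity (vacuum-to-water transfer free energies,
# kcal/mol). Positive = hydrophobic. The padding symbol O is neutral (0).
.HYDROPHOBICITY <- c(
  A =   1.81, C =  1.28, D = -8.72, E = -6.81, F =  2.98,
  G =   0.94, H = -4.66, I =  4.92, K = -5.55, L =  4.92,
  M =   2.35, N = -6.64, P =  4.04, Q = -5.54, R = -14.92,
  S =  -3.40, T = -2.57, V =  4.04, W =  2.33, Y = -0.14,
  O =   0.00
)

#' Hydrophobicity of a residue
#'
#' Side-chain hydrophobicity values on the vacuum-to-water transfer
#' free-energy scale; the padding symbol `O` maps to 0 so that positions
#' beyond the protein termini are hydrophobically neutral.
#'
#' @param letter Character vector of residue letters from [FRAGMENT_ALPHABET].
#' @return Numeric vector of hydrophobicity values.
#' @examples
#' hydrophobicity(c("A", "I", "K", "O"))
#' @export
hydrophobicity <- function(letter) {
  v <- .HYDROPHOBICITY[letter]
  if (anyNA(v)) {
    bad <- unique(letter[is.na(v)])
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  unname(v)
}

# Z-scales: five principal-component physicochemical descriptors per amino
# acid (z1 lipophilicity, z2 steric bulk/polarizability, z3 polarity,
# z4/z5 electronic effects). Padding symbol O contributes all zeros.
.ZSCALES <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,  # A
   0.84, -1.67,  3.71,  0.18, -2.65,  # C
   3.98,  0.93,  1.93, -2.46,  0.75,  # D
   3.11,  0.26, -0.11, -3.04, -0.25,  # E
  -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   2.05, -4.06,  0.36, -0.82, -0.38,  # G
   2.47,  1.95,  0.26,  3.90,  0.09,  # H
  -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   2.29,  0.89, -2.49,  1.49,  0.31,  # K
  -4.28, -1.30, -1.49, -0.72,  0.84,  # L
  -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   3.05,  1.62,  1.04, -1.15,  1.61,  # N
  -1.66,  0.27,  1.84,  0.70,  2.00,  # P
   1.75,  0.50, -1.44, -1.34,  0.66,  # Q
   3.52,  2.50, -3.50,  1.99, -0.17,  # R
   2.39, -1.07,  1.15, -1.39,  0.67,  # S
   0.75, -2.18, -1.12, -1.46, -0.40,  # T
  -2.59, -2.64, -1.54, -0.85, -0.02,  # V
  -4.36,  3.94,  0.59,  3.44, -1.59,  # W
  -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
   0.00,  0.00,  0.00,  0.00,  0.00   # O
), ncol = 5, byrow = TRUE,
   dimnames = list(FRAGMENT_ALPHABET, paste0("z", 1:5)))

#' Z-scale descriptors for residue letters
#'
#' @param letter Character vector of residue letters.
#' @return Numeric matrix with one row per letter and columns `z1`..`z5`.
#' @export
zscales <- function(letter) {
  if (!all(letter %in% FRAGMENT_ALPHABET)) {
    bad <- unique(setdiff(letter, FRAGMENT_ALPHABET))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  .ZSCALES[letter, , drop = FALSE]
}

# Reduced alphabets. Six groups: aliphatic {A,V,L,I}, charged {D,E,R,K},
# polar {S,T,N,Q}, cyclic {F,H,Y,W}, other {G,P,M,C}, padding {O}.
# The nine-letter variant splits "other" into G, P, M, C singletons.
.SIX_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I"),
  charged   = c("D", "E", "R", "K"),
  polar     = c("S", "T", "N", "Q"),
  cyclic    = c("F", "H", "Y", "W"),
  other     = c("G", "P", "M", "C"),
  padding   = "O"
)
.NINE_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I"),
  charged   = c("D", "E", "R", "K"),
  polar     = c("S", "T", "N", "Q"),
  cyclic    = c("F", "H", "Y", "W"),
  glycine    = "G",
  proline    = "P",
  methionine = "M",
  cysteine   = "C",
  padding    = "O"
)

.group_map <- function(groups) {
  m <- integer(0)
  for (g in seq_along(groups)) m[groups[[g]]] <- g
  m
}
.SIX_MAP <- .group_map(.SIX_GROUPS)
.NINE_MAP <- .group_map(.NINE_GROUPS)

#' Reduced-alphabet group index of residue letters
#'
#' @param letter Character vector of residue letters.
#' @param variant `"six"` (aliphatic/charged/polar/cyclic/other/padding) or
#'   `"nine"` (the "other" group split into G, P, M, C singletons).
#' @return Integer vector of 1-based group indices.
#' @export
reduced_group <- function(letter, variant = c("six", "nine")) {
  variant <- match.arg(variant)
  m <- if (variant == "six") .SIX_MAP else .NINE_MAP
  g <- m[letter]
  if (anyNA(g)) {
    bad <- unique(letter[is.na(g)])
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  unname(g)
}

# Normalized BLOSUM62 over the 21-letter alphabet: the standard 20x20
# BLOSUM62 block is min-max rescaled to [0,1]; the padding symbol is
# self-identical (sim(O,O) = 1) and maximally dissimilar to everything else.
.normalized_blosum <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    b <- env$BLOSUM62[STANDARD_AA, STANDARD_AA]
    b <- (b - min(b)) / (max(b) - min(b))
    m <- matrix(0, 21, 21, dimnames = list(FRAGMENT_ALPHABET, FRAGMENT_ALPHABET))
    m[STANDARD_AA, STANDARD_AA] <- b
    m["O", "O"] <- 1
    cache <<- m
    m
  }
})

#' Min-max normalized BLOSUM62 similarity matrix
#'
#' The 20x20 BLOSUM62 substitution matrix rescaled globally to `[0,1]`,
#' extended to the padding symbol `O` with `sim(O,O) = 1` and
#' `sim(O,x) = 0` for any residue `x`.
#'
#' @return 21x21 symmetric numeric matrix with row/column names in
#'   [FRAGMENT_ALPHABET] order.
#' @export
normalized_blosum62 <- function() .normalized_blosum()
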