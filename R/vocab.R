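# Fixed amino-acid vocabulary: the 20 canonical one-letter codes in
# alphabetical order; integer code 0 is reserved for padding, 1-20 for
# residues. All internal arrays are 0-based in concept (pad = 0) but stored
# in R's 1-based containers.
AA_VOCAB <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

SS_VOCAB <- c("H", "E", "L")

# Non-polar residues, used by the hot-spot composition filter.
AA_NONPOLAR <- c("A", "F", "G", "I", "L", "M", "P", "V", "W")

# Kyte-Doolittle hydrophobicity shifted to a strictly positive scale;
# used as per-residue contact weights by the surrogate energy model.
AA_HYDRO <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)
AA_WEIGHT <- (AA_HYDRO + 5) / 9.5   # in (0, 1]; strictly positive

#' Encode amino-acid letters as integer codes
#'
#' Maps one-letter amino-acid codes to the fixed vocabulary (alphabetical
#' order, `A` = 1 ... `Y` = 20); the pad code 0 is never produced here.
#'
#' @param aa character vector of one-letter codes.
#' @return integer vector of codes in 1..20.
#' @export
aa_encode <- function(aa) {
  idx <- match(aa, AA_VOCAB)
  if (anyNA(idx)) {
    bad <- unique(aa[is.na(idx)])
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  idx
}

#' Decode integer codes to amino-acid letters
#'
#' @param idx integer vector in 1..20 (0 decodes to `NA`, the pad).
#' @return character vector of one-letter codes.
#' @export
aa_decode <- function(idx) {
  out <- rep(NA_character_, length(idx))
  ok <- idx >= 1 & idx <= 20
  out[ok] <- AA_VOCAB[idx[ok]]
  out
}

ss_encode <- function(ss) {
  idx <- match(ss, SS_VOCAB)
  if (anyNA(idx)) stop("unknown secondary-structure code(s): ",
                       paste(unique(ss[is.na(idx)]), collapse = ", "))
  idx
}
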