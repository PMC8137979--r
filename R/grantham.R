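# Grantham's physicochemical distance between amino acids (composition,
# polarity, molecular volume). Values are the published integer matrix;
# range 5 (Leu/Ile) to 215 (Cys/Trp).

.GRANTHAM_AA <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                  "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

# Upper triangle, rows in .GRANTHAM_AA order: row i holds d(aa_i, aa_j) for
# j > i.
.GRANTHAM_UPPER <- list(
  S = c(110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177),
  R = c(102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101),
  L = c( 98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61),
  P = c( 38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147),
  T = c( 58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128),
  A = c( 64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148),
  V = c(109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88),
  G = c(135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184),
  I = c( 21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61),
  F = c( 22, 205, 100, 116, 158, 102, 177, 140,  28,  40),
  Y = c(194,  83,  99, 143,  85, 160, 122,  36,  37),
  C = c(174, 154, 139, 202, 154, 170, 196, 215),
  H = c( 24,  68,  32,  81,  40,  87, 115),
  Q = c( 46,  53,  61,  29, 101, 130),
  N = c( 94,  23,  42, 142, 174),
  K = c(101,  56,  95, 110),
  D = c( 45, 160, 181),
  E = c(126, 152),
  M = c(67)
)

.grantham_matrix <- local({
  n <- length(.GRANTHAM_AA)
  m <- matrix(0L, n, n, dimnames = list(.GRANTHAM_AA, .GRANTHAM_AA))
  for (i in seq_len(n - 1)) {
    vals <- .GRANTHAM_UPPER[[.GRANTHAM_AA[i]]]
    m[i, (i + 1):n] <- as.integer(vals)
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
})

.AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

.aa1 <- function(aa) {
  aa <- as.character(aa)
  out <- ifelse(nchar(aa) == 1, toupper(aa),
                unname(.AA3TO1[paste0(toupper(substr(aa, 1, 1)),
                                      tolower(substr(aa, 2, 3)))]))
  bad <- is.na(out) | !(out %in% .GRANTHAM_AA)
  if (any(bad)) {
    stop("not a standard amino acid: ", paste(aa[bad], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Grantham distance between two amino acids
#'
#' Physicochemical distance on the published Grantham scale, combining
#' composition, polarity and molecular volume. Larger values mark more
#' radical substitutions; the scale runs from 5 (Leu/Ile) to 215 (Cys/Trp),
#' and identical residues score 0.
#'
#' @param aa1,aa2 Amino acids as one-letter (`"A"`) or three-letter
#'   (`"Ala"`) codes; vectors recycle.
#' @return Integer vector of Grantham distances.
#' @examples
#' grantham_distance("Ala", "Ser")  # 99
#' grantham_distance("Cys", "Gly")  # 159
#' @export
grantham_distance <- function(aa1, aa2) {
  a <- .aa1(aa1)
  b <- .aa1(aa2)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  .grantham_matrix[cbind(a, b)]
}

#' The full Grantham distance matrix
#'
#' @return A symmetric 20 x 20 integer matrix with zero diagonal, rows and
#'   columns named by one-letter amino acid codes.
#' @export
grantham_matrix <- function() .grantham_matrix
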