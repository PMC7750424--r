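#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the 20 proteinogenic amino acids, in alphabetical
#' order. This ordering is the canonical column order used throughout the
#' package (count profiles, dataset CSVs, model coefficients).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Amino-acid reference table
#'
#' Bundles the classification and physical constants the analyses rely on:
#' the nine amino acids essential to human cells (F, H, I, K, L, M, T, V, W —
#' histidine included), the non-essential complement, the biosynthetic
#' precursor map among non-essential amino acids, and average molar masses of
#' the free amino acids in g/mol.
#'
#' The precursor map pairs each donor NEAA with the NEAAs synthesised from
#' it in human cells: serine gives cysteine and glycine, aspartate gives
#' asparagine, and glutamate gives glutamine, proline and arginine. Both the
#' map and the mass table are configurable for sensitivity analyses.
#'
#' @param molar_mass Optional named numeric vector (g/mol) overriding the
#'   default average free-amino-acid masses; must cover the full alphabet
#'   with positive values.
#' @param precursors Optional named list mapping a donor NEAA to a character
#'   vector of product NEAAs.
#' @return A list of class `aa_table` with elements `alphabet`, `essential`,
#'   `nonessential`, `precursors`, `molar_mass`.
#' @export
#' @examples
#' tab <- aa_table()
#' tab$essential
aa_table <- function(molar_mass = NULL, precursors = NULL) {
  alphabet <- aa_alphabet()
  essential <- c("F", "H", "I", "K", "L", "M", "T", "V", "W")
  if (is.null(molar_mass)) {
    molar_mass <- c(
      A =  89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
      G =  75.07, H = 155.16, I = 131.17, K = 146.19, L = 131.17,
      M = 149.21, N = 132.12, P = 115.13, Q = 146.14, R = 174.20,
      S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19
    )
  }
  if (!all(alphabet %in% names(molar_mass)) || any(molar_mass <= 0)) {
    stop("molar_mass must give a positive mass for every amino acid")
  }
  if (is.null(precursors)) {
    precursors <- list(S = c("C", "G"), D = "N", E = c("Q", "P", "R"))
  }
  nonessential <- setdiff(alphabet, essential)
  bad <- setdiff(c(names(precursors), unlist(precursors)), nonessential)
  if (length(bad) > 0) {
    stop("precursor map entries must all be non-essential amino acids: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      alphabet     = alphabet,
      essential    = essential,
      nonessential = nonessential,
      precursors   = precursors,
      molar_mass   = molar_mass[alphabet]
    ),
    class = "aa_table"
  )
}

# Validate a character vector of sequences against the 20-letter alphabet.
# Returns the upper-cased sequences; errors name the record and the first
# offending character (U, O, X and gap characters are rejected, not dropped).
validate_sequences <- function(seqs, names = NULL) {
  seqs <- toupper(as.character(seqs))
  if (is.null(names)) names <- seq_along(seqs)
  ok <- aa_alphabet()
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, ok)
    if (length(bad) > 0) {
      stop(sprintf("record '%s' contains invalid amino-acid letter '%s'",
                   names[[i]], bad[[1]]), call. = FALSE)
    }
  }
  seqs
}

# Round half away from zero to `digits` decimals -- display convention for
# reported capacities; R's round() uses round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
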