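# Residue alphabet, charge/hydrophobicity classes and integer coding.
# Code 0 is the neutral dummy: it never interacts and is used for window
# padding and for tolerated non-standard symbols.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

# tolerated in input but scored as strictly neutral dummies
NEUTRAL_SYMBOLS <- c("X", "U", "B", "Z", "O", "*")

HYDROPHOBIC_SET <- c("V", "I", "L", "M", "F", "Y")
NEGATIVE_SET <- c("D", "E")
POSITIVE_SET <- c("K", "R")
CHARGED_POLAR_SET <- c("D", "E", "K", "R", "N", "Q")

# the four residue-index triples probed by the network rules, as offsets
NETWORK_TRIPLE_OFFSETS <- list(c(3L, 6L), c(3L, 7L), c(4L, 7L), c(4L, 8L))

# charge (+1/-1/0) and hydrophobic flag indexed by code + 1 (code 0 -> slot 1)
CHARGE_BY_CODE <- c(0L, ifelse(AA_ORDER %in% POSITIVE_SET, 1L,
                        ifelse(AA_ORDER %in% NEGATIVE_SET, -1L, 0L)))
HYDRO_BY_CODE <- c(FALSE, AA_ORDER %in% HYDROPHOBIC_SET)

#' Encode a protein sequence as integer residue codes
#'
#' Maps the 20 standard one-letter codes to integers 1..20 (in the package's
#' fixed matrix order) and tolerated neutral symbols (`X`, `U`, `B`, `Z`,
#' `O`, `*`) to 0, the non-interacting dummy code.
#'
#' @param sequence single character string of residues.
#' @return integer vector, one code per residue.
#' @keywords internal
aa_encode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(AA_ORDER, NEUTRAL_SYMBOLS))
  if (any(bad)) {
    stop("invalid residue symbol(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  codes <- match(chars, AA_ORDER)
  codes[is.na(codes)] <- 0L
  codes
}

#' Heptad position of a residue
#'
#' The first residue of every sequence sits at position `a` of the first
#' heptad; positions repeat with period 7 along the continuous helix.
#'
#' @param index 1-based residue index (vectorized).
#' @return letter(s) in `a`..`g`.
#' @examples
#' heptad_position(c(1, 7, 8, 11))
#' @export
heptad_position <- function(index) {
  if (any(index < 1) || any(index != floor(index))) {
    stop("residue index must be a positive integer")
  }
  letters[((index - 1L) %% 7L) + 1L]
}
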