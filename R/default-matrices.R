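# Default pairwise interaction matrices for i,i+3 and i,i+4 spacings.
#
# Rows are the donor residue at position i, columns the acceptor at i+3 or
# i+4. The tiers encode, in order of strength:
#   * forward salt bridges E->R > E->K, with i,i+4 stronger than i,i+3;
#   * reverse salt bridges (R/K->E) somewhat weaker than the forward ones;
#   * aspartate bridges weaker than their glutamate homologs;
#   * small helix-supporting contributions of Q/N/A paired with charged
#     residues and with themselves;
#   * destabilizing penalties for proline in either position and for
#     glycine pairs (the two canonical helix breakers).
# Pairs of identically charged residues are deliberately 0: they occur in
# every exemplary SAH pattern (e.g. EEEEKKK) and carry no signal.

.matrix_entries_i4 <- function() {
  list(
    # forward salt bridges
    c("E", "R", 1.20), c("E", "K", 1.00),
    c("D", "R", 0.80), c("D", "K", 0.50),
    # reverse salt bridges
    c("R", "E", 0.90), c("K", "E", 0.80),
    c("R", "D", 0.40), c("K", "D", 0.35),
    # helix-supporting polar pairs
    c("Q", "E", 0.30), c("E", "Q", 0.30),
    c("Q", "K", 0.30), c("K", "Q", 0.30),
    c("Q", "R", 0.30), c("R", "Q", 0.30),
    c("N", "E", 0.15), c("E", "N", 0.15),
    c("N", "K", 0.15), c("K", "N", 0.15),
    c("N", "R", 0.15), c("R", "N", 0.15),
    c("Q", "Q", 0.10), c("N", "N", 0.05),
    c("A", "A", 0.10),
    c("A", "E", 0.10), c("E", "A", 0.10),
    c("A", "K", 0.10), c("K", "A", 0.10),
    c("A", "R", 0.10), c("R", "A", 0.10),
    c("A", "Q", 0.05), c("Q", "A", 0.05),
    # helix breakers
    c("G", "G", -0.60)
  )
}

.matrix_entries_i3 <- function() {
  list(
    c("E", "R", 1.00), c("E", "K", 0.70),
    c("D", "R", 0.50), c("D", "K", 0.35),
    c("R", "E", 0.60), c("K", "E", 0.50),
    c("R", "D", 0.30), c("K", "D", 0.25),
    c("Q", "E", 0.20), c("E", "Q", 0.20),
    c("Q", "K", 0.20), c("K", "Q", 0.20),
    c("Q", "R", 0.20), c("R", "Q", 0.20),
    c("N", "E", 0.10), c("E", "N", 0.10),
    c("N", "K", 0.10), c("K", "N", 0.10),
    c("N", "R", 0.10), c("R", "N", 0.10),
    c("Q", "Q", 0.08), c("N", "N", 0.04),
    c("A", "A", 0.08),
    c("A", "E", 0.05), c("E", "A", 0.05),
    c("A", "K", 0.05), c("K", "A", 0.05),
    c("A", "R", 0.05), c("R", "A", 0.05),
    c("A", "Q", 0.04), c("Q", "A", 0.04),
    c("G", "G", -0.50)
  )
}

.build_matrix <- function(entries, proline_penalty = -2) {
  m <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  for (e in entries) {
    m[e[1], e[2]] <- as.numeric(e[3])
  }
  # proline breaks the helix wherever it sits
  m["P", ] <- proline_penalty
  m[, "P"] <- proline_penalty
  m
}

#' Default interaction scoring matrix
#'
#' Returns the package's built-in 20x20 interaction matrix for the given
#' spacing. Rows are the residue at position i, columns the partner at
#' i+3 (`"i3"`) or i+4 (`"i4"`). The same values are shipped as editable
#' CSV files under `system.file("extdata", package = "sahscan")`.
#'
#' @param spacing `"i3"` or `"i4"`.
#' @return numeric 20x20 matrix with residue dimnames, class
#'   `scoring_matrix`.
#' @examples
#' m <- default_scoring_matrix("i4")
#' m["E", "R"] > m["R", "E"]
#' @export
default_scoring_matrix <- function(spacing = c("i3", "i4")) {
  spacing <- match.arg(spacing)
  entries <- if (spacing == "i3") .matrix_entries_i3() else .matrix_entries_i4()
  m <- .build_matrix(entries)
  structure(m, spacing = spacing, class = c("scoring_matrix", "matrix"))
}

#' Load an interaction scoring matrix from CSV
#'
#' Reads a comma-separated 20x20 matrix whose first row and first column
#' hold one-letter residue codes. The row label is the residue at position
#' i, the column label the partner at i+3 or i+4.
#'
#' @param path CSV file path.
#' @param spacing `"i3"` or `"i4"`, recorded on the returned matrix.
#' @return numeric 20x20 matrix, rows/columns in the package residue order,
#'   class `scoring_matrix`.
#' @export
load_scoring_matrix <- function(path, spacing = c("i3", "i4")) {
  spacing <- match.arg(spacing)
  if (!file.exists(path)) {
    stop("scoring matrix file not found: ", path)
  }
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_row <- setdiff(AA_ORDER, rownames(raw))
  if (length(missing_row) > 0) {
    stop("scoring matrix ", path, " is missing row(s) for residue(s): ",
         paste(missing_row, collapse = ", "))
  }
  missing_col <- setdiff(AA_ORDER, colnames(raw))
  if (length(missing_col) > 0) {
    stop("scoring matrix ", path, " is missing column(s) for residue(s): ",
         paste(missing_col, collapse = ", "))
  }
  raw <- raw[AA_ORDER, AA_ORDER]
  for (j in seq_along(raw)) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(col))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in scoring matrix %s at row %s, column %s",
                   path, rownames(raw)[bad[1]], colnames(raw)[j]))
    }
    raw[[j]] <- col
  }
  m <- as.matrix(raw)
  if (any(!is.finite(m))) {
    stop("scoring matrix ", path, " contains non-finite values")
  }
  structure(m, spacing = spacing, class = c("scoring_matrix", "matrix"))
}

#' Write a scoring matrix to CSV
#'
#' Inverse of [load_scoring_matrix()]; used to export the defaults for
#' hand editing.
#'
#' @param matrix 20x20 scoring matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scoring_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(unclass(matrix)[AA_ORDER, AA_ORDER]),
                   path, quote = FALSE)
  invisible(path)
}
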