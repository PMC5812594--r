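# Per-residue SAH-score profiles.
#
# Every pairwise interaction (i, i+3) / (i, i+4) and every network triple
# is attributed to its first index i. A window's raw score is therefore the
# sum of per-position contributions c(i) over the window, which makes the
# profile an exact rolling sum: positions before the window start never
# contribute, and pairs reaching past the window end (the trailing-turn
# rule) are automatically included because they belong to an i inside the
# window. Dummy positions (outside the sequence, or tolerated non-standard
# symbols) have code 0 and contribute nothing to any pair or triple.

# per-position contribution vector c(i), i = 1..length(codes)
position_contributions <- function(codes, config) {
  n <- length(codes)
  ext <- c(codes, rep(0L, 8L))
  i <- seq_len(n)
  # 21x21 lookup tables with a zero border for the dummy code
  l3 <- matrix(0, 21, 21)
  l3[2:21, 2:21] <- config$matrix_i3
  l4 <- matrix(0, 21, 21)
  l4[2:21, 2:21] <- config$matrix_i4
  contrib <- l3[cbind(codes + 1L, ext[i + 3L] + 1L)] +
             l4[cbind(codes + 1L, ext[i + 4L] + 1L)]
  ch <- CHARGE_BY_CODE[ext + 1L]
  hy <- HYDRO_BY_CODE[ext + 1L]
  for (off in NETWORK_TRIPLE_OFFSETS) {
    q0 <- ch[i]; q1 <- ch[i + off[1]]; q2 <- ch[i + off[2]]
    alternating <- q0 != 0L & q1 == -q0 & q2 == q0
    seam <- hy[i] & hy[i + off[1]] & hy[i + off[2]]
    contrib <- contrib + alternating * config$network_charged +
                         seam * config$network_hydrophobic
  }
  contrib
}

# raw window score on an integer-coded sequence; start may address a
# window that overhangs either terminus (overhanging slots are dummies)
window_raw_score_codes <- function(codes, start, window_size, config,
                                   contrib = NULL) {
  if (is.null(contrib)) {
    contrib <- position_contributions(codes, config)
  }
  lo <- max(start, 1L)
  hi <- min(start + window_size - 1L, length(codes))
  if (lo > hi) return(0)
  sum(contrib[lo:hi])
}

# assignment position of a window: the residue its score is assigned to
# (8 / 11 / 15 / 25 for windows 14 / 21 / 28 / 49)
assignment_offset <- function(window_size) {
  as.integer(floor(window_size / 2) + 1L)
}

#' Raw (unnormalized) score of one sequence window
#'
#' Sums all pairwise i,i+3 and i,i+4 interaction scores whose first residue
#' lies inside the window — including pairs from the window's last helical
#' turn to residues beyond the window end — plus the network-rule score of
#' every matching charged or hydrophobic triple whose first residue lies in
#' the window. Windows may overhang the sequence; overhanging positions are
#' neutral dummies.
#'
#' @param record a protein record (see [protein_record()]) or a plain
#'   residue string.
#' @param start 1-based window start (may be < 1 for overhanging windows).
#' @param window_size window length; must be one of the configured sizes.
#' @param config an `sah_config`.
#' @return the raw window score.
#' @export
window_raw_score <- function(record, start, window_size, config) {
  window_size <- as.integer(window_size)
  if (!(window_size %in% config$window_sizes)) {
    stop("window size ", window_size, " is not configured (configured: ",
         paste(config$window_sizes, collapse = ", "), ")")
  }
  seq <- if (is.list(record)) record$sequence else record
  window_raw_score_codes(aa_encode(seq), as.integer(start), window_size, config)
}

#' Per-residue normalized SAH-score profile
#'
#' For every residue r the window of the given size is anchored so that r
#' is the assignment position (residue `floor(w/2) + 1` of the window; 8,
#' 11, 15 and 25 for the default windows). Windows overhanging a terminus
#' are completed with neutral dummy residues, so the first and last few
#' scores decay towards the termini. Raw window scores are divided by the
#' configured normalization constant, pinning a perfect interior `EEEEKKK`
#' repeat at 1.0. Scores are not clamped: matrices rewarding a pattern more
#' strongly than `EEEEKKK` can exceed 1.
#'
#' @param record a protein record (see [protein_record()]) or a plain
#'   residue string.
#' @param window_size one of the configured window sizes.
#' @param config an `sah_config`.
#' @return object of class `sah_profile`: list with `seq_id`,
#'   `window_size`, `sequence` and `scores` (one per residue).
#' @examples
#' cfg <- sah_config()
#' p <- score_profile(make_perfect_sah(7), 21, cfg)
#' p$scores[25]  # interior residue of the perfect repeat: exactly 1
#' @export
score_profile <- function(record, window_size, config) {
  window_size <- as.integer(window_size)
  if (!(window_size %in% config$window_sizes)) {
    stop("window size ", window_size, " is not configured (configured: ",
         paste(config$window_sizes, collapse = ", "), ")")
  }
  if (is.list(record)) {
    seq <- record$sequence
    seq_id <- record$seq_id
  } else {
    seq <- record
    seq_id <- "seq"
  }
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1) {
    stop("empty sequence: a profile needs at least one residue")
  }
  codes <- aa_encode(seq)
  n <- length(codes)
  contrib <- position_contributions(codes, config)
  offset <- assignment_offset(window_size)
  cum <- c(0, cumsum(contrib))
  starts <- seq_len(n) - offset + 1L
  ends <- starts + window_size - 1L
  lo <- pmax(starts, 1L)
  hi <- pmin(ends, n)
  raw <- ifelse(lo > hi, 0, cum[hi + 1L] - cum[lo])
  norm <- config$max_window_scores[[as.character(window_size)]]
  structure(list(seq_id = seq_id, window_size = window_size,
                 sequence = seq, scores = as.numeric(raw) / norm),
            class = "sah_profile")
}

#' @export
print.sah_profile <- function(x, ...) {
  cat(sprintf("SAH-score profile for %s (%d aa, window %d)\n",
              x$seq_id, nchar(x$sequence), x$window_size))
  cat(sprintf("  score range: %.4f .. %.4f\n",
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Construct a protein record
#'
#' A light container for one protein sequence with optional gene and
#' transcript annotation. Trailing stop symbols (`*`) are stripped;
#' internal non-standard symbols (`X`, `U`, `B`, `Z`, `O`, `*`) are kept
#' and scored as neutral dummies.
#'
#' @param seq_id sequence identifier.
#' @param sequence residue string.
#' @param gene_id,transcript_id optional annotation (default: the record is
#'   its own single-transcript gene).
#' @return list of class `protein_record` with fields `seq_id`, `gene_id`,
#'   `transcript_id`, `sequence`, `length`.
#' @export
protein_record <- function(seq_id, sequence, gene_id = NA_character_,
                           transcript_id = NA_character_) {
  sequence <- sub("\\*+$", "", toupper(sequence))
  if (nchar(sequence) < 1) {
    stop("record ", seq_id, " has an empty sequence")
  }
  aa_encode(sequence)  # validates the alphabet
  structure(list(seq_id = as.character(seq_id),
                 gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 sequence = sequence,
                 length = nchar(sequence)),
            class = "protein_record")
}
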