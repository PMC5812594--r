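# Synthetic sequence generation: perfect repeats, planted-SAH datasets
# with ground truth, and bundled example records.

#' Perfect ER/K repeat sequence
#'
#' `EEEEKKK` repeated `n_repeats` times — the motif whose window score
#' defines the normalization constant (SAH-score 1 at interior residues).
#'
#' @param n_repeats number of heptads (>= 1).
#' @return residue string of length `7 * n_repeats`.
#' @examples
#' make_perfect_sah(2)
#' @export
make_perfect_sah <- function(n_repeats) {
  if (n_repeats < 1 || n_repeats != floor(n_repeats)) {
    stop("n_repeats must be a positive integer")
  }
  strrep("EEEEKKK", n_repeats)
}

.random_background <- function(n, alphabet) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a planted-SAH dataset with ground truth
#'
#' Writes a FASTA file of synthetic sequences — low-charge random
#' backgrounds with perfect `EEEEKKK` repeats planted at known offsets —
#' plus a TSV ground-truth table (seq id, insert coordinates). The
#' background alphabet contains no charged residues, so the planted
#' repeats are the only high-scoring regions. Optionally an isoform family
#' is added: one gene with four transcripts, two of which (identical
#' sequences) carry the same planted domain and two of which are
#' insert-free background, exercising the unique-domain comparison
#' (presence fraction 0.5).
#'
#' Identical seed and parameters produce byte-identical files.
#'
#' @param out_fasta output FASTA path.
#' @param out_truth output TSV path for the ground-truth table.
#' @param seed integer seed for the local RNG.
#' @param n_planted sequences with one planted insert each.
#' @param n_background pure-background sequences.
#' @param seq_length length of every generated sequence.
#' @param insert_repeats heptads per planted insert (default 5: 35 aa).
#' @param background background alphabet. The default `{G, S, T, A}` is
#'   charge-free and scores near zero, so detection boundaries reflect the
#'   scoring-window ramp alone; adding breakers/hydrophobics (e.g. `P`,
#'   `V`, `L`) makes flanks strongly negative and noisier.
#' @param margin minimum flank length on either side of an insert, so
#'   planted domains sit in full-window context away from the termini.
#' @param isoform_family add the 4-transcript isoform gene?
#' @return invisibly, the ground-truth data frame (`seq_id`, `gene_id`,
#'   `transcript_id`, `insert_start`, `insert_end`, `insert_seq`; `NA`
#'   coordinates for background-only sequences).
#' @export
make_planted_dataset <- function(out_fasta, out_truth = NULL, seed = 1L,
                                 n_planted = 3L, n_background = 4L,
                                 seq_length = 120L, insert_repeats = 5L,
                                 background = c("G", "S", "T", "A"),
                                 margin = 15L, isoform_family = TRUE) {
  insert <- make_perfect_sah(insert_repeats)
  ilen <- nchar(insert)
  if (ilen > seq_length) {
    stop("insert (", ilen, " aa) longer than the sequence (", seq_length,
         " aa)")
  }
  if (ilen + 2L * margin > seq_length) {
    stop("sequence too short for the insert plus terminal margins")
  }
  set.seed(as.integer(seed))
  rows <- list()
  plant_one <- function(sid, gid, tid, offset = NULL) {
    if (is.null(offset)) {
      offset <- sample(seq.int(margin + 1L, seq_length - ilen + 1L - margin),
                       1L)
    }
    left <- .random_background(offset - 1L, background)
    right <- .random_background(seq_length - ilen - offset + 1L, background)
    data.frame(seq_id = sid, gene_id = gid, transcript_id = tid,
               sequence = paste0(left, insert, right),
               insert_start = offset, insert_end = offset + ilen - 1L,
               insert_seq = insert, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_planted)) {
    sid <- sprintf("PLANT%03d", i)
    rows[[length(rows) + 1L]] <- plant_one(sid, sid, sid)
  }
  for (i in seq_len(n_background)) {
    sid <- sprintf("BKGD%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = sid, gene_id = sid, transcript_id = sid,
      sequence = .random_background(seq_length, background),
      insert_start = NA_integer_, insert_end = NA_integer_,
      insert_seq = NA_character_, stringsAsFactors = FALSE)
  }
  if (isoform_family) {
    shared <- plant_one("ISO_T1", "ISOGENE", "ISO_T1")
    iso2 <- shared
    iso2$seq_id <- iso2$transcript_id <- "ISO_T2"
    rows[[length(rows) + 1L]] <- shared
    rows[[length(rows) + 1L]] <- iso2
    for (tid in c("ISO_T3", "ISO_T4")) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = tid, gene_id = "ISOGENE", transcript_id = tid,
        sequence = .random_background(seq_length, background),
        insert_start = NA_integer_, insert_end = NA_integer_,
        insert_seq = NA_character_, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  write_fasta(truth, out_fasta)
  if (!is.null(out_truth)) {
    .write_tsv(truth[, c("seq_id", "gene_id", "transcript_id",
                         "insert_start", "insert_end", "insert_seq")],
               out_truth)
  }
  invisible(truth)
}

#' Bundled example records
#'
#' Returns packaged example sequences: the 62-residue SAH-domain region of
#' human myosin-10 (Myo10, translation ENSP00000421280), which carries the
#' most common human SAH heptad `RERERER`, and a 49-residue perfect
#' `EEEEKKK` repeat for reference.
#'
#' @return data frame of records (`seq_id`, `gene_id`, `transcript_id`,
#'   `sequence`, `length`, `valid`); ids are stable across calls.
#' @examples
#' bundled_examples()$seq_id
#' @export
bundled_examples <- function() {
  myo10 <- paste0("AEKREQEEKKKQEEEEKKKREEEERERERERREAELRAQQEEETRKQQELEA",
                  "LQKSQKEAEL")
  data.frame(
    seq_id = c("ENSP00000421280_SAH", "PERFECT_SAH_49"),
    gene_id = c("MYO10", "PERFECT_SAH_49"),
    transcript_id = c("ENSP00000421280", "PERFECT_SAH_49"),
    sequence = c(myo10, make_perfect_sah(7L)),
    length = c(nchar(myo10), 49L),
    valid = c(TRUE, TRUE),
    stringsAsFactors = FALSE)
}
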