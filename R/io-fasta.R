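# FASTA input with Ensembl-style header parsing.

#' Read a protein multi-FASTA file
#'
#' Records are streamed through Biostrings; trailing stop symbols (`*`)
#' are stripped; `gene:<ID>` and `transcript:<ID>` tokens in the header are
#' parsed when present, otherwise each sequence is its own
#' single-transcript gene (gene id = transcript id = sequence id).
#' Sequences shorter than `min_length` (by default the smallest scoring
#' window) are flagged invalid and excluded from scoring but kept in the
#' table so run reports can count them.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param min_length minimum residue count for a record to be scorable.
#' @return data frame with columns `seq_id`, `gene_id`, `transcript_id`,
#'   `sequence`, `length`, `valid`.
#' @export
read_fasta <- function(path, min_length = 14L) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    stop("FASTA file contains no records: ", path)
  }
  headers <- names(set)
  seq_id <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  grab <- function(tok) {
    m <- regmatches(headers, regexpr(paste0(tok, ":[^ \t]+"), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(tok, ":"), headers)
    out[hit] <- sub(paste0("^", tok, ":"), "", m)
    out
  }
  gene_id <- grab("gene")
  transcript_id <- grab("transcript")
  transcript_id[is.na(transcript_id)] <- seq_id[is.na(transcript_id)]
  gene_id[is.na(gene_id)] <- transcript_id[is.na(gene_id)]
  seqs <- sub("\\*+$", "", toupper(as.character(set)))
  data.frame(seq_id = seq_id, gene_id = gene_id,
             transcript_id = transcript_id, sequence = unname(seqs),
             length = nchar(unname(seqs)),
             valid = nchar(unname(seqs)) >= min_length,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTA
#'
#' @param records data frame with `seq_id`, `sequence` and optionally
#'   `gene_id` / `transcript_id` (emitted as Ensembl-style header tokens).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- records$seq_id
  if (!is.null(records$gene_id)) {
    extra <- ifelse(is.na(records$gene_id), "",
                    paste0(" gene:", records$gene_id))
    if (!is.null(records$transcript_id)) {
      extra <- paste0(extra, ifelse(is.na(records$transcript_id), "",
                                    paste0(" transcript:",
                                           records$transcript_id)))
    }
    headers <- paste0(headers, extra)
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
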