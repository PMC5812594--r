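# Persistent result store.
#
# Prediction and analysis are separate stages: prediction parses, scores
# and persists once; analyses can be re-run later with different cutoffs
# without re-scoring. The store is a directory of plain TSV tables plus a
# YAML snapshot of the configuration (including matrix CSV copies), laid
# out as <out_dir>/<run_id>/store/.

.store_dir <- function(out_dir, run_id) {
  file.path(out_dir, run_id, "store")
}

#' Does a result store exist for this run id?
#'
#' @param out_dir results directory.
#' @param run_id working title of the run.
#' @return logical.
#' @export
store_exists <- function(out_dir, run_id) {
  file.exists(file.path(.store_dir(out_dir, run_id), "sequences.tsv"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "", colClasses = NA,
                    fileEncoding = "UTF-8")
}

# profiles: one row per (seq_id, window_size); scores serialized at full
# precision so that reloading reproduces them exactly
.serialize_scores <- function(x) paste(sprintf("%.17g", x), collapse = ",")
.deserialize_scores <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

#' Save a prediction run to its store
#'
#' @param run a `sah_run` as returned by [cmd_predict()].
#' @param out_dir results directory.
#' @param overwrite replace an existing store for the same run id?
#' @return the store directory, invisibly.
#' @export
save_store <- function(run, out_dir, overwrite = FALSE) {
  dir <- .store_dir(out_dir, run$run_id)
  if (store_exists(out_dir, run$run_id) && !overwrite) {
    stop("a result store for run id '", run$run_id, "' already exists ",
         "under ", out_dir, "; use overwrite to replace it")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- run$sequences
  seqs$sequence <- NULL  # sequences live in the profile/domain tables
  .write_tsv(seqs, file.path(dir, "sequences.tsv"))
  prof <- run$profiles
  prof_tab <- data.frame(seq_id = vapply(prof, `[[`, "", "seq_id"),
                         window_size = vapply(prof, `[[`, 0L, "window_size"),
                         sequence = vapply(prof, `[[`, "", "sequence"),
                         scores = vapply(prof, function(p)
                           .serialize_scores(p$scores), ""),
                         stringsAsFactors = FALSE)
  .write_tsv(prof_tab, file.path(dir, "profiles.tsv"))
  dom <- run$domains
  dom$residue_scores <- vapply(dom$residue_scores, .serialize_scores, "")
  .write_tsv(dom, file.path(dir, "domains.tsv"))
  write_config_file(run$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a prediction run from its store
#'
#' @param out_dir results directory.
#' @param run_id working title of the run.
#' @return a `sah_run`: list with `run_id`, `sequences`, `profiles`
#'   (list of `sah_profile`), `domains` and `config`.
#' @export
load_store <- function(out_dir, run_id) {
  dir <- .store_dir(out_dir, run_id)
  if (!store_exists(out_dir, run_id)) {
    stop("no result store for run id '", run_id, "' at ", dir)
  }
  sequences <- .read_tsv(file.path(dir, "sequences.tsv"))
  prof_tab <- .read_tsv(file.path(dir, "profiles.tsv"))
  profiles <- lapply(seq_len(nrow(prof_tab)), function(i) {
    structure(list(seq_id = prof_tab$seq_id[i],
                   window_size = as.integer(prof_tab$window_size[i]),
                   sequence = prof_tab$sequence[i],
                   scores = .deserialize_scores(prof_tab$scores[i])),
              class = "sah_profile")
  })
  domains <- .read_tsv(file.path(dir, "domains.tsv"))
  if (nrow(domains) > 0) {
    domains$residue_scores <- I(lapply(domains$residue_scores,
                                       .deserialize_scores))
    domains$seq_id <- as.character(domains$seq_id)
    domains$subsequence <- as.character(domains$subsequence)
  } else {
    domains <- .empty_domains()
  }
  config <- read_config_file(file.path(dir, "config.yaml"))
  structure(list(run_id = run_id, sequences = sequences,
                 profiles = profiles, domains = domains, config = config),
            class = "sah_run")
}
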