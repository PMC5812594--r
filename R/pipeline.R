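# Pipeline stages: predict (parse + score + detect + persist) and analyze
# (re-filter + analytics + reports). The stages are separable: a combined
# run and predict-then-analyze produce identical stores and reports.

#' Predict SAH-domains for a FASTA dataset and persist the results
#'
#' Reads the FASTA file, scores every valid sequence for every requested
#' window size, detects and filters SAH-domains, and saves everything
#' (sequences, score profiles of domain-bearing sequences, domains,
#' configuration snapshot) to the result store
#' `<out_dir>/<run_id>/store/`. Only results above the cutoffs are kept.
#'
#' @param input_fasta protein multi-FASTA path.
#' @param run_id working title of the run; names the results subfolder.
#' @param out_dir results directory (created if needed).
#' @param config an `sah_config`.
#' @param window_sizes windows to scan (subset of the configured ones).
#' @param overwrite replace an existing store with the same run id?
#' @param quiet suppress the per-run summary on stderr?
#' @return a `sah_run` (list with `run_id`, `sequences`, `profiles`,
#'   `domains`, `config`), invisibly.
#' @export
cmd_predict <- function(input_fasta, run_id, out_dir,
                        config = sah_config(),
                        window_sizes = config$window_sizes,
                        overwrite = FALSE, quiet = FALSE) {
  window_sizes <- as.integer(window_sizes)
  bad <- setdiff(window_sizes, config$window_sizes)
  if (length(bad) > 0) {
    stop("requested window size(s) not configured: ",
         paste(bad, collapse = ", "))
  }
  if (store_exists(out_dir, run_id) && !overwrite) {
    stop("a result store for run id '", run_id, "' already exists under ",
         out_dir, "; use overwrite = TRUE to replace it")
  }
  sequences <- read_fasta(input_fasta, min_length = min(config$window_sizes))
  profiles <- list()
  dom_list <- list()
  for (i in which(sequences$valid)) {
    rec <- structure(list(seq_id = sequences$seq_id[i],
                          sequence = sequences$sequence[i]),
                     class = "protein_record")
    keep_profiles <- list()
    has_domain <- FALSE
    for (w in window_sizes) {
      prof <- score_profile(rec, w, config)
      doms <- filter_domains(detect_domains(prof, config), config)
      keep_profiles[[as.character(w)]] <- prof
      if (nrow(doms) > 0) {
        has_domain <- TRUE
        dom_list[[length(dom_list) + 1L]] <- doms
      }
    }
    # profiles are persisted only for domain-bearing sequences
    if (has_domain) {
      profiles <- c(profiles, unname(keep_profiles))
    }
  }
  domains <- if (length(dom_list) > 0) {
    do.call(rbind, dom_list)
  } else {
    .empty_domains()
  }
  run <- structure(list(run_id = run_id, sequences = sequences,
                        profiles = profiles, domains = domains,
                        config = config),
                   class = "sah_run")
  save_store(run, out_dir, overwrite = overwrite)
  if (!quiet) {
    message(sprintf(
      "run %s: %d sequences (%d valid, %d with SAH-domains); %s",
      run_id, nrow(sequences), sum(sequences$valid),
      length(unique(domains$seq_id)),
      paste(sprintf("window %s: %d domains", window_sizes,
                    vapply(window_sizes, function(w)
                      sum(domains$window_size == w), 0L)),
            collapse = ", ")))
  }
  invisible(run)
}

#' Analyze a stored prediction run and write reports
#'
#' Loads the result store, re-detects domains from the stored score
#' profiles under the active configuration (so cutoffs can be tightened
#' without re-scoring), runs the dataset analytics and writes all summary
#' tables and per-sequence reports. With no overrides this reproduces the
#' prediction-stage domains and reports exactly.
#'
#' @param run_id working title of the stored run.
#' @param out_dir results directory holding the store.
#' @param residue_cutoff,domain_score_cutoffs optional overrides of the
#'   stored configuration.
#' @param window_sizes windows to report (default: all stored).
#' @param top_heptads rows in the heptad-frequency tables.
#' @param svg also write SVG profile plots for domain-bearing sequences?
#' @return list with `run`, `domains`, `uniques`, `tables` (per-window
#'   analytics), invisibly.
#' @export
cmd_analyze <- function(run_id, out_dir, residue_cutoff = NULL,
                        domain_score_cutoffs = NULL,
                        window_sizes = NULL, top_heptads = 10L,
                        svg = FALSE) {
  run <- load_store(out_dir, run_id)
  config <- run$config
  if (!is.null(residue_cutoff)) config$residue_cutoff <- residue_cutoff
  if (!is.null(domain_score_cutoffs)) {
    config$domain_score_cutoffs[names(domain_score_cutoffs)] <-
      domain_score_cutoffs
  }
  if (is.null(window_sizes)) window_sizes <- config$window_sizes
  window_sizes <- as.integer(window_sizes)
  config$window_sizes <- window_sizes
  # re-detect from stored profiles under the active cutoffs
  dom_list <- lapply(run$profiles, function(prof) {
    if (!(prof$window_size %in% window_sizes)) return(NULL)
    filter_domains(detect_domains(prof, config), config)
  })
  dom_list <- Filter(function(d) !is.null(d) && nrow(d) > 0, dom_list)
  domains <- if (length(dom_list) > 0) {
    do.call(rbind, dom_list)
  } else {
    .empty_domains()
  }
  report_run <- run
  report_run$config <- config
  write_reports(report_run, out_dir, domains = domains,
                top_heptads = top_heptads)
  # gene-level unique-domain comparison
  gene_map <- stats::setNames(run$sequences$gene_id,
                              run$sequences$seq_id)
  transcript_counts <- vapply(split(run$sequences$seq_id,
                                    run$sequences$gene_id),
                              length, 0L)
  tables <- list()
  for (w in window_sizes) {
    dw <- domains[domains$window_size == w, , drop = FALSE]
    uniq <- unique_domains(dw, gene_map, transcript_counts,
                           min_overlap_aa = config$min_overlap_aa)
    .write_tsv(cbind(uniq[, c("gene_id", "sequence", "n_carriers",
                              "gene_transcript_count")],
                     presence_fraction = .fmt4(uniq$presence_fraction),
                     uniq[, c("including", "included", "overlapping")]),
               file.path(out_dir, run_id, paste0("window_", w),
                         "unique_domains.tsv"))
    tables[[as.character(w)]] <- list(
      domains = dw, uniques = uniq,
      counts = multi_domain_counts(dw),
      lengths = length_histogram(run$sequences, dw))
  }
  if (svg) {
    pdir <- file.path(out_dir, run_id, "plots")
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    for (prof in run$profiles) {
      if (!(prof$window_size %in% window_sizes)) next
      stem <- sprintf("%s_w%d", gsub("[^A-Za-z0-9._-]", "_", prof$seq_id),
                      prof$window_size)
      export_profile_plot(prof, domains, file.path(pdir, paste0(stem, ".tsv")),
                          svg = TRUE, residue_cutoff = config$residue_cutoff)
    }
  }
  invisible(list(run = run, domains = domains, tables = tables))
}
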