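# Report writing: per-window summary tables, per-sequence text reports and
# profile plot exports (TSV always, native SVG on request).

.fmt4 <- function(x) sprintf("%.4f", x)

#' Write all result tables and per-sequence reports for a run
#'
#' Creates `<out_dir>/<run_id>/window_<w>/` for every window size with:
#' `composition.tsv` (amino-acid distribution over SAH residues),
#' `domains_by_length.tsv` (predicted domains ordered by length),
#' `domains_detailed.tsv` (coordinates, subsequence, per-residue scores,
#' SAH-domain-score), `heptad_frequency.tsv` and `summary.tsv`; plus one
#' plain-text report per sequence with at least one retained domain under
#' `<out_dir>/<run_id>/sequences/`. Tables are TSV, UTF-8, header row,
#' 1-based inclusive coordinates, scores printed to 4 decimals. Outputs
#' are deterministic: identical runs produce byte-identical files.
#'
#' @param run a `sah_run` (see [cmd_predict()] / [load_store()]).
#' @param out_dir results directory.
#' @param domains optional domain table to report (default: the run's
#'   retained domains).
#' @param top_heptads rows kept in the heptad table per window.
#' @return character vector of files written, invisibly.
#' @export
write_reports <- function(run, out_dir, domains = run$domains,
                          top_heptads = 10L) {
  base <- file.path(out_dir, run$run_id)
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (w in run$config$window_sizes) {
    wdir <- file.path(base, paste0("window_", w))
    dir.create(wdir, showWarnings = FALSE)
    dw <- domains[domains$window_size == w, , drop = FALSE]
    # composition
    comp_path <- file.path(wdir, "composition.tsv")
    if (nrow(dw) > 0) {
      comp <- composition(dw)
      comp_df <- data.frame(residue = AA_ORDER,
                            count = comp$counts,
                            fraction = .fmt4(comp$fractions))
      comp_df <- rbind(comp_df,
                       data.frame(residue = "charged_polar",
                                  count = NA_integer_,
                                  fraction = .fmt4(comp$charged_polar_fraction)),
                       data.frame(residue = "heptad_equivalent",
                                  count = NA_integer_,
                                  fraction = .fmt4(comp$heptad_equivalent)))
    } else {
      comp_df <- data.frame(residue = character(0), count = integer(0),
                            fraction = character(0))
    }
    .write_tsv(comp_df, comp_path)
    # domains by length
    bylen <- dw[order(-dw$length, dw$seq_id, dw$start),
                c("seq_id", "start", "end", "length", "domain_score"),
                drop = FALSE]
    bylen$domain_score <- .fmt4(bylen$domain_score)
    if (nrow(bylen) == 0) bylen$domain_score <- character(0)
    .write_tsv(bylen, file.path(wdir, "domains_by_length.tsv"))
    # detailed domain list
    det <- dw[order(dw$seq_id, dw$start),
              c("seq_id", "window_size", "start", "end", "length",
                "subsequence", "domain_score", "below_cutoff_fraction"),
              drop = FALSE]
    det$domain_score <- .fmt4(dw$domain_score[order(dw$seq_id, dw$start)])
    det$below_cutoff_fraction <-
      .fmt4(dw$below_cutoff_fraction[order(dw$seq_id, dw$start)])
    det$residue_scores <- vapply(
      dw$residue_scores[order(dw$seq_id, dw$start)],
      function(x) paste(.fmt4(x), collapse = ","), "")
    if (nrow(det) == 0) {
      det$domain_score <- character(0)
      det$below_cutoff_fraction <- character(0)
      det$residue_scores <- character(0)
    }
    .write_tsv(det, file.path(wdir, "domains_detailed.tsv"))
    # heptad ranking
    .write_tsv(heptad_frequency(dw, top_heptads),
               file.path(wdir, "heptad_frequency.tsv"))
    # summary counts
    counts <- multi_domain_counts(dw)
    counts$window_size <- w
    counts$n_sequences_total <- nrow(run$sequences)
    counts$n_sequences_valid <- sum(run$sequences$valid)
    .write_tsv(counts, file.path(wdir, "summary.tsv"))
    written <- c(written, comp_path)
  }
  # per-sequence text reports, only for sequences with retained domains
  sdir <- file.path(base, "sequences")
  dir.create(sdir, showWarnings = FALSE)
  for (sid in sort(unique(domains$seq_id))) {
    ds <- domains[domains$seq_id == sid, , drop = FALSE]
    ds <- ds[order(ds$window_size, ds$start), , drop = FALSE]
    path <- file.path(sdir, paste0(gsub("[^A-Za-z0-9._-]", "_", sid), ".txt"))
    lines <- c(sprintf("Sequence: %s", sid),
               sprintf("SAH-domains: %d", nrow(ds)), "")
    for (i in seq_len(nrow(ds))) {
      lines <- c(lines,
        sprintf("window %d aa | residues %d-%d (%d aa) | SAH-domain-score %s",
                ds$window_size[i], ds$start[i], ds$end[i], ds$length[i],
                .fmt4(ds$domain_score[i])),
        ds$subsequence[i],
        paste(.fmt4(ds$residue_scores[[i]]), collapse = ","),
        "")
    }
    writeLines(lines, path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Export a score profile as plot data and optional SVG
#'
#' Always writes a two-column TSV (`position`, `score`) at full precision,
#' so reimporting reproduces the profile exactly. With `svg = TRUE` a
#' self-contained SVG line plot is written next to it, with detected
#' domain spans shaded and the residue cutoff drawn as a dashed line.
#'
#' @param profile an `sah_profile`.
#' @param domains optional domain table for shading (rows with other
#'   `window_size`s are ignored).
#' @param out_path path of the TSV; the SVG replaces the extension.
#' @param svg write the SVG plot as well?
#' @param residue_cutoff cutoff drawn in the plot.
#' @return paths written, invisibly.
#' @export
export_profile_plot <- function(profile, domains = NULL, out_path,
                                svg = FALSE, residue_cutoff = 0.25) {
  df <- data.frame(position = seq_along(profile$scores),
                   score = sprintf("%.17g", profile$scores))
  .write_tsv(df, out_path)
  paths <- out_path
  if (svg) {
    svg_path <- paste0(tools::file_path_sans_ext(out_path), ".svg")
    .write_profile_svg(profile, domains, svg_path, residue_cutoff)
    paths <- c(paths, svg_path)
  }
  invisible(paths)
}

# minimal self-contained SVG line plot
.write_profile_svg <- function(profile, domains, path, residue_cutoff) {
  n <- length(profile$scores)
  width <- 900; height <- 300
  pad <- 40
  ymin <- min(0, profile$scores); ymax <- max(1, profile$scores)
  xs <- pad + (seq_len(n) - 1) / max(1, n - 1) * (width - 2 * pad)
  ys <- height - pad - (profile$scores - ymin) / (ymax - ymin) *
    (height - 2 * pad)
  cy <- height - pad - (residue_cutoff - ymin) / (ymax - ymin) *
    (height - 2 * pad)
  shade <- ""
  if (!is.null(domains) && nrow(domains) > 0) {
    dw <- domains[domains$window_size == profile$window_size &
                  domains$seq_id == profile$seq_id, , drop = FALSE]
    shade <- paste(vapply(seq_len(nrow(dw)), function(i) {
      x1 <- pad + (dw$start[i] - 1) / max(1, n - 1) * (width - 2 * pad)
      x2 <- pad + (dw$end[i] - 1) / max(1, n - 1) * (width - 2 * pad)
      sprintf(paste0('<rect class="domain" x="%.1f" y="%d" width="%.1f" ',
                     'height="%d" fill="#9ecae1" fill-opacity="0.5"/>'),
              x1, pad, x2 - x1, height - 2 * pad)
    }, ""), collapse = "\n")
  }
  poly <- paste(sprintf("%.1f,%.1f", xs, ys), collapse = " ")
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<title>SAH-score profile %s (window %d)</title>',
            profile$seq_id, profile$window_size),
    '<rect width="100%" height="100%" fill="white"/>',
    shade,
    sprintf('<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="grey" stroke-dasharray="4 3"/>',
            pad, cy, width - pad, cy),
    sprintf('<polyline points="%s" fill="none" stroke="#08519c" stroke-width="1.5"/>',
            poly),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            pad, height - pad, width - pad, height - pad),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            pad, pad, pad, height - pad),
    '</svg>')
  writeLines(svg, path)
  invisible(path)
}
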