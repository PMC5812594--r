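# Scoring configuration: matrices, network rules, windows, cutoffs and the
# per-window normalization constants.

.default_domain_cutoffs <- c("14" = 0.35, "21" = 0.32, "28" = 0.29, "49" = 0.25)

#' Assemble a scoring configuration
#'
#' Bundles the interaction matrices, network scores, window sizes and all
#' filtering cutoffs, and computes the per-window normalization constants:
#' the raw score of a window laid over a perfect `EEEEKKK` repeat, which is
#' defined to normalize to 1. Rescaling both matrices and network scores by
#' a common positive factor therefore leaves all normalized scores
#' unchanged.
#'
#' @param matrix_i3,matrix_i4 20x20 interaction matrices for i,i+3 and
#'   i,i+4 spacings (default: the built-in matrices).
#' @param window_sizes integer vector of scoring window lengths.
#' @param residue_cutoff minimum normalized per-residue SAH-score for a
#'   residue to belong to an SAH-domain (in (0, 1)).
#' @param domain_score_cutoffs named numeric vector, minimum
#'   SAH-domain-score per window size. Windows 14 and 49 default to 0.35
#'   and 0.25; intermediate windows are linearly interpolated on window
#'   size (21 -> 0.32, 28 -> 0.29).
#' @param domain_subwindow sub-window length (residues) for the
#'   SAH-domain-score; capped at the smallest window size.
#' @param below_cutoff_tolerance maximum fraction of residues inside a
#'   domain allowed at or below `residue_cutoff` (in [0, 1)).
#' @param min_overlap_aa minimum terminal overlap (residues) for two unique
#'   domains of a gene to count as overlapping.
#' @param network_charged positive score added per alternating
#'   oppositely-charged triple (members of {D,E} vs {K,R}) in
#'   (i,i+3,i+6), (i,i+3,i+7), (i,i+4,i+7) or (i,i+4,i+8) spacing.
#' @param network_hydrophobic negative score added per all-hydrophobic
#'   ({V,I,L,M,F,Y}) triple in the same spacings (a coiled-coil seam
#'   signature, hence destabilizing for SAH calls).
#' @return object of class `sah_config`; a list that additionally carries
#'   `max_window_scores`, the computed normalization constants.
#' @examples
#' cfg <- sah_config()
#' cfg$max_window_scores
#' @export
sah_config <- function(matrix_i3 = default_scoring_matrix("i3"),
                       matrix_i4 = default_scoring_matrix("i4"),
                       window_sizes = c(14L, 21L, 28L, 49L),
                       residue_cutoff = 0.25,
                       domain_score_cutoffs = NULL,
                       domain_subwindow = 14L,
                       below_cutoff_tolerance = 0.20,
                       min_overlap_aa = 5L,
                       network_charged = 0.25,
                       network_hydrophobic = -0.25) {
  stopifnot(is.matrix(matrix_i3), all(dim(matrix_i3) == 20),
            is.matrix(matrix_i4), all(dim(matrix_i4) == 20))
  if (!all(AA_ORDER %in% rownames(matrix_i3)) ||
      !all(AA_ORDER %in% rownames(matrix_i4))) {
    stop("scoring matrices must be labelled with the 20 standard residues")
  }
  matrix_i3 <- unclass(matrix_i3)[AA_ORDER, AA_ORDER]
  matrix_i4 <- unclass(matrix_i4)[AA_ORDER, AA_ORDER]
  if (any(!is.finite(matrix_i3)) || any(!is.finite(matrix_i4))) {
    stop("scoring matrices must be finite")
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (length(window_sizes) == 0 || any(window_sizes < 7)) {
    stop("window sizes must be integers >= 7")
  }
  if (!(residue_cutoff > 0 && residue_cutoff < 1)) {
    stop("residue_cutoff must lie in (0, 1)")
  }
  if (!(below_cutoff_tolerance >= 0 && below_cutoff_tolerance < 1)) {
    stop("below_cutoff_tolerance must lie in [0, 1)")
  }
  if (network_charged < 0) {
    stop("the charged network score must be >= 0")
  }
  if (network_hydrophobic > 0) {
    stop("the hydrophobic network score must be <= 0")
  }
  if (is.null(domain_score_cutoffs)) {
    # canonical windows use the fixed defaults; any other window size is
    # interpolated between the 14 aa and 49 aa endpoints
    domain_score_cutoffs <- stats::setNames(
      round(stats::approx(x = c(14, 49), y = c(0.35, 0.25),
                          xout = pmin(pmax(window_sizes, 14), 49))$y, 2),
      window_sizes)
    known <- intersect(names(.default_domain_cutoffs), names(domain_score_cutoffs))
    domain_score_cutoffs[known] <- .default_domain_cutoffs[known]
  }
  missing_cut <- setdiff(as.character(window_sizes), names(domain_score_cutoffs))
  if (length(missing_cut) > 0) {
    stop("no SAH-domain-score cutoff for window size(s): ",
         paste(missing_cut, collapse = ", "))
  }
  cfg <- structure(list(
    matrix_i3 = matrix_i3,
    matrix_i4 = matrix_i4,
    window_sizes = window_sizes,
    residue_cutoff = residue_cutoff,
    domain_score_cutoffs = domain_score_cutoffs,
    domain_subwindow = as.integer(min(domain_subwindow, min(window_sizes))),
    below_cutoff_tolerance = below_cutoff_tolerance,
    min_overlap_aa = as.integer(min_overlap_aa),
    network_charged = network_charged,
    network_hydrophobic = network_hydrophobic
  ), class = "sah_config")
  cfg$max_window_scores <- stats::setNames(
    vapply(window_sizes, function(w) compute_normalization(cfg, w), 0),
    window_sizes)
  if (any(cfg$max_window_scores <= 0)) {
    stop("matrices cannot normalize: a perfect EEEEKKK repeat does not ",
         "obtain a positive window score under the supplied matrices")
  }
  cfg
}

#' @export
print.sah_config <- function(x, ...) {
  cat("SAH scoring configuration\n")
  cat("  windows:          ", paste(x$window_sizes, collapse = ", "), "\n")
  cat("  residue cutoff:   ", x$residue_cutoff, "\n")
  cat("  domain cutoffs:   ",
      paste(sprintf("%s aa -> %.2f", names(x$domain_score_cutoffs),
                    x$domain_score_cutoffs), collapse = ", "), "\n")
  cat("  domain sub-window:", x$domain_subwindow, "\n")
  cat("  gap tolerance:    ", x$below_cutoff_tolerance, "\n")
  cat("  network scores:   ", sprintf("charged %+.2f, hydrophobic %+.2f",
                                      x$network_charged, x$network_hydrophobic), "\n")
  cat("  normalization:    ",
      paste(sprintf("%s aa -> %.4g", names(x$max_window_scores),
                    x$max_window_scores), collapse = ", "), "\n")
  invisible(x)
}

#' Normalization constant for one window size
#'
#' Raw (unnormalized) score of a window of `window_size` residues starting
#' at the first residue of a long perfect `EEEEKKK` repeat, under exactly
#' the same window-scoring rules as real sequences (including the
#' trailing-turn pairs reaching past the window end). Normalized profiles
#' divide by this constant, which pins the perfect repeat at score 1.
#'
#' @param config an `sah_config` (the matrices and network scores are read
#'   from it; its stored constants are not).
#' @param window_size window length in residues.
#' @return the raw window score (a positive number for usable matrices).
#' @export
compute_normalization <- function(config, window_size) {
  n_rep <- ceiling((window_size + 8) / 7) + 1
  codes <- aa_encode(strrep("EEEEKKK", n_rep))
  window_raw_score_codes(codes, 1L, as.integer(window_size), config)
}

#' Read a scoring configuration from a YAML file
#'
#' The file is a flat key/value document; recognised keys are
#' `matrix_i3`, `matrix_i4` (CSV paths, relative paths resolved against the
#' config file's directory), `window_sizes`, `residue_cutoff`,
#' `domain_score_cutoffs` (mapping window -> cutoff), `domain_subwindow`,
#' `below_cutoff_tolerance`, `min_overlap_aa`, `network_charged` and
#' `network_hydrophobic`. Absent keys fall back to the package defaults.
#'
#' @param path YAML file.
#' @return an `sah_config`.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  args <- list()
  if (!is.null(doc$matrix_i3)) {
    args$matrix_i3 <- load_scoring_matrix(resolve(doc$matrix_i3), "i3")
  }
  if (!is.null(doc$matrix_i4)) {
    args$matrix_i4 <- load_scoring_matrix(resolve(doc$matrix_i4), "i4")
  }
  if (!is.null(doc$window_sizes)) args$window_sizes <- as.integer(doc$window_sizes)
  if (!is.null(doc$residue_cutoff)) args$residue_cutoff <- doc$residue_cutoff
  if (!is.null(doc$domain_score_cutoffs)) {
    args$domain_score_cutoffs <- unlist(doc$domain_score_cutoffs)
  }
  if (!is.null(doc$domain_subwindow)) args$domain_subwindow <- doc$domain_subwindow
  if (!is.null(doc$below_cutoff_tolerance)) {
    args$below_cutoff_tolerance <- doc$below_cutoff_tolerance
  }
  if (!is.null(doc$min_overlap_aa)) args$min_overlap_aa <- doc$min_overlap_aa
  if (!is.null(doc$network_charged)) args$network_charged <- doc$network_charged
  if (!is.null(doc$network_hydrophobic)) {
    args$network_hydrophobic <- doc$network_hydrophobic
  }
  do.call(sah_config, args)
}

#' Write a scoring configuration (and its matrices) to disk
#'
#' Serializes the scalar settings to YAML and the two matrices to CSV files
#' next to it, so that [read_config_file()] reproduces the configuration.
#'
#' @param config an `sah_config`.
#' @param path output YAML path; matrices are written to
#'   `scoring_matrix_i_3.csv` / `scoring_matrix_i_4.csv` in the same
#'   directory.
#' @return `path`, invisibly.
#' @export
write_config_file <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  m3 <- file.path(dirname(path), "scoring_matrix_i_3.csv")
  m4 <- file.path(dirname(path), "scoring_matrix_i_4.csv")
  write_scoring_matrix(config$matrix_i3, m3)
  write_scoring_matrix(config$matrix_i4, m4)
  doc <- list(
    matrix_i3 = basename(m3),
    matrix_i4 = basename(m4),
    window_sizes = as.integer(config$window_sizes),
    residue_cutoff = config$residue_cutoff,
    domain_score_cutoffs = as.list(config$domain_score_cutoffs),
    domain_subwindow = config$domain_subwindow,
    below_cutoff_tolerance = config$below_cutoff_tolerance,
    min_overlap_aa = config$min_overlap_aa,
    network_charged = config$network_charged,
    network_hydrophobic = config$network_hydrophobic
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
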