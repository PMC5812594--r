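# Segmentation of score profiles into SAH-domains and domain scoring.

# max over all rolling means of length k (k <= length(x))
.max_rolling_mean <- function(x, k) {
  n <- length(x)
  cum <- c(0, cumsum(x))
  max((cum[(k + 1):(n + 1)] - cum[1:(n - k + 1)]) / k)
}

#' Length-independent SAH-domain-score
#'
#' The SAH-domain-score of a candidate is the maximum, over all contiguous
#' sub-windows of `subwindow` residues inside the domain, of the mean
#' per-residue SAH-score; a domain of length L yields `L - subwindow + 1`
#' sub-window means. Averaging over a fixed-length sub-window keeps short
#' and long domains comparable.
#'
#' @param scores numeric vector of per-residue SAH-scores of the candidate.
#' @param subwindow sub-window length (default 14).
#' @return the SAH-domain-score.
#' @examples
#' sah_domain_score(rep(0.3, 20))  # mean of constants: 0.3
#' @export
sah_domain_score <- function(scores, subwindow = 14L) {
  subwindow <- as.integer(subwindow)
  if (length(scores) < subwindow) {
    stop("candidate shorter (", length(scores),
         ") than the domain sub-window (", subwindow, ")")
  }
  .max_rolling_mean(scores, subwindow)
}

.empty_domains <- function() {
  data.frame(seq_id = character(0), window_size = integer(0),
             start = integer(0), end = integer(0),
             length = integer(0), subsequence = character(0),
             domain_score = numeric(0), below_cutoff_fraction = numeric(0),
             residue_scores = I(list()), stringsAsFactors = FALSE)
}

#' Detect SAH-domain candidates in a score profile
#'
#' Candidate spans must start and end with residues strictly above the
#' per-residue cutoff, contain at most the tolerated fraction of residues
#' at or below the cutoff, and be at least as long as the scoring window
#' (the window size sets the minimum detectable domain length). Spans are
#' built deterministically: maximal above-cutoff runs are listed left to
#' right and greedily merged with the next run whenever the union span
#' (including the gap) keeps the below-cutoff fraction within tolerance —
#' this keeps long domains from splitting over one or a few weak residues.
#' Candidates are not yet filtered by SAH-domain-score; see
#' [filter_domains()].
#'
#' @param profile an `sah_profile` from [score_profile()].
#' @param config the `sah_config` the profile was computed with.
#' @return data frame of candidate domains (possibly empty), sorted by
#'   start coordinate, with columns `seq_id`, `window_size`, `start`,
#'   `end`, `length`, `subsequence`, `domain_score`,
#'   `below_cutoff_fraction` and the list column `residue_scores`.
#' @export
detect_domains <- function(profile, config) {
  scores <- profile$scores
  cutoff <- config$residue_cutoff
  above <- scores > cutoff
  if (!any(above)) return(.empty_domains())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_start <- starts[runs$values]
  run_end <- ends[runs$values]
  # greedy left-to-right merge under the gap tolerance
  spans <- list()
  cur_s <- run_start[1]
  cur_e <- run_end[1]
  for (k in seq_along(run_start)[-1]) {
    union_len <- run_end[k] - cur_s + 1L
    n_below <- sum(!above[cur_s:run_end[k]])
    if (n_below / union_len <= config$below_cutoff_tolerance) {
      cur_e <- run_end[k]
    } else {
      spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
      cur_s <- run_start[k]
      cur_e <- run_end[k]
    }
  }
  spans[[length(spans) + 1L]] <- c(cur_s, cur_e)
  spans <- Filter(function(sp) sp[2] - sp[1] + 1L >= profile$window_size, spans)
  if (length(spans) == 0) return(.empty_domains())
  subwindow <- min(config$domain_subwindow, profile$window_size)
  rows <- lapply(spans, function(sp) {
    s <- sp[1]; e <- sp[2]
    dscores <- scores[s:e]
    data.frame(seq_id = profile$seq_id,
               window_size = profile$window_size,
               start = as.integer(s), end = as.integer(e),
               length = as.integer(e - s + 1L),
               subsequence = substr(profile$sequence, s, e),
               domain_score = sah_domain_score(dscores, subwindow),
               below_cutoff_fraction = mean(dscores <= cutoff),
               residue_scores = I(list(dscores)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Filter candidate domains by SAH-domain-score
#'
#' Keeps candidates whose SAH-domain-score reaches the per-window minimum
#' (default 0.35 / 0.32 / 0.29 / 0.25 for windows 14 / 21 / 28 / 49);
#' order is preserved.
#'
#' @param candidates data frame from [detect_domains()].
#' @param config an `sah_config`.
#' @return the retained rows.
#' @export
filter_domains <- function(candidates, config) {
  if (nrow(candidates) == 0) return(candidates)
  w <- as.character(candidates$window_size)
  unknown <- setdiff(unique(w), names(config$domain_score_cutoffs))
  if (length(unknown) > 0) {
    stop("no SAH-domain-score cutoff configured for window size(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- candidates$domain_score >= config$domain_score_cutoffs[w]
  candidates[keep, , drop = FALSE]
}

#' Predict SAH-domains in one record
#'
#' Convenience wrapper: profile, candidate detection and domain-score
#' filtering for one or all configured window sizes.
#'
#' @param record a `protein_record` or residue string.
#' @param config an `sah_config`.
#' @param window_sizes windows to scan (default: all configured).
#' @return data frame of retained domains across the requested windows.
#' @examples
#' cfg <- sah_config()
#' predict_domains(make_perfect_sah(10), cfg, window_sizes = 14)
#' @export
predict_domains <- function(record, config, window_sizes = config$window_sizes) {
  res <- lapply(window_sizes, function(w) {
    filter_domains(detect_domains(score_profile(record, w, config), config),
                   config)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) .empty_domains() else out
}
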