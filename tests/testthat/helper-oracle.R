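# Independent reference implementation used as an oracle: every window is
# re-enumerated from the raw character string with direct matrix lookups,
# with no sharing of the package's contribution-vector / rolling-sum path.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

oracle_window_score <- function(chars, start, window_size, config) {
  n <- length(chars)
  pick <- function(ix) ifelse(ix >= 1 & ix <= n, chars[pmax(pmin(ix, n), 1)], "-")
  i <- start:(start + window_size - 1)
  a <- pick(i)
  s <- 0
  for (d in c(3L, 4L)) {
    b <- pick(i + d)
    ok <- a %in% AA20 & b %in% AA20
    if (any(ok)) {
      m <- if (d == 3L) config$matrix_i3 else config$matrix_i4
      s <- s + sum(m[cbind(a[ok], b[ok])])
    }
  }
  neg <- c("D", "E"); pos <- c("K", "R")
  hyd <- c("V", "I", "L", "M", "F", "Y")
  for (off in list(c(3L, 6L), c(3L, 7L), c(4L, 7L), c(4L, 8L))) {
    b <- pick(i + off[1]); cc <- pick(i + off[2])
    charged <- (a %in% neg & b %in% pos & cc %in% neg) |
               (a %in% pos & b %in% neg & cc %in% pos)
    seam <- a %in% hyd & b %in% hyd & cc %in% hyd
    s <- s + sum(charged) * config$network_charged +
             sum(seam) * config$network_hydrophobic
  }
  s
}

oracle_profile <- function(sequence, window_size, config) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offset <- floor(window_size / 2) + 1
  norm_chars <- strsplit(strrep("EEEEKKK", ceiling((window_size + 8) / 7) + 1),
                         "", fixed = TRUE)[[1]]
  norm <- oracle_window_score(norm_chars, 1L, window_size, config)
  vapply(seq_along(chars), function(r) {
    oracle_window_score(chars, r - offset + 1L, window_size, config) / norm
  }, 0)
}

random_sequence <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force SAH-domain-score: explicit loop over all sub-windows
oracle_domain_score <- function(scores, subwindow) {
  n_sub <- length(scores) - subwindow + 1
  max(vapply(seq_len(n_sub), function(i) {
    mean(scores[i:(i + subwindow - 1)])
  }, 0))
}

default_cfg <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- sah_config()
    cached
  }
})
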