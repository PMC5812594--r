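# helper: wrap a bare score vector as a profile over a dummy sequence
fake_profile <- function(scores, window_size = 14L, seq_id = "t") {
  structure(list(seq_id = seq_id, window_size = as.integer(window_size),
                 sequence = strrep("E", length(scores)),
                 scores = scores),
            class = "sah_profile")
}

# exhaustive oracle: all spans satisfying the three domain conditions
all_valid_spans <- function(scores, cutoff, tol, wmin) {
  n <- length(scores)
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (e - s + 1 < wmin) next
    if (scores[s] <= cutoff || scores[e] <= cutoff) next
    if (mean(scores[s:e] <= cutoff) > tol) next
    out[[length(out) + 1]] <- c(s, e)
  }
  out
}

test_that("uniform profiles yield one full-span domain or nothing", {
  cfg <- default_cfg()
  d <- detect_domains(fake_profile(rep(0.30, 30)), cfg)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(1, 30))
  expect_equal(d$below_cutoff_fraction, 0)
  expect_equal(nrow(detect_domains(fake_profile(rep(0.10, 30)), cfg)), 0)
})

test_that("short below-cutoff gaps merge, long ones split", {
  cfg <- default_cfg()
  # 2/40 = 5% below cutoff: one merged domain
  sc <- rep(0.40, 40); sc[18:19] <- 0.10
  d <- detect_domains(fake_profile(sc), cfg)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(1, 40))
  expect_equal(d$below_cutoff_fraction, 2 / 40)
  # a 12-residue gap cannot be absorbed: two clean 14-residue domains
  sc2 <- rep(0.40, 40); sc2[15:26] <- 0.10
  d2 <- detect_domains(fake_profile(sc2), cfg)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$start, c(1, 27))
  expect_equal(d2$end, c(14, 40))
  # every reported span is valid under the exhaustive condition check,
  # and reported spans are maximal: not contained in another valid span
  # that the greedy scan could have produced
  for (dd in list(d, d2)) {
    spans <- all_valid_spans(if (nrow(dd) == 1) sc else sc2, 0.25, 0.20, 14)
    for (i in seq_len(nrow(dd))) {
      expect_true(any(vapply(spans, function(sp)
        sp[1] == dd$start[i] && sp[2] == dd$end[i], TRUE)))
    }
  }
})

test_that("reported domains always satisfy the segment invariants", {
  cfg <- default_cfg()
  set.seed(5)
  for (rep in 1:25) {
    sc <- round(stats::runif(60, 0, 0.6), 3)
    d <- detect_domains(fake_profile(sc, 14), cfg)
    if (nrow(d) == 0) next
    expect_true(all(sc[d$start] > cfg$residue_cutoff))
    expect_true(all(sc[d$end] > cfg$residue_cutoff))
    expect_true(all(d$below_cutoff_fraction <= cfg$below_cutoff_tolerance))
    expect_true(all(d$length >= 14))
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))  # disjoint, sorted
  }
})

test_that("the SAH-domain-score is the max of sub-window means", {
  # a 20-residue candidate: every possible 14-residue sub-window
  # (length - subwindow + 1 of them) is evaluated
  set.seed(8)
  sc <- stats::runif(20, 0.25, 0.8)
  expect_equal(length(sc) - 14 + 1, 7)
  expect_equal(sah_domain_score(sc, 14), oracle_domain_score(sc, 14),
               tolerance = 1e-12)
  # mean of constants is the constant
  expect_equal(sah_domain_score(rep(0.31, 20), 14), 0.31)
  expect_error(sah_domain_score(stats::runif(10), 14), "shorter")
})

test_that("domain-score filtering is per-window and order-preserving", {
  cfg <- default_cfg()
  cand <- rbind(
    data.frame(seq_id = "a", window_size = 14L, start = 1L, end = 20L,
               length = 20L, subsequence = strrep("E", 20),
               domain_score = 0.40, below_cutoff_fraction = 0,
               residue_scores = I(list(rep(0.4, 20)))),
    data.frame(seq_id = "b", window_size = 14L, start = 1L, end = 20L,
               length = 20L, subsequence = strrep("E", 20),
               domain_score = 0.30, below_cutoff_fraction = 0,
               residue_scores = I(list(rep(0.3, 20)))))
  kept <- filter_domains(cand, cfg)
  expect_equal(kept$seq_id, "a")   # 0.30 < 0.35 cutoff for window 14
  cand49 <- cand[2, ]; cand49$window_size <- 49L
  expect_equal(nrow(filter_domains(cand49, cfg)), 1)  # 0.30 >= 0.25
  expect_equal(nrow(filter_domains(cand[0, ], cfg)), 0)
  cand15 <- cand; cand15$window_size <- 15L
  expect_error(filter_domains(cand15, cfg), "15")
})

test_that("planted perfect repeats are recovered as single domains", {
  cfg <- default_cfg()
  # detected boundaries ride the scoring-window ramp: the left boundary
  # can precede the insert by up to ~(3/4)w - offset + 2 residues
  ramp <- c("14" = 4, "21" = 6, "28" = 8)
  set.seed(13)
  for (rep in 1:10) {
    off <- sample(20:60, 1)
    left <- random_sequence(off - 1, c("G", "S", "T", "A"))
    right <- random_sequence(120 - off - 34, c("G", "S", "T", "A"))
    s <- paste0(left, make_perfect_sah(5), right)
    for (w in c(14, 21, 28)) {
      d <- filter_domains(detect_domains(score_profile(s, w, cfg), cfg), cfg)
      expect_equal(nrow(d), 1)
      covered <- min(d$end, off + 34) - max(d$start, off) + 1
      expect_gte(covered / 35, 0.9)
      expect_lte(abs(d$start - off), ramp[[as.character(w)]])
      expect_lte(abs(d$end - (off + 34)), 4)
    }
    # pure background stays empty
    bg <- random_sequence(120, c("G", "S", "T", "A"))
    for (w in c(14, 21, 28)) {
      expect_equal(nrow(filter_domains(
        detect_domains(score_profile(bg, w, cfg), cfg), cfg)), 0)
    }
  }
})

test_that("larger windows report longer, fewer domains deterministically", {
  cfg <- default_cfg()
  set.seed(21)
  seqs <- replicate(6, paste0(random_sequence(25, c("G", "S", "T", "A")),
                              make_perfect_sah(sample(3:8, 1)),
                              random_sequence(25, c("G", "S", "T", "A"))))
  counts <- sapply(c(14, 21, 28, 49), function(w) {
    sum(vapply(seqs, function(s) {
      d <- filter_domains(detect_domains(score_profile(s, w, cfg), cfg), cfg)
      expect_true(all(d$length >= w))
      nrow(d)
    }, 0L))
  })
  expect_true(all(diff(counts) <= 0))
  # identical inputs give identical outputs
  d1 <- predict_domains(seqs[1], cfg)
  d2 <- predict_domains(seqs[1], cfg)
  expect_identical(d1, d2)
})
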