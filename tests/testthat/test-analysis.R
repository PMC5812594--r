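dom_table <- function(seqs, seq_id = paste0("s", seq_along(seqs)),
                      window_size = 14L) {
  data.frame(seq_id = seq_id, window_size = window_size,
             start = 1L, end = nchar(seqs), length = nchar(seqs),
             subsequence = seqs, domain_score = 0.5,
             below_cutoff_fraction = 0,
             residue_scores = I(lapply(nchar(seqs), function(n) rep(0.5, n))),
             stringsAsFactors = FALSE)
}

test_that("composition pools residues exactly", {
  comp <- composition(dom_table("EEEEKKK"))
  expect_equal(comp$fractions[["E"]], 4 / 7)
  expect_equal(comp$fractions[["K"]], 3 / 7)
  expect_equal(comp$charged_polar_fraction, 1)
  expect_equal(comp$heptad_equivalent, 7)
  comp2 <- composition(dom_table("EKEKEKEKEKEKEK"))
  expect_equal(comp2$fractions[["E"]], 0.5)
  expect_equal(comp2$fractions[["K"]], 0.5)
  expect_error(composition(dom_table("EEEEKKK")[0, ]), "at least one")
})

test_that("composition equals an independent tally and ignores order", {
  set.seed(31)
  seqs <- replicate(100, random_sequence(sample(14:40, 1)))
  comp <- composition(dom_table(seqs))
  chars <- unlist(strsplit(paste(seqs, collapse = ""), ""))
  for (aa in c("A", "E", "K", "P", "W")) {
    expect_equal(comp$fractions[[aa]], sum(chars == aa) / length(chars))
  }
  expect_equal(sum(comp$fractions), 1, tolerance = 1e-9)
  shuffled <- composition(dom_table(rev(seqs)))
  expect_equal(shuffled$fractions, comp$fractions)
})

test_that("heptad counting slides one residue at a time", {
  # 8-residue homopolymer: two sliding heptads, same string
  h <- heptad_frequency(dom_table("EEEEEEEE"), 5)
  expect_equal(h$count[h$heptad == "EEEEEEE"], 2)
  # the Myo10 region contains the most common human heptad
  myo <- bundled_examples()$sequence[1]
  h2 <- heptad_frequency(dom_table(myo), top_n = 1000)
  expect_gte(h2$count[h2$heptad == "RERERER"], 1)
  # total heptads = sum over domains of max(0, len - 6)
  set.seed(32)
  seqs <- replicate(40, random_sequence(sample(5:30, 1)))
  hall <- heptad_frequency(dom_table(seqs), top_n = .Machine$integer.max)
  expect_equal(sum(hall$count), sum(pmax(0, nchar(seqs) - 6)))
  # equals a direct substring tally, ties broken lexicographically
  tally <- table(unlist(lapply(seqs[nchar(seqs) >= 7], function(s)
    substring(s, 1:(nchar(s) - 6), 7:nchar(s)))))
  expect_equal(sum(hall$count), sum(tally))
  top <- hall[hall$count == max(hall$count), "heptad"]
  expect_equal(top[1], sort(names(tally)[tally == max(tally)])[1])
  expect_error(heptad_frequency(dom_table("EEEEEEE"), 0), "top_n")
})

test_that("unique domains deduplicate within genes with presence fractions", {
  d <- dom_table(c("EEEEKKKEEEEKKKEEEEKK", "EEEEKKKEEEEKKKEEEEKK"),
                 seq_id = c("T1", "T2"))
  gm <- c(T1 = "G1", T2 = "G1", T3 = "G1", T4 = "G1")
  tc <- c(G1 = 4L)
  u <- unique_domains(d, gm, tc)
  expect_equal(nrow(u), 1)
  expect_equal(u$presence_fraction, 0.5)
  expect_equal(u$carrier_transcripts[[1]], c("T1", "T2"))
  expect_error(unique_domains(dom_table("EEEEKKKEEEEKKK", seq_id = "TX"),
                              gm, tc), "TX")
})

test_that("inclusion and overlap flags follow the string relations", {
  a <- "EEEEKKKEEEEKKK"
  b <- "EEEEKKKEEEEKKKEEEEKKK"
  gm <- c(T1 = "G1", T2 = "G1", T3 = "G1"); tc <- c(G1 = 3L)
  u <- unique_domains(dom_table(c(a, b), seq_id = c("T1", "T2")), gm, tc)
  expect_true(u$included[u$sequence == a])
  expect_true(u$including[u$sequence == b])
  expect_false(u$overlapping[u$sequence == a])
  # included and including come in pairs within a gene
  expect_equal(sum(u$included), sum(u$including))
  # terminal overlap of exactly 5 qualifies, 4 does not
  x5 <- "RRRRRRRRRRKKKKEEEEE"   # suffix EEEEE
  y5 <- "EEEEEDDDDDDDDDDRRRR"   # prefix EEEEE
  u5 <- unique_domains(dom_table(c(x5, y5), seq_id = c("T1", "T2")), gm, tc)
  expect_true(all(u5$overlapping))
  x4 <- "RRRRRRRRRRKKKKKEEEE"
  u4 <- unique_domains(dom_table(c(x4, y5), seq_id = c("T1", "T2")), gm, tc)
  expect_false(any(u4$overlapping))
  # different genes never get within-gene flags
  gm2 <- c(T1 = "G1", T2 = "G2"); tc2 <- c(G1 = 1L, G2 = 1L)
  u2 <- unique_domains(dom_table(c(a, b), seq_id = c("T1", "T2")), gm2, tc2)
  expect_false(any(u2$included | u2$including))
})

test_that("presence histograms bin on half-open 5% intervals", {
  u <- data.frame(presence_fraction = c(0.5, 0.5, 1.0))
  h <- presence_histogram(u)
  expect_equal(h$count[abs(h$bin_lo - 0.45) < 1e-9], 2)
  expect_equal(h$count[abs(h$bin_lo - 0.95) < 1e-9], 1)
  expect_equal(sum(h$count), 3)
  hall <- presence_histogram(data.frame(presence_fraction = rep(1, 7)))
  expect_equal(sum(hall$count), 7)
  expect_equal(hall$count[nrow(hall)], 7)
  # 500 random fractions against a direct binning oracle
  set.seed(33)
  fr <- stats::runif(500, 0.001, 1)
  h5 <- presence_histogram(data.frame(presence_fraction = fr))
  for (i in sample(nrow(h5), 8)) {
    expect_equal(h5$count[i],
                 sum(fr > h5$bin_lo[i] & fr <= h5$bin_hi[i]))
  }
})

test_that("cross-gene identity groups and inclusion pairs are found", {
  u <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    sequence = c("EEEEKKKEEEEKKKEEEEKK", "EEEEKKKEEEEKKKEEEEKK",
                 "KKKEEEEKKKEEEE", "RRREEEKKKEEEEKKKEEEERRR"),
    stringsAsFactors = FALSE)
  cg <- cross_gene_identity(u)
  expect_equal(nrow(cg$identity_groups), 1)
  expect_equal(cg$identity_groups$n_genes, 2)
  expect_equal(cg$identity_groups$genes[[1]], c("G1", "G2"))
  # G3's sequence sits inside G4's longer one
  expect_true(any(cg$inclusion_pairs$short_gene == "G3" &
                  cg$inclusion_pairs$long_gene == "G4"))
  disjoint <- cross_gene_identity(data.frame(
    gene_id = c("A", "B"), sequence = c("EEEEKKK", "DDDDRRR"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(disjoint$identity_groups), 0)
  expect_equal(nrow(disjoint$inclusion_pairs), 0)
})

test_that("length histograms use 50-aa bins and drop giants", {
  recs <- data.frame(seq_id = c("a", "b", "c", "d"),
                     length = c(120L, 50L, 3001L, 160L))
  doms <- dom_table("EEEEKKKEEEEKKK", seq_id = "a")
  h <- length_histogram(recs, doms)
  expect_equal(h$n_proteins[h$bin_lo == 101], 1)   # length 120 -> 101-150
  expect_equal(h$n_proteins[h$bin_lo == 1], 1)     # length 50 -> 1-50
  expect_equal(sum(h$n_proteins), 3)               # 3001 omitted
  expect_equal(sum(h$n_sah_proteins), 1)
  expect_equal(h$n_sah_proteins[h$bin_lo == 101], 1)
  # direct binning oracle on a random fixture proteome
  set.seed(34)
  lens <- sample(10:3200, 300, replace = TRUE)
  recs2 <- data.frame(seq_id = paste0("s", 1:300), length = lens)
  doms2 <- dom_table("EEEEKKKEEEEKKK", seq_id = "s1")
  h2 <- length_histogram(recs2, doms2)
  keep <- lens[lens <= 3000]
  for (i in sample(nrow(h2), 10)) {
    expect_equal(h2$n_proteins[i],
                 sum(keep >= h2$bin_lo[i] & keep <= h2$bin_hi[i]))
  }
})

test_that("multi-domain counts distinguish sequences and domains", {
  d <- dom_table(c("EEEEKKKEEEEKKK", "EEEEKKKEEEEKKK", "EEEEKKKEEEEKKK"),
                 seq_id = c("s1", "s1", "s2"))
  m <- multi_domain_counts(d)
  expect_equal(m$n_domains, 3L)
  expect_equal(m$n_sequences_with_domains, 2L)
  expect_equal(m$n_sequences_with_multiple, 1L)
  m0 <- multi_domain_counts(d[0, ])
  expect_equal(unlist(m0[, -1]), c(n_domains = 0L,
                                   n_sequences_with_domains = 0L,
                                   n_sequences_with_multiple = 0L))
})
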