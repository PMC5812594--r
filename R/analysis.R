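# Dataset-level analytics over predicted SAH-domains: composition,
# heptad-frequency ranking, length distributions, multi-domain counts and
# the unique-domain comparison across alternative transcripts.

#' Residue composition of a set of SAH-domains
#'
#' Pools the residues of all domain subsequences and reports the fraction
#' of each standard amino acid, the charged/polar fraction (D, E, K, R, N,
#' Q) and its heptad equivalent (fraction x 7): the number of heptad
#' positions fully occupied by charged/polar residues.
#'
#' @param domains data frame of domains with a `subsequence` column.
#' @return list of class `sah_composition` with `fractions` (named over
#'   the 20 residues, summing to 1), `counts`, `charged_polar_fraction`
#'   and `heptad_equivalent`.
#' @examples
#' d <- data.frame(subsequence = "EEEEKKK")
#' composition(d)$heptad_equivalent  # 7: every position charged
#' @export
composition <- function(domains) {
  if (nrow(domains) == 0) {
    stop("composition needs at least one domain")
  }
  chars <- unlist(strsplit(domains$subsequence, "", fixed = TRUE))
  chars <- chars[chars %in% AA_ORDER]
  counts <- table(factor(chars, levels = AA_ORDER))
  total <- sum(counts)
  fractions <- as.numeric(counts) / total
  names(fractions) <- AA_ORDER
  cp <- sum(fractions[CHARGED_POLAR_SET])
  structure(list(fractions = fractions,
                 counts = stats::setNames(as.integer(counts), AA_ORDER),
                 n_residues = as.integer(total),
                 charged_polar_fraction = cp,
                 heptad_equivalent = cp * 7),
            class = "sah_composition")
}

#' Most frequent heptads in a set of SAH-domains
#'
#' Counts every 7-residue substring (sliding, step 1) across all domain
#' subsequences and returns the most frequent; ties are broken
#' lexicographically, so the ranking is deterministic.
#'
#' @param domains data frame of domains with a `subsequence` column.
#' @param top_n number of heptads to return (fewer if fewer exist).
#' @return data frame with columns `heptad` and `count`, ordered by
#'   decreasing count.
#' @export
heptad_frequency <- function(domains, top_n = 10L) {
  if (top_n < 1) stop("top_n must be >= 1")
  heps <- unlist(lapply(domains$subsequence, function(s) {
    n <- nchar(s)
    if (n < 7) return(character(0))
    substring(s, 1:(n - 6), 7:n)
  }))
  if (length(heps) == 0) {
    return(data.frame(heptad = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(heps)
  out <- data.frame(heptad = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$heptad), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

# longest terminal overlap: suffix of x matching a prefix of y
.terminal_overlap <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  kmax <- min(nx, ny) - 1L
  if (kmax < 1L) return(0L)
  for (k in seq.int(kmax, 1L, by = -1L)) {
    if (substr(x, nx - k + 1L, nx) == substr(y, 1L, k)) return(k)
  }
  0L
}

#' Deduplicate SAH-domains within genes and relate them across transcripts
#'
#' Identical domain subsequences from transcripts of the same gene are
#' combined into one unique SAH-domain; for each, the fraction of the
#' gene's transcripts carrying it is computed. Unique domains of the same
#' gene are flagged `included`/`including` when one is a strict substring
#' of another, and `overlapping` when a terminal overlap (suffix of one
#' equals prefix of the other) of at least `min_overlap_aa` residues
#' exists and neither includes the other.
#'
#' @param domains data frame of domains; `seq_id` must be the transcript
#'   identifier.
#' @param gene_map named character vector mapping transcript id -> gene id.
#' @param transcript_counts named integer vector mapping gene id -> number
#'   of annotated transcripts.
#' @param min_overlap_aa minimum terminal overlap (default 5).
#' @return data frame with one row per unique domain: `gene_id`,
#'   `sequence`, `n_carriers`, `gene_transcript_count`,
#'   `presence_fraction`, logical flags `including`, `included`,
#'   `overlapping`, and the list column `carrier_transcripts`.
#' @export
unique_domains <- function(domains, gene_map, transcript_counts,
                           min_overlap_aa = 5L) {
  if (nrow(domains) == 0) {
    return(data.frame(gene_id = character(0), sequence = character(0),
                      n_carriers = integer(0),
                      gene_transcript_count = integer(0),
                      presence_fraction = numeric(0),
                      including = logical(0), included = logical(0),
                      overlapping = logical(0),
                      carrier_transcripts = I(list()),
                      stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(domains$seq_id), names(gene_map))
  if (length(unmapped) > 0) {
    stop("transcript(s) without gene mapping: ",
         paste(unmapped, collapse = ", "))
  }
  genes <- unname(gene_map[domains$seq_id])
  key <- paste(genes, domains$subsequence, sep = "\r")
  grp <- split(seq_len(nrow(domains)), key)
  rows <- lapply(grp, function(idx) {
    g <- genes[idx[1]]
    carriers <- sort(unique(domains$seq_id[idx]))
    ntr <- transcript_counts[[g]]
    if (is.null(ntr) || is.na(ntr)) {
      stop("gene without transcript count: ", g)
    }
    data.frame(gene_id = g, sequence = domains$subsequence[idx[1]],
               n_carriers = length(carriers),
               gene_transcript_count = as.integer(ntr),
               presence_fraction = length(carriers) / ntr,
               including = FALSE, included = FALSE, overlapping = FALSE,
               carrier_transcripts = I(list(carriers)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, -nchar(out$sequence), out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  # relation flags within each gene
  for (g in unique(out$gene_id)) {
    idx <- which(out$gene_id == g)
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) {
      if (a == b) next
      sa <- out$sequence[a]; sb <- out$sequence[b]
      if (nchar(sa) > nchar(sb) && grepl(sb, sa, fixed = TRUE)) {
        out$including[a] <- TRUE
        out$included[b] <- TRUE
      }
    }
    for (a in idx) for (b in idx) {
      if (a >= b) next
      sa <- out$sequence[a]; sb <- out$sequence[b]
      contains <- (nchar(sa) >= nchar(sb) && grepl(sb, sa, fixed = TRUE)) ||
                  (nchar(sb) > nchar(sa) && grepl(sa, sb, fixed = TRUE))
      if (contains) next
      ov <- max(.terminal_overlap(sa, sb), .terminal_overlap(sb, sa))
      if (ov >= min_overlap_aa) {
        out$overlapping[a] <- TRUE
        out$overlapping[b] <- TRUE
      }
    }
  }
  out
}

#' Histogram of unique-domain presence fractions
#'
#' Bins the presence fractions of unique SAH-domains over (0, 1] into
#' half-open bins `(lo, hi]` of the given width.
#'
#' @param uniques data frame from [unique_domains()].
#' @param bin_width bin width (default 0.05, i.e. 5% bins).
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
presence_histogram <- function(uniques, bin_width = 0.05) {
  if (nrow(uniques) == 0) stop("no unique domains to bin")
  breaks <- seq(0, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  counts <- table(cut(uniques$presence_fraction, breaks = breaks,
                      right = TRUE, include.lowest = FALSE))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = as.integer(counts))
}

#' Identical and included unique domains across genes
#'
#' Groups unique-domain sequences shared verbatim by two or more genes,
#' and lists cross-gene pairs where one gene's unique domain is a strict
#' substring of a longer unique domain of another gene.
#'
#' @param uniques data frame from [unique_domains()].
#' @return list with `identity_groups` (data frame: `sequence`,
#'   `n_genes`, list column `genes`) and `inclusion_pairs` (data frame:
#'   `short_gene`, `short_sequence`, `long_gene`, `long_sequence`).
#' @export
cross_gene_identity <- function(uniques) {
  per_seq <- split(uniques$gene_id, uniques$sequence)
  shared <- Filter(function(g) length(unique(g)) >= 2, per_seq)
  identity_groups <- if (length(shared) == 0) {
    data.frame(sequence = character(0), n_genes = integer(0),
               genes = I(list()), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(names(shared), function(s) {
      gs <- sort(unique(shared[[s]]))
      data.frame(sequence = s, n_genes = length(gs), genes = I(list(gs)),
                 stringsAsFactors = FALSE)
    }))
  }
  pairs <- list()
  n <- nrow(uniques)
  ord <- order(nchar(uniques$sequence))
  for (ii in seq_len(n)) for (jj in seq_len(n)) {
    a <- ord[ii]; b <- ord[jj]
    if (uniques$gene_id[a] == uniques$gene_id[b]) next
    sa <- uniques$sequence[a]; sb <- uniques$sequence[b]
    if (nchar(sa) < nchar(sb) && grepl(sa, sb, fixed = TRUE)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        short_gene = uniques$gene_id[a], short_sequence = sa,
        long_gene = uniques$gene_id[b], long_sequence = sb,
        stringsAsFactors = FALSE)
    }
  }
  inclusion_pairs <- if (length(pairs) == 0) {
    data.frame(short_gene = character(0), short_sequence = character(0),
               long_gene = character(0), long_sequence = character(0),
               stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, pairs))
  }
  rownames(inclusion_pairs) <- NULL
  list(identity_groups = identity_groups, inclusion_pairs = inclusion_pairs)
}

#' Protein-length histograms for all vs SAH-containing proteins
#'
#' Bins protein lengths (bin width 50 aa by default) for the whole dataset
#' and, aligned on the same bins, for the proteins carrying at least one
#' SAH-domain. Proteins longer than `max_len` are omitted from both.
#'
#' @param records data frame of sequence records with `seq_id` and
#'   `length` columns.
#' @param domains data frame of domains (`seq_id` column).
#' @param bin bin width in residues.
#' @param max_len longest protein length kept (default 3000).
#' @return data frame with `bin_lo`, `bin_hi`, `n_proteins`,
#'   `n_sah_proteins`.
#' @export
length_histogram <- function(records, domains, bin = 50L, max_len = 3000L) {
  lens <- records$length
  keep <- lens <= max_len
  lens <- lens[keep]
  sah_ids <- unique(domains$seq_id)
  sah_lens <- records$length[keep & records$seq_id %in% sah_ids]
  breaks <- seq(0, max_len, by = bin)
  h_all <- table(cut(lens, breaks = breaks, right = TRUE,
                     include.lowest = FALSE))
  h_sah <- table(cut(sah_lens, breaks = breaks, right = TRUE,
                     include.lowest = FALSE))
  data.frame(bin_lo = breaks[-length(breaks)] + 1L, bin_hi = breaks[-1],
             n_proteins = as.integer(h_all),
             n_sah_proteins = as.integer(h_sah))
}

#' Domain and multi-domain sequence counts
#'
#' Per window size: total number of domains, number of distinct sequences
#' with at least one domain, and with at least two (sequences whose domain
#' count exceeds their sequence count carry multiple independent domains).
#'
#' @param domains data frame of domains.
#' @return data frame with `window_size`, `n_domains`,
#'   `n_sequences_with_domains`, `n_sequences_with_multiple`; a single
#'   all-zero row if `domains` is empty.
#' @export
multi_domain_counts <- function(domains) {
  if (nrow(domains) == 0) {
    return(data.frame(window_size = NA_integer_, n_domains = 0L,
                      n_sequences_with_domains = 0L,
                      n_sequences_with_multiple = 0L))
  }
  res <- lapply(split(domains, domains$window_size), function(d) {
    per_seq <- table(d$seq_id)
    data.frame(window_size = d$window_size[1],
               n_domains = nrow(d),
               n_sequences_with_domains = length(per_seq),
               n_sequences_with_multiple = sum(per_seq >= 2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$window_size), , drop = FALSE]
}
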