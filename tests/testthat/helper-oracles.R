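# Brute-force oracle: check every substring of length 6 and 7 against the
# target k-mers, then apply the maximality rule (a 6-mer hit wholly inside a
# 7-mer hit is dropped; identical degenerate 6-mers collapse to one locus).
# Stays independent of scan_utr's vectorized matching path.
oracle_scan <- function(utr, seed, min_match = 6L, gene_id = "utr") {
  utr <- chartr("U", "T", toupper(utr))
  kmers <- seed$target_kmers
  n <- nchar(utr)
  rows <- list()
  for (start in seq_len(max(0L, n - 7L + 1L))) {
    if (substr(utr, start, start + 6L) == kmers[["complete7"]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, start = start - 1L, end = start + 6L, length = 7L,
        site_class = "complete7", matched_kmer = kmers[["complete7"]],
        stringsAsFactors = FALSE)
  }
  if (min_match == 6L) {
    starts7 <- vapply(rows, function(r) r$start, numeric(1))
    for (start in seq_len(max(0L, n - 6L + 1L))) {
      w <- substr(utr, start, start + 5L)
      for (cl in c("partial6_5p", "partial6_3p")) {
        if (w == kmers[[cl]]) {
          s0 <- start - 1L
          contained <- length(starts7) > 0 &&
            any(s0 >= starts7 & s0 + 6L <= starts7 + 7L)
          if (!contained)
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = gene_id, start = s0, end = s0 + 6L, length = 6L,
              site_class = cl, matched_kmer = kmers[[cl]],
              stringsAsFactors = FALSE)
          break  # degenerate identical 6-mers: one row per locus
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      site_class = character(), matched_kmer = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# 5-gene toy screen used across modules (mirrors the hand-worked example)
toy_screen_inputs <- function() {
  list(
    records = data.frame(
      gene_id = paste0("g", 1:5),
      ratio_hm_norm = c(0.6, 0.75, 0.81, 1.0, 0.7),
      intensity = c(10, 20, 30, 40, 50),
      stringsAsFactors = FALSE),
    complete_sites = c(g1 = 1L, g2 = 0L, g3 = 2L, g4 = 1L, g5 = 0L)
  )
}

# build a sites data.frame with n complete sites per gene
fake_sites <- function(counts, kmer = "GATCCGT") {
  genes <- rep(names(counts), counts)
  if (!length(genes))
    return(seedscreen::scan_utrs(c(x = "AAAA"),
                                 extract_seed("UACGGAUCCG", "t")))
  starts <- unlist(lapply(counts[counts > 0], function(k)
    seq(0, by = 10, length.out = k)))
  data.frame(gene_id = genes, start = starts, end = starts + 7L,
             length = 7L, site_class = "complete7",
             matched_kmer = kmer, stringsAsFactors = FALSE)
}

# Vectorized exhaustive oracle: every substring of length 6/7 compared against
# the target k-mers by string equality, then the containment suppression.
# Same contract as oracle_scan but fast enough for thousands of UTRs.
oracle_scan_fast <- function(utr, seed, min_match = 6L, gene_id = "utr") {
  utr <- chartr("U", "T", toupper(utr))
  n <- nchar(utr)
  k <- seed$target_kmers
  w7 <- if (n >= 7L) substring(utr, 1:(n - 6L), 7:n) else character(0)
  s7 <- which(w7 == k[["complete7"]]) - 1L
  rows <- list()
  if (length(s7))
    rows$c7 <- data.frame(gene_id = gene_id, start = s7, end = s7 + 7L,
                          length = 7L, site_class = "complete7",
                          matched_kmer = k[["complete7"]],
                          stringsAsFactors = FALSE)
  if (min_match == 6L && n >= 6L) {
    w6 <- substring(utr, 1:(n - 5L), 6:n)
    hit5p <- w6 == k[["partial6_5p"]]
    hit3p <- w6 == k[["partial6_3p"]] & !hit5p   # 5p wins degenerate ties
    for (cl in c("partial6_5p", "partial6_3p")) {
      s6 <- which(if (cl == "partial6_5p") hit5p else hit3p) - 1L
      if (length(s7))
        s6 <- s6[!vapply(s6, function(s)
          any(s >= s7 & s + 6L <= s7 + 7L), logical(1))]
      if (length(s6))
        rows[[cl]] <- data.frame(gene_id = gene_id, start = s6, end = s6 + 6L,
                                 length = 6L, site_class = cl,
                                 matched_kmer = k[[cl]],
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      site_class = character(), matched_kmer = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
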