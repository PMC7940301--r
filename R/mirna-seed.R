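#' Extract the seed region of a mature miRNA
#'
#' The seed is the 7-nt heptamer at positions 2-8 (1-based) of the mature
#' sequence, the region whose Watson-Crick complementarity to a 3'UTR site
#' dominates target recognition. Alongside the seed, the three target-site
#' k-mers a UTR scan looks for are precomputed: the DNA reverse complement of
#' the full seed (the "complete" 7-mer site) and of each of its two contiguous
#' 6-nt sub-windows (partial sites).
#'
#' @param mature_seq Mature miRNA sequence, 5'->3', RNA alphabet (A/C/G/U;
#'   T is accepted and converted to U). Length must be at least 8.
#' @param name Identifier for the miRNA (e.g. `"mmu-miR-126-3p"`).
#' @return An object of class `mirna_seed`: a list with elements `name`,
#'   `mature_seq`, `seed` (RNA, length 7) and `target_kmers` (named character
#'   vector of DNA k-mers: `complete7`, `partial6_5p`, `partial6_3p`).
#' @examples
#' ms <- extract_seed("UACGGAUCCGAAAUGCAUGCAU", "toy-miR")
#' ms$seed           # "ACGGAUC"
#' ms$target_kmers   # complete7 "GATCCGT", partials "ATCCGT", "GATCCG"
#' @export
extract_seed <- function(mature_seq, name = "miRNA") {
  stopifnot(is.character(mature_seq), length(mature_seq) == 1L)
  seq <- chartr("tu", "TU", toupper(mature_seq))
  seq <- chartr("T", "U", seq)
  bad <- regexpr("[^ACGU]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d of mature sequence",
                 substr(seq, bad, bad), bad))
  }
  if (nchar(seq) < 8L) {
    stop(sprintf("sequence too short: mature miRNA must be >= 8 nt, got %d",
                 nchar(seq)))
  }
  seed <- substr(seq, 2L, 8L)
  structure(
    list(name = name, mature_seq = seq, seed = seed,
         target_kmers = seed_target_kmers(seed)),
    class = "mirna_seed"
  )
}

#' @export
print.mirna_seed <- function(x, ...) {
  cat("<mirna_seed>", x$name, "\n")
  cat("  mature:", x$mature_seq, "\n")
  cat("  seed (pos 2-8):", x$seed, "\n")
  cat("  target k-mers:",
      paste(names(x$target_kmers), x$target_kmers, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Target-site k-mers complementary to a 7-nt seed
#'
#' Computes the DNA k-mers that a 3'UTR must contain to pair with the seed:
#' the reverse complement of the full heptamer and of its two 6-nt
#' sub-windows (seed positions 1-6 and 2-7), each written 5'->3' in the DNA
#' alphabet.
#'
#' @param seed RNA string of length 7.
#' @return Named character vector `c(complete7=, partial6_5p=, partial6_3p=)`.
#'   `partial6_5p` pairs with seed positions 1-6, `partial6_3p` with 2-7.
#' @examples
#' seed_target_kmers("ACGGAUC")
#' @export
seed_target_kmers <- function(seed) {
  stopifnot(is.character(seed), length(seed) == 1L)
  if (nchar(seed) != 7L)
    stop(sprintf("seed must be exactly 7 nt, got %d", nchar(seed)))
  dna <- chartr("U", "T", toupper(seed))
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  c(complete7   = rc(dna),
    partial6_5p = rc(substr(dna, 1L, 6L)),
    partial6_3p = rc(substr(dna, 2L, 7L)))
}

## Normalize a UTR sequence to upper-case DNA; U -> T, N allowed.
normalize_utr_seq <- function(sequence, gene_id = "?") {
  s <- chartr("U", "T", toupper(sequence))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d of UTR '%s'",
                 substr(s, bad, bad), bad, gene_id))
  }
  if (!nzchar(s)) stop(sprintf("empty UTR sequence for '%s'", gene_id))
  s
}

#' Scan one 3'UTR for seed-match sites
#'
#' Reports every occurrence of a target k-mer of length >= `min_match`,
#' 0-based half-open coordinates on the supplied (5'->3') UTR strand.
#' Overlapping occurrences at distinct starts are all reported, but a 6-mer
#' occurrence wholly contained inside a reported 7-mer occurrence is
#' suppressed (maximality: every complete site would otherwise trivially also
#' yield its two partial sub-sites). Windows containing N never match.
#'
#' @param utr A single UTR: either a character string, or a list/record with
#'   `gene_id` and `sequence` fields.
#' @param seed A `mirna_seed` object from [extract_seed()].
#' @param min_match Minimum contiguous match length, 6 or 7.
#' @param gene_id Identifier used in the output when `utr` is a bare string.
#' @return A data.frame with columns `gene_id`, `start`, `end`, `length`,
#'   `site_class` (`complete7`, `partial6_5p`, `partial6_3p`) and
#'   `matched_kmer`, sorted by `start`.
#' @examples
#' ms <- extract_seed("UACGGAUCCGAAAUGCAUGCAU", "toy")
#' scan_utr("AAAGATCCGTAAA", ms)   # one complete7 site at start 3
#' @export
scan_utr <- function(utr, seed, min_match = 6L, gene_id = "utr") {
  if (is.list(utr)) {
    gene_id <- utr$gene_id
    utr <- utr$sequence
  }
  seqs <- stats::setNames(as.character(utr), gene_id)
  scan_utrs(seqs, seed, min_match = min_match)
}

#' Scan a set of 3'UTRs for seed-match sites
#'
#' Vectorized scanner over a named set of UTR sequences; the workhorse behind
#' [scan_utr()] and the screen. Matching uses exact string occurrence of each
#' target k-mer (all overlapping starts), with the same maximality suppression
#' as [scan_utr()].
#'
#' @param utrs Named character vector or `Biostrings::DNAStringSet` of UTR
#'   sequences (names are gene identifiers).
#' @param seed A `mirna_seed` object.
#' @param min_match Minimum contiguous match length, 6 or 7.
#' @return data.frame as in [scan_utr()], sorted by `gene_id` then `start`.
#' @export
scan_utrs <- function(utrs, seed, min_match = 6L) {
  stopifnot(inherits(seed, "mirna_seed"))
  if (!min_match %in% c(6L, 7L))
    stop("min_match must be 6 or 7, got ", min_match)
  if (inherits(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  if (is.null(names(utrs)) || anyNA(names(utrs)) || any(!nzchar(names(utrs))))
    stop("UTR sequences must be named by gene_id")
  seqs <- vapply(seq_along(utrs), function(i)
    normalize_utr_seq(utrs[[i]], names(utrs)[i]), character(1))
  names(seqs) <- names(utrs)
  subject <- Biostrings::DNAStringSet(seqs)

  kmers <- seed$target_kmers
  classes <- if (min_match == 7L) "complete7" else names(kmers)
  hits <- lapply(classes, function(cl) {
    m <- Biostrings::vmatchPattern(kmers[[cl]], subject, fixed = TRUE)
    n_per <- lengths(m)
    if (sum(n_per) == 0L) return(NULL)
    st <- unlist(IRanges::start(m), use.names = FALSE)
    data.frame(gene_id = rep(names(seqs), n_per),
               start = st - 1L,                      # 0-based
               length = nchar(kmers[[cl]]),
               site_class = cl,
               matched_kmer = kmers[[cl]],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, hits)
  if (is.null(sites)) return(empty_sites())
  sites$end <- sites$start + sites$length

  ## maximality: drop 6-mer hits wholly inside a 7-mer hit of the same gene
  if (min_match == 6L) {
    keep <- rep(TRUE, nrow(sites))
    is7 <- sites$length == 7L
    for (g in unique(sites$gene_id[is7])) {
      gi <- sites$gene_id == g
      s7 <- sites$start[gi & is7]
      part <- which(gi & !is7)
      if (length(part)) {
        contained <- vapply(part, function(i)
          any(sites$start[i] >= s7 & sites$end[i] <= s7 + 7L), logical(1))
        keep[part[contained]] <- FALSE
      }
    }
    sites <- sites[keep, , drop = FALSE]
    ## degenerate seeds can give identical 5p/3p 6-mers: one row per locus
    dup <- duplicated(sites[, c("gene_id", "start", "length")])
    sites <- sites[!dup, , drop = FALSE]
  }
  sites <- sites[order(sites$gene_id, sites$start, -sites$length), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites[, c("gene_id", "start", "end", "length", "site_class", "matched_kmer")]
}

empty_sites <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             length = integer(), site_class = character(),
             matched_kmer = character(), stringsAsFactors = FALSE)
}

#' Count complete (7-nt) seed sites in a 3'UTR
#'
#' @inheritParams scan_utr
#' @return Integer count of `complete7` sites.
#' @examples
#' ms <- extract_seed("UACGGAUCCGAAAUGCAUGCAU", "toy")
#' count_complete_sites("AAGATCCGTTTGATCCGTAA", ms)  # 2 planted sites
#' @export
count_complete_sites <- function(utr, seed, gene_id = "utr") {
  sites <- scan_utr(utr, seed, min_match = 7L, gene_id = gene_id)
  sum(sites$length == 7L)
}

#' Expected chance seed-site count in a random UTR
#'
#' Closed-form expectation of the number of occurrences of one fixed k-mer of
#' length `site_length` in a uniform-composition i.i.d. random sequence of
#' length `utr_length`: `(L - k + 1) * 4^-k`. Used as the analytic null for
#' the scanner; assumes uniform base composition.
#'
#' @param utr_length UTR length in nt (> `site_length`... equal allowed for
#'   the single-window case).
#' @param site_length Site length in nt (6 or 7 in practice).
#' @return Expected number of occurrences (real).
#' @examples
#' expected_background_sites(300, 7)   # ~0.0179
#' @export
expected_background_sites <- function(utr_length, site_length) {
  stopifnot(utr_length >= site_length, site_length >= 1)
  (utr_length - site_length + 1) * 4^(-site_length)
}

#' Read 3'UTR sequences from a FASTA file
#'
#' Record ID up to the first whitespace is taken as the gene identifier;
#' sequences are upper-cased and U converted to T.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  stats::setNames(seqs, ids)
}

#' Write seed sites as TSV or BED6
#'
#' @param sites data.frame from [scan_utrs()].
#' @param path Output file path.
#' @param format `"tsv"` (columns gene_id, start, end, length, site_class,
#'   matched_kmer) or `"bed"` (BED6: chrom = gene_id, score = match length,
#'   strand = "+").
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = sites$gene_id, chromStart = sites$start,
                      chromEnd = sites$end,
                      name = sites$site_class, score = sites$length,
                      strand = "+")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
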