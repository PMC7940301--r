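#' Configuration for the synthetic pSILAC screen
#'
#' Defaults emulate the scale and effect regime of a ~4569-protein screen in
#' which roughly 8% of proteins appear downregulated: 1% of genes are direct
#' targets (mean repression to ratio 0.7, seed sites planted in their UTRs),
#' 7% are indirectly repressed (mean ratio 0.75, no planted sites), the rest
#' are null (ratio centered at 1). Ratio noise is multiplicative log-normal.
#'
#' @param n_proteins Number of simulated proteins/genes.
#' @param frac_direct Fraction of genes that are direct targets.
#' @param frac_indirect Fraction indirectly repressed (no planted sites).
#' @param direct_effect Mean log2 ratio of direct genes (default `log2(0.7)`).
#' @param indirect_effect Mean log2 ratio of indirect genes
#'   (default `log2(0.75)`).
#' @param noise_sd SD of the log2 ratio noise.
#' @param utr_length_range Integer pair: UTR lengths are drawn uniformly from
#'   this range.
#' @param gc_content GC fraction of the random UTR background.
#' @param planted_sites_per_direct Complete 7-mer sites planted per direct
#'   gene.
#' @param rng_seed Integer seed; the simulation is byte-reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 4569L,
                              frac_direct = 0.01,
                              frac_indirect = 0.07,
                              direct_effect = log2(0.7),
                              indirect_effect = log2(0.75),
                              noise_sd = 0.1,
                              utr_length_range = c(200L, 2000L),
                              gc_content = 0.5,
                              planted_sites_per_direct = 2L,
                              rng_seed = 1L) {
  stopifnot(n_proteins >= 1,
            frac_direct >= 0, frac_indirect >= 0,
            frac_direct + frac_indirect < 1,
            noise_sd >= 0,
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 10, diff(utr_length_range) >= 0,
            gc_content > 0, gc_content < 1,
            planted_sites_per_direct >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 frac_direct = frac_direct, frac_indirect = frac_indirect,
                 direct_effect = direct_effect,
                 indirect_effect = indirect_effect,
                 noise_sd = noise_sd,
                 utr_length_range = as.integer(utr_length_range),
                 gc_content = gc_content,
                 planted_sites_per_direct = as.integer(planted_sites_per_direct),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

random_utr <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

## Replace non-overlapping windows of a UTR with the target k-mer.
plant_sites <- function(utr, kmer, n_sites) {
  k <- nchar(kmer)
  len <- nchar(utr)
  if (len < n_sites * k)
    stop(sprintf("UTR too short (%d nt) to plant %d sites of %d nt",
                 len, n_sites, k))
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n_sites) {
    s <- sample.int(len - k + 1L, 1L)
    if (!any(abs(s - starts) < k)) starts <- c(starts, s)
    tries <- tries + 1L
    if (tries > 1000L * n_sites)
      stop("could not place non-overlapping sites; UTR too short")
  }
  for (s in sort(starts)) {
    substr(utr, s, s + k - 1L) <- kmer
  }
  utr
}

#' Simulate a pSILAC screen with planted ground truth
#'
#' Generates a protein ratio table, matching 3'UTR sequences and a truth
#' table. Class labels are assigned at random; raw H/M ratios are drawn as
#' `2^(true_log2_effect + Normal(0, noise_sd))`; UTRs are i.i.d. with the
#' configured GC content; each direct gene receives the configured number of
#' complete seed sites inserted by substring replacement at non-overlapping
#' uniform random positions (UTR length preserved). Chance complete sites in
#' non-planted UTRs are recorded post hoc by rescanning.
#'
#' @param config A [simulation_config()].
#' @param mirna A `mirna_seed` object (sites planted are the reverse
#'   complement of its full seed).
#' @return List with elements `ratios` (data.frame: `protein_id`, `gene_id`,
#'   `ratio_hm_raw`, `intensity`, `n_peptides`), `utrs` (named character
#'   vector) and `truth` (data.frame: `gene_id`, `true_class`,
#'   `true_log2_effect`, `planted_site_count`, `chance_site_count`).
#' @export
simulate_experiment <- function(config, mirna) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(mirna, "mirna_seed"))
  set.seed(config$rng_seed)
  n <- config$n_proteins
  gene_id <- sprintf("gene%05d", seq_len(n))

  n_direct <- round(n * config$frac_direct)
  n_indirect <- round(n * config$frac_indirect)
  cls <- rep("null", n)
  picked <- sample.int(n, n_direct + n_indirect)
  cls[picked[seq_len(n_direct)]] <- "direct"
  cls[picked[-seq_len(n_direct)]] <- "indirect"

  effect <- ifelse(cls == "direct", config$direct_effect,
                   ifelse(cls == "indirect", config$indirect_effect, 0))
  ratio <- 2^(effect + stats::rnorm(n, 0, config$noise_sd))
  intensity <- stats::rlnorm(n, meanlog = log(1e7), sdlog = 1.5)
  n_peptides <- 1L + stats::rpois(n, 4)

  lens <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                 n, replace = TRUE)
  utrs <- vapply(lens, random_utr, character(1), gc = config$gc_content)
  kmer <- mirna$target_kmers[["complete7"]]
  planted <- integer(n)
  for (i in which(cls == "direct")) {
    utrs[i] <- plant_sites(utrs[i], kmer, config$planted_sites_per_direct)
    planted[i] <- config$planted_sites_per_direct
  }
  names(utrs) <- gene_id

  chance <- integer(n)
  bg <- cls != "direct"
  if (any(bg)) {
    bg_sites <- scan_utrs(utrs[bg], mirna, min_match = 7L)
    cnt <- table(factor(bg_sites$gene_id, levels = gene_id[bg]))
    chance[bg] <- as.integer(cnt)
  }

  list(
    ratios = data.frame(protein_id = paste0("P_", gene_id),
                        gene_id = gene_id,
                        ratio_hm_raw = ratio,
                        intensity = intensity,
                        n_peptides = n_peptides,
                        stringsAsFactors = FALSE),
    utrs = utrs,
    truth = data.frame(gene_id = gene_id, true_class = cls,
                       true_log2_effect = effect,
                       planted_site_count = planted,
                       chance_site_count = chance,
                       stringsAsFactors = FALSE)
  )
}

#' Write simulated screen inputs to a directory
#'
#' Emits `ratios.tsv` (MaxQuant-style headers), `utrs.fa` and `truth.tsv`;
#' each file carries a header comment line recording the RNG seed.
#'
#' @param sim Output of [simulate_experiment()].
#' @param out_dir Output directory (created if needed).
#' @param config The [simulation_config()] used (for the seed in headers).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- if (!is.null(config))
    sprintf("# rng_seed=%d", config$rng_seed) else NULL
  tab <- data.frame(`Protein IDs` = sim$ratios$protein_id,
                    `Gene names` = sim$ratios$gene_id,
                    `Ratio H/M normalized` = sim$ratios$ratio_hm_raw,
                    Intensity = sim$ratios$intensity,
                    Peptides = sim$ratios$n_peptides,
                    check.names = FALSE)
  con <- file.path(out_dir, "ratios.tsv")
  if (!is.null(seed_line)) writeLines(seed_line, con)
  suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, append = !is.null(seed_line)))
  fa <- file.path(out_dir, "utrs.fa")
  writeLines(paste0(">", names(sim$utrs), "\n", sim$utrs), fa)
  tr <- file.path(out_dir, "truth.tsv")
  if (!is.null(seed_line)) writeLines(seed_line, tr)
  suppressWarnings(utils::write.table(sim$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE, append = !is.null(seed_line)))
  invisible(out_dir)
}

#' Recovery metrics of a screen against simulated truth
#'
#' @param candidates Output of [screen_targets()].
#' @param truth Truth table from [simulate_experiment()].
#' @return List with the 3x3 confusion matrix (`declared` x `truth`), exact
#'   counts and fractions: `sensitivity` (recovered direct / true direct),
#'   `fdp` (false-discovery proportion among declared directs; 0 with
#'   `fdp_undefined = TRUE` when nothing is declared), `specificity`
#'   (fraction of true nulls not declared direct).
#' @export
evaluate_recovery <- function(candidates, truth) {
  if (!setequal(candidates$gene_id, truth$gene_id))
    stop("candidate and truth gene universes differ")
  m <- match(candidates$gene_id, truth$gene_id)
  declared <- factor(candidates$classification,
                     levels = c("direct", "indirect", "unchanged"))
  true_cls <- factor(truth$true_class[m],
                     levels = c("direct", "indirect", "null"))
  confusion <- table(declared = declared, truth = true_cls)

  n_true_direct <- sum(true_cls == "direct")
  n_declared <- sum(declared == "direct")
  tp <- sum(declared == "direct" & true_cls == "direct")
  fp <- n_declared - tp
  n_null <- sum(true_cls == "null")
  null_declared <- sum(declared == "direct" & true_cls == "null")

  list(confusion = confusion,
       n_true_direct = n_true_direct,
       n_declared_direct = n_declared,
       true_positives = tp,
       false_positives = fp,
       sensitivity = if (n_true_direct > 0) tp / n_true_direct else NA_real_,
       fdp = if (n_declared > 0) fp / n_declared else 0,
       fdp_undefined = n_declared == 0,
       specificity = if (n_null > 0) 1 - null_declared / n_null else NA_real_)
}
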