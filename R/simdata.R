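#' Simulation configuration for the reporter read-length model
#'
#' The reporter transcript-length distribution is a three-peak mixture over
#' termination landmarks: premature Rho-dependent termination within the
#' elongation switch (~80 nt), termination at the end of the switch
#' (~140 nt), and full-length read-through (200 nt) when the probe
#' hybridizes its target. A region of true accessibility `a` produces
#' read-through with weight `a`; the remaining `1 - a` termination mass is
#' split `rho : (1 - rho)` between the early and late termination landmarks.
#' Per-read lengths get rounded Gaussian jitter.
#'
#' @param landmarks strictly increasing termination landmarks (nt); the last
#'   is the full-length read-through.
#' @param jitter_sd per-landmark length jitter standard deviation (nt).
#' @param rho share of the termination mass at the earliest landmark.
#' @param reads_per_probe sequencing depth per probe.
#' @param replicates biological replicates per strain.
#' @param shape1,shape2 Beta parameters for sampling true accessibilities.
#' @param acc_noise_sd per-replicate accessibility noise (sd, 0-1 scale).
#' @param ref_length reporter transcript length (nt); lengths are truncated
#'   to `[1, ref_length]`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(landmarks = c(80, 140, 200), jitter_sd = 3, rho = 0.7,
                       reads_per_probe = 10000L, replicates = 3L,
                       shape1 = 2, shape2 = 2, acc_noise_sd = 0.02,
                       ref_length = max(landmarks)) {
  if (is.unsorted(landmarks, strictly = TRUE)) stop("landmarks must be strictly increasing")
  if (reads_per_probe < 1L) stop("reads_per_probe must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(landmarks = landmarks, jitter_sd = jitter_sd, rho = rho,
                 reads_per_probe = as.integer(reads_per_probe),
                 replicates = as.integer(replicates),
                 shape1 = shape1, shape2 = shape2,
                 acc_noise_sd = acc_noise_sd,
                 ref_length = as.integer(ref_length)),
            class = "sim_config")
}

#' Sample ground-truth regional accessibilities
#'
#' Seeded Beta draws standing in for the stochastic process generating true
#' accessibility coefficients in algorithm benchmarking simulations.
#'
#' @param n number of regions.
#' @param shape1,shape2 Beta parameters.
#' @param seed optional integer seed.
#' @return numeric vector in `[0, 1]`.
#' @export
simulate_true_accessibilities <- function(n, shape1 = 2, shape2 = 2,
                                          seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rbeta(n, shape1, shape2)
}

#' Simulate per-probe transcript-length histograms
#'
#' Draws `reads` transcript lengths per probe from the three-peak mixture of
#' [sim_config()]: landmark weights `(1 - a) * rho`, `(1 - a) * (1 - rho)`
#' and `a` for a region of true accessibility `a`, plus rounded Gaussian
#' jitter, truncated to `[1, ref_length]`.
#'
#' @param truth per-probe true accessibilities in `[0, 1]`.
#' @param config a [sim_config()].
#' @param probe_ids probe identifiers (default `probe_01` ...).
#' @param reads reads per probe (default from `config`).
#' @return data.frame `probe_id`, `length`, `count`.
#' @export
simulate_histograms <- function(truth, config = sim_config(),
                                probe_ids = NULL, reads = NULL) {
  stopifnot(all(truth >= 0 & truth <= 1))
  n <- length(truth)
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%02d", seq_len(n))
  if (is.null(reads)) reads <- config$reads_per_probe
  lm <- config$landmarks
  k <- length(lm)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- truth[i]
    w <- c((1 - a) * config$rho, (1 - a) * (1 - config$rho), a)
    if (k != 3L) {  # general form: termination mass spread evenly below
      w <- c(rep((1 - a) / (k - 1), k - 1), a)
    }
    peak <- sample.int(k, reads, replace = TRUE, prob = w)
    len <- lm[peak] + round(rnorm(reads, 0, config$jitter_sd))
    len <- pmin(pmax(len, 1L), config$ref_length)
    tab <- table(len)
    out[[i]] <- data.frame(probe_id = probe_ids[i],
                           length = as.integer(names(tab)),
                           count = as.integer(tab))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full two-strain replicated reporter experiment
#'
#' For each strain and replicate, the per-region accessibility is the truth
#' (plus any planted strain effect) perturbed by Gaussian replicate noise,
#' clamped to `[0, 1]`, and converted to a length histogram.
#'
#' @param truth per-probe true accessibilities (wild-type strain).
#' @param config a [sim_config()].
#' @param probe_ids probe identifiers.
#' @param taRNA_id sRNA label for the stacked table.
#' @param strain_effect named list `strain -> per-probe accessibility deltas`
#'   (e.g. `list(dhfq = c(0, -0.4, 0, ...))`); strains absent from the list
#'   get delta 0. Default: single `wt` strain.
#' @param reads reads per probe (default from `config`).
#' @return stacked histogram data.frame with columns `probe_id`, `length`,
#'   `count`, `taRNA_id`, `strain`, `replicate`, ready for
#'   [accessibility_table()]; the per-replicate noisy accessibilities are in
#'   attribute `replicate_truth`.
#' @export
simulate_experiment <- function(truth, config = sim_config(),
                                probe_ids = NULL, taRNA_id = "sRNA1",
                                strain_effect = list(wt = 0), reads = NULL) {
  n <- length(truth)
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%02d", seq_len(n))
  out <- list(); rt <- list()
  for (strain in names(strain_effect)) {
    base <- pmin(pmax(truth + rep_len(strain_effect[[strain]], n), 0), 1)
    for (r in seq_len(config$replicates)) {
      a <- pmin(pmax(base + rnorm(n, 0, config$acc_noise_sd), 0), 1)
      h <- simulate_histograms(a, config, probe_ids, reads)
      h$taRNA_id <- taRNA_id
      h$strain <- strain
      h$replicate <- r
      out[[length(out) + 1L]] <- h
      rt[[paste(strain, r, sep = ".")]] <- a
    }
  }
  structure(do.call(rbind, out), replicate_truth = rt)
}

#' Emit simulated read pairs for a length histogram
#'
#' Expands a histogram into paired reads against the reference library:
#' R1 is the first `min(read_len, L_t)` nucleotides of the simulated
#' transcript, R2 the reverse complement of its last `min(read_len, L_t)`
#' nucleotides, sharing a read id (75 x 2 paired-end layout by default).
#' Error-free by default; `error_rate` applies uniform random substitutions
#' (documents the exact-matcher limitation, not an Illumina error model).
#'
#' @param hist histogram data.frame (`probe_id`, `length`, `count`).
#' @param refs reference library from [build_reference_library()].
#' @param read_len read length (nt).
#' @param error_rate per-base substitution probability.
#' @return data.frame `read_id`, `r1`, `r2`; transcripts shorter than the
#'   probe span are still emitted and counted in attribute `short`.
#' @export
simulate_read_pairs <- function(hist, refs, read_len = 75L, error_rate = 0) {
  ridx <- match(hist$probe_id, refs$probe_id)
  if (anyNA(ridx)) stop("histogram references unknown probe id")
  lt <- pmin(hist$length, refs$ref_length[ridx])
  tx <- substring(refs$ref_seq[ridx], 1L, lt)
  r1u <- substring(tx, 1L, pmin(read_len, lt))
  r2u <- reverse_complement(substring(tx, pmax(1L, lt - read_len + 1L), lt))
  idx <- rep(seq_len(nrow(hist)), hist$count)
  pairs <- data.frame(
    read_id = sprintf("read_%07d", seq_along(idx)),
    r1 = r1u[idx], r2 = r2u[idx])
  if (error_rate > 0) {
    mutate <- function(x) {
      vapply(strsplit(x, ""), function(b) {
        hit <- runif(length(b)) < error_rate
        b[hit] <- sample(c("A", "C", "G", "U"), sum(hit), replace = TRUE)
        paste(b, collapse = "")
      }, "")
    }
    pairs$r1 <- mutate(pairs$r1)
    pairs$r2 <- mutate(pairs$r2)
  }
  short <- lt[idx] < (refs$probe_end[ridx] - refs$tss[ridx] + 1L)[idx]
  structure(pairs, short = sum(short))
}

#' Write simulated read pairs as a paired FASTQ run
#'
#' @param pairs read pairs from [simulate_read_pairs()].
#' @param r1_path,r2_path output FASTQ paths (written as DNA with uniform
#'   qualities).
#' @return invisible character vector of the two paths.
#' @export
emit_paired_fastq <- function(pairs, r1_path, r2_path) {
  wr <- function(seqs, ids, path) {
    dna <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
    names(dna) <- ids
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      strrep("I", n), ""))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  }
  wr(pairs$r1, pairs$read_id, r1_path)
  wr(pairs$r2, pairs$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Generate a complete labelled fixture bundle
#'
#' Writes a self-contained synthetic dataset to `dir`: target RNA FASTA,
#' probe table, paired FASTQ for two strains (`wt`, `dhfq`) times
#' `config$replicates` replicates, a ground-truth CSV (including which
#' regions carry a planted Hfq effect) and a prediction CSV with one
#' interaction planted to overlap the most accessible region by exactly the
#' filter minimum of 5 nt.
#'
#' @param dir output directory (must be empty unless `force`).
#' @param config a [sim_config()].
#' @param n_probes number of tiled 12-nt probes.
#' @param reads reads per probe per replicate (bundle default 300 keeps the
#'   files small; raise for depth studies).
#' @param hfq_delta planted accessibility change in the `dhfq` strain.
#' @param n_hfq number of regions carrying the planted effect.
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param force overwrite a non-empty directory.
#' @return invisible list with the generated truth, probe table and file
#'   paths.
#' @export
make_fixture_bundle <- function(dir, config = sim_config(), n_probes = 12L,
                                reads = 300L, hfq_delta = 0.4, n_hfq = 3L,
                                seed = 1L, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory not empty (use force = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  w <- 12L
  L <- (n_probes - 1L) * 9L + w  # 12-mers tiled every 9 nt
  taRNA <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  start <- seq(1L, by = 9L, length.out = n_probes)
  probes <- data.frame(probe_id = sprintf("p%02d", seq_len(n_probes)),
                       taRNA_id = "sRNA1", start = start, end = start + w - 1L,
                       probe_seq = reverse_complement(substring(taRNA, start,
                                                                start + w - 1L)))
  refs <- build_reference_library(probes)
  truth <- simulate_true_accessibilities(n_probes, config$shape1, config$shape2)
  planted <- sort(sample.int(n_probes, n_hfq))
  delta <- numeric(n_probes)
  delta[planted] <- ifelse(truth[planted] > 0.5, -hfq_delta, hfq_delta)
  paths <- character(0)
  fa <- file.path(dir, "taRNA.fasta")
  write_fasta(c(sRNA1 = taRNA), fa)
  pt <- file.path(dir, "probes.tsv")
  write_probe_table(probes, pt)
  for (strain in c("wt", "dhfq")) {
    base <- pmin(pmax(truth + if (strain == "dhfq") delta else 0, 0), 1)
    for (r in seq_len(config$replicates)) {
      a <- pmin(pmax(base + rnorm(n_probes, 0, config$acc_noise_sd), 0), 1)
      h <- simulate_histograms(a, config, probes$probe_id, reads)
      pairs <- simulate_read_pairs(h, refs)
      p1 <- file.path(dir, sprintf("r1_%s_rep%d.fastq", strain, r))
      p2 <- file.path(dir, sprintf("r2_%s_rep%d.fastq", strain, r))
      emit_paired_fastq(pairs, p1, p2)
      paths <- c(paths, p1, p2)
    }
  }
  truth_df <- data.frame(probe_id = probes$probe_id, start = probes$start,
                         end = probes$end, truth_wt = truth,
                         truth_dhfq = pmin(pmax(truth + delta, 0), 1),
                         hfq_planted = seq_len(n_probes) %in% planted)
  tc <- file.path(dir, "truth.csv")
  write.csv(truth_df, tc, row.names = FALSE)
  # synthetic predictions: 20 ranked pairs; rank 1 planted to overlap the
  # most accessible region by exactly 5 nt
  best <- which.max(truth)
  n_pred <- 20L
  ps <- pmin(pmax(sample.int(L - 8L, n_pred, replace = TRUE), 1L), L - 8L)
  preds <- data.frame(mrna = sprintf("gene%03d", sample.int(999, n_pred)),
                      rank = seq_len(n_pred),
                      energy = sort(round(runif(n_pred, -20, -5), 2)),
                      srna_start = ps, srna_end = ps + 8L,
                      mrna_start = sample(-60:40, n_pred, replace = TRUE),
                      mrna_end = NA_integer_)
  preds$mrna_end <- preds$mrna_start + 8L
  preds$srna_start[1] <- probes$end[best] - 4L
  preds$srna_end[1] <- probes$end[best] + 4L
  pc <- file.path(dir, "predictions.csv")
  write.csv(preds, pc, row.names = FALSE)
  invisible(list(truth = truth_df, probes = probes,
                 paths = c(fa, pt, tc, pc, paths)))
}
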