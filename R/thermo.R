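#' Fold an RNA sequence into its Boltzmann ensemble
#'
#' Runs McCaskill-style inside/outside recursions (O(n^3) inside, pair
#' probabilities by a top-down outside pass) over the nested structure space
#' of [energy_model()]: Watson-Crick plus GU pairs, hairpin loops of at least
#' `min_hairpin_loop` nucleotides, no pseudoknots. The empty structure is
#' always part of the ensemble, so Z >= 1 and the ensemble free energy
#' -RT ln Z is <= 0.
#'
#' @param seq a single RNA sequence (character scalar; T accepted).
#' @param model an [energy_model()].
#' @return an object of class `fold_ensemble` with elements `seq`, `n`,
#'   `Z`, `logZ`, `ensemble_dG` (kcal/mol), `pair_prob` (n x n symmetric
#'   matrix) and `unpaired_prob` (length-n vector, `1 - rowSums(pair_prob)`).
#' @export
#' @examples
#' ens <- fold_ensemble("GGGAAACCC")
#' ens$unpaired_prob
fold_ensemble <- function(seq, model = energy_model()) {
  seq <- normalize_rna(seq)
  if (length(seq) != 1L) stop("fold_ensemble takes a single sequence")
  n <- nchar(seq)
  check_fold_length(n)
  s <- encode_rna(seq)
  res <- .pf_pairprob(s, unname(model$emat), model$min_hairpin_loop,
                      model$rt, model$sigma)
  P <- res$pair_prob
  up <- pmin(pmax(1 - rowSums(P), 0), 1)
  structure(
    list(seq = seq, n = n, Z = exp(res$logZ), logZ = res$logZ,
         ensemble_dG = -model$rt * res$logZ,
         pair_prob = P, unpaired_prob = up, model = model),
    class = "fold_ensemble")
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat("Fold ensemble:", x$n, "nt, ln Z =", format(x$logZ, digits = 6),
      ", ensemble dG =", format(x$ensemble_dG, digits = 6), "kcal/mol\n")
  cat("mean unpaired probability:", format(mean(x$unpaired_prob), digits = 4), "\n")
  invisible(x)
}

check_interval <- function(interval, n) {
  if (length(interval) != 2L || any(!is.finite(interval))) stop("interval must be c(start, end)")
  i <- as.integer(interval[1]); j <- as.integer(interval[2])
  if (i < 1L || j > n || i > j)
    stop("interval [", i, ",", j, "] out of bounds for length ", n)
  c(i, j)
}

#' Per-nucleotide unpaired probabilities over a region
#'
#' Restriction of the ensemble unpaired profile to a 1-based closed interval.
#' The sum of this profile is the pseudo-frequency factor entering the
#' hybridization score.
#'
#' @param ens a [fold_ensemble()].
#' @param interval integer vector `c(start, end)`, 1-based closed.
#' @return numeric vector of unpaired probabilities, one per position.
#' @export
unpaired_profile <- function(ens, interval) {
  stopifnot(inherits(ens, "fold_ensemble"))
  ij <- check_interval(interval, ens$n)
  ens$unpaired_prob[ij[1]:ij[2]]
}

#' Free energy of the probe:target duplex
#'
#' Probes are designed as exact Watson-Crick reverse complements of their
#' target region, so the duplex is perfect and its energy is the sum of the
#' pair energies over all formed pairs.
#'
#' @param probe antisense probe sequence.
#' @param target_region the target region it was designed against.
#' @param model an [energy_model()].
#' @return duplex free energy in kcal/mol (<= 0).
#' @export
#' @examples
#' duplex_energy("CCC", "GGG")  # 3 GC pairs = -9
duplex_energy <- function(probe, target_region, model = energy_model()) {
  probe <- normalize_rna(probe); target_region <- normalize_rna(target_region)
  if (nchar(probe) != nchar(target_region))
    stop("probe and target region lengths differ")
  if (probe != reverse_complement(target_region))
    stop("probe is not the reverse complement of the target region")
  p <- strsplit(probe, "")[[1]]
  t <- rev(strsplit(target_region, "")[[1]])
  sum(model$emat[cbind(p, t)])
}

#' Target-region opening free energy
#'
#' Free-energy cost of constraining every nucleotide of the interval to be
#' unpaired: `dG_open = -RT ln(Z_constrained / Z) >= 0`, where the
#' constrained partition function sums only structures leaving the whole
#' interval single-stranded.
#'
#' @param seq target RNA sequence.
#' @param interval 1-based closed interval to open.
#' @param model an [energy_model()].
#' @return opening free energy in kcal/mol (>= 0).
#' @export
opening_energy <- function(seq, interval, model = energy_model()) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  check_fold_length(n)
  ij <- check_interval(interval, n)
  s <- encode_rna(seq)
  h <- model$min_hairpin_loop
  mask0 <- rep(FALSE, n)
  mask1 <- mask0
  mask1[ij[1]:ij[2]] <- TRUE
  logz <- .pf_partition(s, unname(model$emat), h, model$rt, model$sigma, mask0)
  logzc <- .pf_partition(s, unname(model$emat), h, model$rt, model$sigma, mask1)
  max(model$rt * (logz - logzc), 0)
}

#' Probe self-folding free energy
#'
#' Minimum free energy of the probe over the nested structure space; 0 when
#' no structure can form. Probe design targets 9-26 nt; lengths outside that
#' range are accepted with a warning (library mode).
#'
#' @param probe antisense probe sequence.
#' @param model an [energy_model()].
#' @return minimum free energy in kcal/mol (<= 0).
#' @export
probe_folding_energy <- function(probe, model = energy_model()) {
  probe <- normalize_rna(probe)
  n <- nchar(probe)
  if (n < 9L || n > 26L)
    warning("probe length ", n, " nt outside the designed 9-26 nt range")
  check_fold_length(n)
  .pf_mfe(encode_rna(probe), unname(model$emat), model$min_hairpin_loop)
}
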