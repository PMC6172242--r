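#' Exhaustively enumerate the nested structure space (testing oracle)
#'
#' Direct recursive enumeration of every pseudoknot-free pair set respecting
#' the minimum hairpin loop, with exact Boltzmann sums. This is the
#' independent oracle for the dynamic-programming engine: it shares no code
#' with [fold_ensemble()] beyond the energy lookup. Refuses sequences longer
#' than 18 nt (combinatorial guard).
#'
#' @param seq RNA sequence, at most 18 nt.
#' @param model an [energy_model()].
#' @return a list with `structures` (list of 2-column pair matrices, 1-based),
#'   `energies` (kcal/mol per structure), `Z`, `pair_prob`, `unpaired_prob`
#'   and `mfe`.
#' @export
#' @examples
#' enumerate_structures("GAAAC")$Z
enumerate_structures <- function(seq, model = energy_model()) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n > 18L) stop("enumeration refused for n > 18 (oracle only)")
  b <- strsplit(seq, "")[[1]]
  h <- model$min_hairpin_loop
  pairable <- function(i, j) is.finite(model$emat[b[i], b[j]])

  # all pair sets on [i, j]; each structure a 2-column matrix of pairs
  empty <- matrix(integer(0), ncol = 2)
  enum <- function(i, j) {
    if (j - i < h + 1L) return(list(empty))
    out <- enum(i, j - 1L)                  # j unpaired
    for (k in i:(j - h - 1L)) {             # j paired with k
      if (!pairable(k, j)) next
      left <- enum(i, k - 1L)
      right <- enum(k + 1L, j - 1L)
      for (ls in left) for (rs in right)
        out[[length(out) + 1L]] <- rbind(ls, rs, c(k, j))
    }
    out
  }
  structures <- if (n == 1L) list(empty) else enum(1L, n)

  energies <- vapply(structures, function(st) {
    if (nrow(st) == 0L) return(0)
    sum(model$emat[cbind(b[st[, 1]], b[st[, 2]])])
  }, 0)
  w <- exp(-energies / model$rt)
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (m in seq_along(structures)) {
    st <- structures[[m]]
    if (nrow(st) == 0L) next
    idx <- rbind(st, st[, 2:1, drop = FALSE])
    P[idx] <- P[idx] + w[m]
  }
  P <- P / Z
  list(structures = structures, energies = energies, Z = Z,
       pair_prob = P, unpaired_prob = 1 - rowSums(P), mfe = min(energies))
}

#' Opening free energy by exhaustive enumeration (testing oracle)
#'
#' Constrained-versus-unconstrained ensemble free-energy difference computed
#' directly from the enumerated structure list.
#'
#' @inheritParams enumerate_structures
#' @param interval 1-based closed interval forced unpaired.
#' @return opening free energy in kcal/mol.
#' @export
enumerate_opening_energy <- function(seq, interval, model = energy_model()) {
  enum <- enumerate_structures(seq, model)
  ij <- check_interval(interval, nchar(normalize_rna(seq)))
  keep <- vapply(enum$structures, function(st) {
    nrow(st) == 0L || !any(st >= ij[1] & st <= ij[2])
  }, TRUE)
  zc <- sum(exp(-enum$energies[keep] / model$rt))
  -model$rt * log(zc / enum$Z)
}
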