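#' Nucleic-acid pair energy model
#'
#' The folding engine scores a nested secondary structure as the sum of its
#' base-pair energies: one constant per pair class (GC, AU, GU wobble), with a
#' minimum hairpin loop and thermal energy RT. This deliberately simple model
#' keeps the whole structure ensemble exactly enumerable (see
#' [enumerate_structures()]); a nearest-neighbor engine can be substituted
#' behind the same interface without changing any downstream code.
#'
#' @param gc,au,gu pair energies in kcal/mol (finite, <= 0).
#' @param min_hairpin_loop minimum number of unpaired nucleotides enclosed by
#'   a hairpin-closing pair (>= 3).
#' @param rt thermal energy kcal/mol; default 0.616 corresponds to 37 degrees C.
#' @return an object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' m$pair_energy
energy_model <- function(gc = -3.0, au = -2.0, gu = -1.0,
                         min_hairpin_loop = 3L, rt = 0.616) {
  pe <- c(GC = gc, AU = au, GU = gu)
  if (any(!is.finite(pe)) || any(pe > 0)) stop("pair energies must be finite and <= 0")
  if (min_hairpin_loop < 3L) stop("min_hairpin_loop must be >= 3")
  if (!is.finite(rt) || rt <= 0) stop("RT must be > 0")
  # 4x4 energy lookup, base order A C G U; Inf = not pairable
  emat <- matrix(Inf, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  emat["G","C"] <- emat["C","G"] <- gc
  emat["A","U"] <- emat["U","A"] <- au
  emat["G","U"] <- emat["U","G"] <- gu
  structure(
    list(pair_energy = pe, min_hairpin_loop = as.integer(min_hairpin_loop),
         rt = rt, emat = emat,
         # per-base scaling factor keeping the scaled partition function O(1);
         # valid for sequences up to ~500 nt under the default energies
         sigma = exp(-min(pe) / (4 * rt))),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Pair energy model (kcal/mol): GC", x$pair_energy[["GC"]],
      " AU", x$pair_energy[["AU"]], " GU", x$pair_energy[["GU"]], "\n")
  cat("min hairpin loop:", x$min_hairpin_loop, " RT:", x$rt, "\n")
  invisible(x)
}

.MAX_FOLD_N <- 500L

check_fold_length <- function(n) {
  if (n > .MAX_FOLD_N)
    stop("sequence longer than ", .MAX_FOLD_N,
         " nt exceeds the numeric range of the scaled recursions")
}
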