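#' Enumerate candidate target regions on an RNA
#'
#' All contiguous windows of the design lengths (default 9-16 nt), or a
#' seeded random sample of them without replacement.
#'
#' @param taRNA target RNA sequence.
#' @param min_len,max_len window length bounds (design mode uses 9-16 nt).
#' @param mode `"exhaustive"` (all windows) or `"random"` (seeded subsample).
#' @param sample_size number of windows to draw in random mode; capped at the
#'   total window count with a warning.
#' @param seed integer seed for random mode (same seed, same sample).
#' @return data.frame with columns `start`, `end`, `length`, `region_seq`,
#'   `probe_seq` (reverse complement of the region).
#' @export
#' @examples
#' nrow(candidate_regions(strrep("A", 20)))  # sum over w = 9..16 of 20-w+1 = 76
candidate_regions <- function(taRNA, min_len = 9L, max_len = 16L,
                              mode = c("exhaustive", "random"),
                              sample_size = NULL, seed = NULL) {
  mode <- match.arg(mode)
  taRNA <- normalize_rna(taRNA)
  L <- nchar(taRNA)
  if (L < min_len) stop("target RNA shorter than min_len")
  lens <- seq.int(min_len, min(max_len, L))
  start <- unlist(lapply(lens, function(w) seq_len(L - w + 1L)))
  len <- rep(lens, vapply(lens, function(w) L - w + 1L, 0L))
  df <- data.frame(start = start, end = start + len - 1L, length = len)
  if (mode == "random") {
    if (is.null(sample_size)) stop("sample_size required in random mode")
    if (!is.null(seed)) set.seed(seed)
    if (sample_size > nrow(df)) {
      warning("sample_size exceeds window count (", nrow(df), "); capped")
      sample_size <- nrow(df)
    }
    df <- df[sort(sample.int(nrow(df), sample_size)), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$region_seq <- substring(taRNA, df$start, df$end)
  df$probe_seq <- reverse_complement(df$region_seq)
  df
}

#' Biophysical hybridization score of a candidate region
#'
#' Scores the propensity of an antisense probe to hybridize its target
#' region in vivo as
#' \deqn{\nu = \bar\theta\,(\Delta G_{tf} - \Delta G_{asT}) + \Delta G_{asF}}
#' where \eqn{\bar\theta} is the sum of per-nucleotide unpaired probabilities
#' over the region (pseudo-frequency factor), \eqn{\Delta G_{tf}} the
#' target-opening cost, \eqn{\Delta G_{asT}} the probe:target duplex energy
#' and \eqn{\Delta G_{asF}} the probe self-folding energy.
#'
#' @param regions data.frame as from [candidate_regions()] (columns `start`,
#'   `end`; region/probe sequences are recomputed from `taRNA`).
#' @param taRNA the target RNA sequence the regions live on.
#' @param model an [energy_model()].
#' @param ensemble optional precomputed [fold_ensemble()] of `taRNA`.
#' @return `regions` with added columns `theta_bar`, `dG_tf`, `dG_asT`,
#'   `dG_asF` and `nu`.
#' @export
hybridization_score <- function(regions, taRNA, model = energy_model(),
                                ensemble = NULL) {
  taRNA <- normalize_rna(taRNA)
  if (is.null(ensemble)) ensemble <- fold_ensemble(taRNA, model)
  stopifnot(inherits(ensemble, "fold_ensemble"), ensemble$seq == taRNA)
  n <- nrow(regions)
  out <- regions
  out$region_seq <- substring(taRNA, regions$start, regions$end)
  out$probe_seq <- reverse_complement(out$region_seq)
  out$theta_bar <- vapply(seq_len(n), function(k)
    sum(unpaired_profile(ensemble, c(regions$start[k], regions$end[k]))), 0)
  out$dG_tf <- vapply(seq_len(n), function(k)
    opening_energy(taRNA, c(regions$start[k], regions$end[k]), model), 0)
  out$dG_asT <- vapply(seq_len(n), function(k)
    duplex_energy(out$probe_seq[k], out$region_seq[k], model), 0)
  out$dG_asF <- vapply(seq_len(n), function(k)
    suppressWarnings(probe_folding_energy(out$probe_seq[k], model)), 0)
  out$nu <- out$theta_bar * (out$dG_tf - out$dG_asT) + out$dG_asF
  out
}

#' Knowledge-gradient value of measuring one alternative
#'
#' Independent-normal knowledge gradient for ranking-and-selection: the
#' expected gain in the posterior maximum from one noisy measurement of
#' alternative k, given belief means `mu`, belief variances `sigma2` and
#' measurement noise variance `noise_var`. Closed form:
#' `sigtilde_k = sigma2_k / sqrt(sigma2_k + noise_var)`,
#' `zeta_k = -|mu_k - max_{j != k} mu_j| / sigtilde_k`,
#' `v_k = sigtilde_k * (zeta_k * Phi(zeta_k) + phi(zeta_k))`.
#'
#' @param mu belief means (length >= 2).
#' @param sigma2 belief variances (>= 0), recycled.
#' @param noise_var measurement noise variance (> 0).
#' @return nonnegative knowledge-gradient values, zero exactly where
#'   `sigtilde` is zero.
#' @export
#' @examples
#' kg_value(c(0, 0), c(1, 1), 1)  # both ~ dnorm(0)/sqrt(2) = 0.28209
kg_value <- function(mu, sigma2, noise_var = 1) {
  n <- length(mu)
  if (n < 2L) stop("knowledge gradient needs at least 2 alternatives")
  sigma2 <- rep_len(sigma2, n)
  if (any(sigma2 < 0)) stop("belief variances must be >= 0")
  if (noise_var <= 0) stop("noise variance must be > 0")
  sigtilde <- sigma2 / sqrt(sigma2 + noise_var)
  # best competing mean for each k
  ord <- order(mu, decreasing = TRUE)
  best <- mu[ord[1]]; second <- mu[ord[2]]
  competing <- ifelse(seq_len(n) == ord[1], second, best)
  v <- numeric(n)
  pos <- sigtilde > 0
  zeta <- -abs(mu[pos] - competing[pos]) / sigtilde[pos]
  v[pos] <- sigtilde[pos] * (zeta * pnorm(zeta) + dnorm(zeta))
  pmax(v, 0)
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Greedy weighted set cover over an interval
#'
#' Approximates the NP-complete weighted set-cover design problem
#' (maximize total region value minus a per-region penalty `lambda`, subject
#' to full coverage of `[1, L]`): at each step compute, for every unselected
#' region with nonzero marginal coverage,
#' `alpha_k = (lambda - v_k) / |[i_k, j_k] \ C|` and select the argmin.
#' Ties break to the smallest start, then the shortest region. Regions whose
#' marginal coverage has dropped to zero leave the candidate pool.
#'
#' @param starts,ends 1-based closed candidate intervals.
#' @param v per-region values (e.g. knowledge-gradient values), same length.
#' @param lambda per-region penalty (>= 0); larger values favour fewer regions.
#' @param L target RNA length; coverage target is `[1, L]`.
#' @return an object of class `cover_design`: `selected` (indices in
#'   selection order), `trace` (data.frame of step, index, alpha, marginal
#'   gain), `lambda`, `L`.
#' @export
#' @examples
#' d <- greedy_set_cover(c(1, 5, 1), c(6, 10, 10), v = c(0.5, 0.5, 0.1),
#'                       lambda = 1, L = 10)
#' d$selected  # 1 then 2
greedy_set_cover <- function(starts, ends, v, lambda = 1, L) {
  n <- length(starts)
  stopifnot(length(ends) == n, length(v) == n, n >= 1L, lambda >= 0)
  if (any(starts < 1L | ends > L | starts > ends))
    stop("candidate intervals out of bounds")
  cov_all <- rep(FALSE, L)
  for (k in seq_len(n)) cov_all[starts[k]:ends[k]] <- TRUE
  if (!all(cov_all))
    stop("candidates cannot cover [1,", L, "]; uncovered: ",
         paste(which(!cov_all), collapse = ","))
  covered <- rep(FALSE, L)
  selected <- integer(0)
  trace <- list()
  step <- 0L
  while (!all(covered)) {
    step <- step + 1L
    pool <- setdiff(seq_len(n), selected)
    marg <- vapply(pool, function(k) sum(!covered[starts[k]:ends[k]]), 0L)
    pool <- pool[marg > 0L]; marg <- marg[marg > 0L]
    alpha <- (lambda - v[pool]) / marg
    best <- order(alpha, starts[pool], ends[pool] - starts[pool])[1]
    k <- pool[best]
    trace[[step]] <- data.frame(step = step, index = k, alpha = alpha[best],
                                marginal = marg[best])
    covered[starts[k]:ends[k]] <- TRUE
    selected <- c(selected, k)
  }
  structure(list(selected = selected, trace = do.call(rbind, trace),
                 lambda = lambda, L = L),
            class = "cover_design")
}

#' @export
print.cover_design <- function(x, ...) {
  cat("Greedy weighted set cover: ", length(x$selected), " regions covering [1,",
      x$L, "], lambda = ", x$lambda, "\n", sep = "")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Design an antisense probe panel over a target RNA
#'
#' End-to-end panel design. `"kg"` scores every candidate window with the
#' biophysical model, converts the min-max-normalized scores into
#' knowledge-gradient values ([kg_value()]) and runs the greedy weighted set
#' cover; `"exploit"` uses the normalized biophysical scores directly as
#' region values (same coverage and overlap constraints, no value-of-
#' information step); `"explore"` tiles seeded random 12-mers until the RNA
#' is covered.
#'
#' @param taRNA target RNA sequence (named scalar or plain character).
#' @param mode `"kg"`, `"exploit"` or `"explore"`.
#' @param min_len,max_len candidate window lengths.
#' @param lambda set-cover penalty.
#' @param prior_var,noise_var knowledge-gradient belief and noise variances.
#' @param seed seed for `"explore"` mode.
#' @param model an [energy_model()].
#' @return an object of class `probe_design`: `regions` (scored candidate
#'   table, `"explore"` carries sequences only), `selected` (row indices of
#'   the panel), `panel` (selected rows with probe sequences), `design`
#'   (the [greedy_set_cover()] object, modes kg/exploit), `mode`.
#' @export
design_probes <- function(taRNA, mode = c("kg", "exploit", "explore"),
                          min_len = 9L, max_len = 16L, lambda = 1,
                          prior_var = 1, noise_var = 1, seed = NULL,
                          model = energy_model()) {
  mode <- match.arg(mode)
  id <- if (!is.null(names(taRNA))) names(taRNA)[1] else "taRNA"
  taRNA <- normalize_rna(unname(taRNA))
  L <- nchar(taRNA)
  if (mode == "explore") {
    if (!is.null(seed)) set.seed(seed)
    w <- 12L
    if (L < w) stop("target RNA shorter than the 12-nt exploration window")
    covered <- rep(FALSE, L)
    start <- integer(0)
    while (!all(covered)) {
      s <- sample.int(L - w + 1L, 1L)
      start <- c(start, s)
      covered[s:(s + w - 1L)] <- TRUE
    }
    regions <- data.frame(start = start, end = start + w - 1L, length = w)
    regions$region_seq <- substring(taRNA, regions$start, regions$end)
    regions$probe_seq <- reverse_complement(regions$region_seq)
    out <- list(regions = regions, selected = seq_len(nrow(regions)),
                panel = regions, design = NULL, mode = mode,
                taRNA_id = id, L = L)
    return(structure(out, class = "probe_design"))
  }
  regions <- candidate_regions(taRNA, min_len, max_len)
  scored <- hybridization_score(regions, taRNA, model)
  mu <- minmax_scale(scored$nu)
  scored$v <- switch(mode,
    exploit = mu,
    kg = kg_value(mu, prior_var, noise_var))
  design <- greedy_set_cover(scored$start, scored$end, scored$v, lambda, L)
  panel <- scored[design$selected, , drop = FALSE]
  panel$probe_id <- sprintf("%s_%03d", id, seq_len(nrow(panel)))
  rownames(panel) <- NULL
  structure(list(regions = scored, selected = design$selected, panel = panel,
                 design = design, mode = mode, taRNA_id = id, L = L),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat("Probe panel (", x$mode, " mode): ", length(x$selected),
      " probes covering [1,", x$L, "] of ", x$taRNA_id, "\n", sep = "")
  cols <- intersect(c("probe_id", "start", "end", "probe_seq", "nu", "v"),
                    names(x$panel))
  print(head(x$panel[, cols], 10), row.names = FALSE)
  invisible(x)
}

#' Keep the top fraction of value-ranked regions
#'
#' Post-hoc rank filter applied across RNAs: retains the globally highest
#' `fraction` of regions by value (default 1.5 percent).
#'
#' @param v region values (e.g. knowledge-gradient values pooled over RNAs).
#' @param fraction fraction to keep in (0, 1]; at least one region is kept.
#' @return logical vector marking retained regions.
#' @export
top_fraction <- function(v, fraction = 0.015) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, round(fraction * length(v)))
  rank(-v, ties.method = "first") <= k
}

#' Experimental-effort benchmark metric
#'
#' For one RNA, the raw effort of a probe selection is the gap between the
#' best true accessibility over all candidates and the best true
#' accessibility among the selected regions; zero means the optimal region
#' was probed. [rescale_efforts()] maps a set of algorithms' efforts onto
#' `[0, 1]` for comparison.
#'
#' @param truth true accessibility of every candidate region.
#' @param selected indices of the selected regions.
#' @return raw experimental effort (>= 0).
#' @export
experimental_effort <- function(truth, selected) {
  if (length(selected) == 0L) stop("empty selection")
  max(truth) - max(truth[selected])
}

#' @rdname experimental_effort
#' @param efforts raw efforts, one per compared algorithm.
#' @export
rescale_efforts <- function(efforts) {
  r <- range(efforts)
  if (r[1] == r[2]) return(rep(0, length(efforts)))
  (efforts - r[1]) / (r[2] - r[1])
}
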