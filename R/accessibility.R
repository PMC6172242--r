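#' Weighted-average transcript length per probe
#'
#' `sum(length * count) / sum(count)` over a probe's length histogram.
#' Probes with zero reads get `NA` (missing, never 0) and are counted in the
#' `missing` attribute.
#'
#' @param hist length-histogram data.frame (`probe_id`, `length`, `count`),
#'   as from [length_histograms()].
#' @return named numeric vector of weighted-average lengths (nt) per probe.
#' @export
#' @examples
#' h <- data.frame(probe_id = "p", length = c(80, 140, 200), count = c(3, 1, 1))
#' weighted_average_length(h)  # (240 + 140 + 200) / 5 = 116
weighted_average_length <- function(hist) {
  stopifnot(all(c("probe_id", "length", "count") %in% names(hist)))
  tot <- tapply(hist$count, hist$probe_id, sum)
  wsum <- tapply(hist$length * hist$count, hist$probe_id, sum)
  wa <- wsum / tot
  wa[tot == 0] <- NA_real_
  structure(as.numeric(wa), names = names(wa),
            missing = sum(tot == 0))
}

#' Relative accessibility in overexpression mode
#'
#' For reporter runs against an overexpressed target RNA: both weighted
#' averages are adjusted by the baseline transcript size (the minimum
#' reporter transcript length, 85 nt in the original assay), floored at zero,
#' and accessibility is the induced/uninduced ratio of the adjusted values.
#'
#' @param wa_induced,wa_uninduced weighted-average transcript lengths with and
#'   without target induction (nt); vectorized.
#' @param baseline baseline transcript size in nt.
#' @return accessibility ratios; `NA` where the uninduced adjusted average is
#'   not positive (logged via warning).
#' @export
#' @examples
#' overexpression_accessibility(185, 135)  # 100/50 = 2
overexpression_accessibility <- function(wa_induced, wa_uninduced,
                                         baseline = 85) {
  num <- pmax(wa_induced - baseline, 0)
  den <- pmax(wa_uninduced - baseline, 0)
  bad <- !is.na(den) & den <= 0
  if (any(bad))
    warning(sum(bad), " region(s) with non-positive uninduced adjusted ",
            "average; accessibility set to NA")
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Raw accessibility in native mode
#'
#' For native target RNAs: weighted-average transcript lengths are adjusted
#' by the baseline (164 nt in the original assay; negative adjusted values
#' floored at 0) and then min-max normalized to `[0, 1]` within each
#' sRNA-replicate group.
#'
#' @param wa weighted-average transcript lengths (nt).
#' @param group grouping factor (one level per sRNA x replicate x strain).
#' @param baseline baseline transcript size in nt; `"auto"` uses the minimum
#'   observed weighted average across the run.
#' @return raw accessibilities in `[0, 1]`; degenerate groups (max = min, or
#'   a single region) are set to 0.5 with a warning.
#' @export
native_raw_accessibility <- function(wa, group, baseline = 164) {
  if (identical(baseline, "auto")) baseline <- min(wa, na.rm = TRUE)
  adj <- pmax(wa - baseline, 0)
  out <- rep(NA_real_, length(adj))
  degen <- character(0)
  for (g in split(seq_along(adj), group)) {
    x <- adj[g]
    r <- range(x, na.rm = TRUE)
    if (!is.finite(r[1]) || r[1] == r[2]) {
      out[g] <- 0.5
      degen <- c(degen, as.character(group[g[1]]))
    } else out[g] <- (x - r[1]) / (r[2] - r[1])
  }
  if (length(degen))
    warning("degenerate normalization group(s) set to 0.5: ",
            paste(degen, collapse = ", "))
  out
}

#' Reported accessibility: replicate mean, second normalization, SE
#'
#' Raw accessibilities are averaged over replicates per region, the means are
#' min-max normalized once more within each sRNA, and the replicate standard
#' error is propagated through that second normalization by the same linear
#' map (its min and max treated as constants).
#'
#' @param raw matrix of raw accessibilities, regions in rows, replicates in
#'   columns (`NA` allowed for depth-limited regions).
#' @return data.frame `mean_raw`, `reported`, `se`, `n_rep` (one row per
#'   region, ordered as the input rows).
#' @export
#' @examples
#' m <- rbind(a = c(0.2, 0.4, 0.6), b = c(0, 0, 0), c = c(1, 1, 1))
#' reported_accessibility(m)
reported_accessibility <- function(raw) {
  raw <- as.matrix(raw)
  n_rep <- rowSums(!is.na(raw))
  if (any(n_rep < 1L)) stop("every region needs at least one replicate")
  mean_raw <- rowMeans(raw, na.rm = TRUE)
  se_raw <- apply(raw, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / sqrt(length(x))
  })
  r <- range(mean_raw)
  if (r[1] == r[2]) {
    warning("degenerate second normalization; reported set to 0.5")
    reported <- rep(0.5, length(mean_raw))
    scale <- NA_real_
  } else {
    scale <- r[2] - r[1]
    reported <- (mean_raw - r[1]) / scale
  }
  data.frame(mean_raw = mean_raw, reported = reported,
             se = se_raw / scale, n_rep = n_rep,
             row.names = rownames(raw))
}

#' Full native-mode accessibility table from length histograms
#'
#' Pipeline convenience wrapper: weighted-average lengths per probe and
#' replicate, baseline adjustment, within-replicate raw normalization, then
#' replicate aggregation with the second normalization and SE propagation,
#' per sRNA and strain.
#'
#' @param hists data.frame with columns `probe_id`, `length`, `count`,
#'   `taRNA_id`, `replicate` and optionally `strain` (histograms of all
#'   replicates stacked).
#' @param baseline baseline transcript size (nt) or `"auto"` (minimum
#'   observed transcript length across the run, the rule by which the
#'   published constants were derived; use `auto` whenever the reporter
#'   scaffold differs from the published one).
#' @return data.frame with one row per (taRNA, strain, probe): columns
#'   `taRNA_id`, `strain`, `probe_id`, `mean_raw`, `reported`, `se`, `n_rep`.
#'   The per-replicate intermediate values (weighted averages and raw
#'   accessibilities) are attached as attribute `replicates`.
#' @export
accessibility_table <- function(hists, baseline = 164) {
  stopifnot(all(c("probe_id", "length", "count", "taRNA_id", "replicate")
                %in% names(hists)))
  if (is.null(hists$strain)) hists$strain <- "wt"
  key <- interaction(hists$taRNA_id, hists$strain, hists$replicate,
                     hists$probe_id, drop = TRUE)
  tot <- tapply(hists$count, key, sum)
  wsum <- tapply(hists$length * hists$count, key, sum)
  meta <- hists[!duplicated(key), c("taRNA_id", "strain", "replicate", "probe_id")]
  meta <- meta[match(names(tot), as.character(key[!duplicated(key)])), ]
  meta$wa <- as.numeric(wsum / tot)
  if (identical(baseline, "auto"))
    baseline <- min(hists$length[hists$count > 0], na.rm = TRUE)
  grp <- interaction(meta$taRNA_id, meta$strain, meta$replicate, drop = TRUE)
  meta$raw <- native_raw_accessibility(meta$wa, grp, baseline)
  out <- list()
  for (g in split(meta, interaction(meta$taRNA_id, meta$strain, drop = TRUE))) {
    reps <- sort(unique(g$replicate))
    probes <- unique(g$probe_id)
    raw <- matrix(NA_real_, length(probes), length(reps),
                  dimnames = list(probes, reps))
    raw[cbind(match(g$probe_id, probes), match(g$replicate, reps))] <- g$raw
    rep_tab <- reported_accessibility(raw)
    out[[length(out) + 1L]] <- cbind(
      data.frame(taRNA_id = g$taRNA_id[1], strain = g$strain[1],
                 probe_id = probes),
      rep_tab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  rownames(meta) <- NULL
  structure(res, replicates = meta)
}

#' Spread per-replicate raw accessibilities into a region-by-replicate matrix
#'
#' Helper for strain comparisons: extracts the `replicates` attribute of an
#' [accessibility_table()] for one strain as the matrix [compare_strains()]
#' expects.
#'
#' @param tab result of [accessibility_table()].
#' @param strain strain label to extract.
#' @return numeric matrix, regions (probe ids) x replicates.
#' @export
replicate_matrix <- function(tab, strain = "wt") {
  meta <- attr(tab, "replicates")
  if (is.null(meta)) stop("table carries no replicate attribute")
  m <- meta[meta$strain == strain, ]
  if (nrow(m) == 0L) stop("no rows for strain ", strain)
  probes <- unique(m$probe_id)
  reps <- sort(unique(m$replicate))
  out <- matrix(NA_real_, length(probes), length(reps),
                dimnames = list(probes, reps))
  out[cbind(match(m$probe_id, probes), match(m$replicate, reps))] <- m$raw
  out
}
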