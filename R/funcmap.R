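#' Scan a sequence for the YUNR RNA:RNA recognition motif
#'
#' Exact scan for the tetramer class pyrimidine-U-any-purine
#' (`[CU][U][ACGU][AG]`), the loop motif associated with antisense RNA
#' recognition. The match p-value is the exact probability that a random
#' 4-mer drawn from the background matches the motif (1/16 under the uniform
#' background: enumeration of the 256 4-mers gives 16 matches); the
#' sequence-level p-value for at least one match over the `m = n - 3` scanned
#' positions is `1 - (1 - p_match)^m`.
#'
#' @param seq RNA sequence.
#' @param background named base frequencies (A, C, G, U); `"uniform"` for
#'   1/4 each, `"sequence"` for the observed composition of `seq` (the
#'   FIMO-like choice, under which perfect matches in AU-rich sRNAs can reach
#'   small p-values).
#' @return list `matches` (data.frame `start`, `match`), `p_match`, `p_any`,
#'   `n_scanned`.
#' @export
#' @examples
#' yunr_scan("CUGA")$matches  # match at position 1
yunr_scan <- function(seq, background = "uniform") {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  if (identical(background, "uniform")) {
    bg <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  } else if (identical(background, "sequence")) {
    bg <- table(factor(b, levels = c("A", "C", "G", "U"))) / n
    bg <- setNames(as.numeric(bg), c("A", "C", "G", "U"))
  } else {
    stopifnot(is.numeric(background), setequal(names(background), c("A","C","G","U")))
    bg <- background / sum(background)
  }
  p_match <- (bg["C"] + bg["U"]) * bg["U"] * 1 * (bg["A"] + bg["G"])
  m <- max(n - 3L, 0L)
  if (m == 0L) {
    matches <- data.frame(start = integer(0), match = character(0))
  } else {
    hit <- which(b[1:m] %in% c("C", "U") & b[2:(m + 1L)] == "U" &
                   b[4:(m + 3L)] %in% c("A", "G"))
    matches <- data.frame(
      start = hit,
      match = if (length(hit)) substring(seq, hit, hit + 3L) else character(0))
  }
  list(matches = matches, p_match = unname(p_match),
       p_any = 1 - (1 - unname(p_match))^m, n_scanned = m)
}

#' Select likely functional sRNA regions from an accessibility profile
#'
#' A region qualifies when it lies in the 5' or 3' end window (each spanning
#' `window_frac` of the sRNA length) and its reported accessibility is
#' extreme (`> hi` or `< lo`). Up to `max_n` regions are returned, most
#' extreme first (distance from 0.5, ties to the 5'-most). Two fallbacks
#' mirror the published procedure: when the 3' window yields no candidate the
#' 5' search window may be extended to `extended_frac` of the length; and
#' when the windows show mid-accessibility clustering (no candidate at all)
#' the YUNR tie-break selects the 5'-most extreme region of the 5' half that
#' contains a significant YUNR motif (scanned against the sequence
#' composition background).
#'
#' @param profile data.frame with columns `start`, `end`, `accessibility`
#'   and optionally `region` ids.
#' @param L sRNA length in nt.
#' @param seq sRNA sequence, required only for the YUNR tie-break path.
#' @param window_frac,extended_frac end-window sizes as fractions of `L`.
#' @param hi,lo extremeness thresholds (strict).
#' @param max_n maximum regions returned.
#' @param yunr_alpha significance level for the YUNR tie-break.
#' @return data.frame of selected regions with logical rationale flags
#'   `extreme_high`, `extreme_low`, `window_5prime`, `window_3prime`,
#'   `yunr_tiebreak`.
#' @export
select_functional_regions <- function(profile, L, seq = NULL,
                                      window_frac = 0.2, hi = 0.75, lo = 0.25,
                                      max_n = 3L, extended_frac = 0.4,
                                      yunr_alpha = 0.05) {
  stopifnot(all(c("start", "end", "accessibility") %in% names(profile)))
  if (nrow(profile) == 0L) stop("empty accessibility profile")
  acc <- profile$accessibility
  w5 <- ceiling(window_frac * L)
  w3 <- L - ceiling(window_frac * L) + 1L
  in5 <- profile$start <= w5
  in3 <- profile$end >= w3
  extreme <- acc > hi | acc < lo
  cand5 <- in5 & extreme
  cand3 <- in3 & extreme
  if (!any(cand3)) {
    w5x <- ceiling(extended_frac * L)
    in5 <- profile$start <= w5x
    cand5 <- in5 & extreme
  }
  sel <- which(cand5 | cand3)
  yunr <- rep(FALSE, nrow(profile))
  if (length(sel) == 0L) {
    # mid-accessibility clustering: YUNR tie-break over the 5' half
    if (is.null(seq)) {
      warning("no extreme end-window region and no sequence for the YUNR tie-break")
      sel <- integer(0)
    } else {
      half <- which(profile$start <= L / 2)
      pool <- half[extreme[half]]
      if (length(pool) == 0L) pool <- half
      sig <- vapply(pool, function(i) {
        sc <- yunr_scan(substring(normalize_rna(seq), profile$start[i],
                                  profile$end[i]),
                        background = "sequence")
        nrow(sc$matches) > 0L && sc$p_match < yunr_alpha
      }, TRUE)
      pool <- pool[sig]
      if (length(pool)) {
        sel <- pool[which.min(profile$start[pool])]
        yunr[sel] <- TRUE
      }
    }
  }
  if (length(sel) > max_n) {
    ord <- order(-abs(acc[sel] - 0.5), profile$start[sel])
    sel <- sel[ord[seq_len(max_n)]]
  }
  out <- profile[sel, , drop = FALSE]
  out$extreme_high <- acc[sel] > hi
  out$extreme_low <- acc[sel] < lo
  out$window_5prime <- in5[sel]
  out$window_3prime <- in3[sel]
  out$yunr_tiebreak <- yunr[sel]
  out <- out[order(-abs(out$accessibility - 0.5), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter target predictions by overlap with functional regions
#'
#' Keeps predictions whose sRNA interaction interval overlaps any called
#' functional region by at least `min_overlap` nucleotides (inclusive;
#' overlap of exactly 5 is kept under the default).
#'
#' @param preds prediction data.frame with columns `srna_start`, `srna_end`
#'   (1-based closed sRNA interaction interval).
#' @param regions functional regions (columns `start`, `end`).
#' @param min_overlap minimum shared nucleotides.
#' @return logical vector marking the accessibility-informed predictions.
#' @export
informed_filter <- function(preds, regions, min_overlap = 5L) {
  stopifnot(all(c("srna_start", "srna_end") %in% names(preds)))
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(preds)))
  vapply(seq_len(nrow(preds)), function(i) {
    ov <- pmin(preds$srna_end[i], regions$end) -
      pmax(preds$srna_start[i], regions$start) + 1L
    any(ov >= min_overlap)
  }, TRUE)
}

#' Read an IntaRNA-style prediction table
#'
#' CSV (or `sep`-delimited) reader mapping common column aliases onto the
#' canonical schema `mrna`, `rank`, `energy`, `srna_start`, `srna_end`,
#' `mrna_start`, `mrna_end` (mRNA coordinates relative to the start codon,
#' +1 = first codon nucleotide, negative = 5'-UTR). Missing ranks are
#' assigned by increasing predicted energy.
#'
#' @param path file path.
#' @param sep field separator.
#' @return canonical prediction data.frame, ranked.
#' @export
read_prediction_table <- function(path, sep = ",") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  alias <- list(
    mrna = c("mrna", "id1", "target", "target_id", "name"),
    rank = c("rank"),
    energy = c("energy", "e", "dg"),
    srna_start = c("srna_start", "start2", "qstart"),
    srna_end = c("srna_end", "end2", "qend"),
    mrna_start = c("mrna_start", "start1", "tstart"),
    mrna_end = c("mrna_end", "end1", "tend"))
  nl <- tolower(names(df))
  out <- list()
  for (k in names(alias)) {
    j <- which(nl %in% alias[[k]])[1]
    if (!is.na(j)) out[[k]] <- df[[j]]
  }
  need <- c("mrna", "srna_start", "srna_end")
  if (!all(need %in% names(out)))
    stop("prediction table lacks required columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (is.null(out$rank)) {
    if (is.null(out$energy)) stop("need a rank or an energy column")
    out$rank <- rank(out$energy, ties.method = "first")
  }
  if (anyDuplicated(out$rank)) stop("ranks must be unique")
  out[order(out$rank), , drop = FALSE]
}

normalize_category <- function(x) {
  x <- tolower(gsub("[ -]", "_", trimws(x)))
  map <- c(interface = "informed", interface_informed = "informed",
           informed = "informed", top_ranked = "top_ranked", both = "both")
  out <- map[x]
  if (anyNA(out)) stop("unknown category label: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

normalize_binding <- function(x) {
  x <- tolower(trimws(x))
  x[grepl("weak", x)] <- "weak"
  if (!all(x %in% c("yes", "weak", "no")))
    stop("binding labels must be yes / weak / no")
  x
}

#' Categorize predictions and compute positive predictive values
#'
#' Tested candidates fall in exactly one category: `both` when
#' accessibility-informed and within the top `top_n` ranks, `informed` when
#' informed only, `top_ranked` when top-ranked only. The PPV of a category is
#' the fraction of its tested candidates with confirmed binding; weak binding
#' counts as positive.
#'
#' @param preds canonical prediction data.frame (needs `mrna`, `rank`).
#' @param informed logical vector from [informed_filter()].
#' @param outcomes data.frame `mrna`, `binding` (yes / weak / no) for the
#'   tested candidates.
#' @param top_n size of the top-ranked comparison group (default 5).
#' @return list `rows` (benchmark rows: `mrna`, `rank`, `category`,
#'   `binding`) and `ppv` (named vector per category).
#' @export
categorize_and_ppv <- function(preds, informed, outcomes, top_n = 5L) {
  stopifnot(length(informed) == nrow(preds))
  unknown <- setdiff(outcomes$mrna, preds$mrna)
  if (length(unknown))
    stop("outcome for unknown mRNA: ", paste(unknown, collapse = ", "))
  top <- preds$rank <= top_n
  category <- ifelse(informed & top, "both",
                     ifelse(informed, "informed",
                            ifelse(top, "top_ranked", "none")))
  i <- match(outcomes$mrna, preds$mrna)
  rows <- data.frame(mrna = outcomes$mrna, rank = preds$rank[i],
                     category = category[i],
                     binding = normalize_binding(outcomes$binding))
  pos <- rows$binding %in% c("yes", "weak")
  ppv <- vapply(split(pos, rows$category), mean, 0)
  list(rows = rows, ppv = ppv)
}

#' Tally a benchmark validation table
#'
#' Counts confirmed targets (binding yes or weak) overall and per prediction
#' category, and the highest confirmed rank per sRNA — the headline summary
#' of an in vitro validation table.
#'
#' @param rows data.frame with columns `srna`, `mrna`, `rank`, `category`
#'   (informed / top_ranked / both; printed-label aliases accepted) and
#'   `binding` (yes / weak / no).
#' @return list `confirmed`, `informed_only`, `top_only`, `both`,
#'   `max_confirmed_rank` (named per sRNA), `n_tested`.
#' @export
tally_validation <- function(rows) {
  if (nrow(rows) == 0L)
    return(list(confirmed = 0L, informed_only = 0L, top_only = 0L, both = 0L,
                max_confirmed_rank = setNames(integer(0), character(0)),
                n_tested = 0L))
  cat <- normalize_category(rows$category)
  bind <- normalize_binding(rows$binding)
  confirmed <- bind %in% c("yes", "weak")
  mcr <- tapply(rows$rank[confirmed], rows$srna[confirmed], max)
  list(confirmed = sum(confirmed),
       informed_only = sum(confirmed & cat == "informed"),
       top_only = sum(confirmed & cat == "top_ranked"),
       both = sum(confirmed & cat == "both"),
       max_confirmed_rank = setNames(as.integer(mcr), names(mcr)),
       n_tested = nrow(rows))
}

#' Published benchmark table of tested sRNA:mRNA predictions
#'
#' Loads the bundled validation benchmark (three uncharacterized E. coli
#' sRNAs: SroE, SroG, Tpke70; per tested mRNA its prediction rank out of 100,
#' prediction category and in vitro binding outcome).
#'
#' @return data.frame `srna`, `rank`, `mrna`, `category`, `binding`.
#' @export
load_validated_targets <- function() {
  path <- system.file("extdata", "validated_targets.csv", package = "asaccess",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
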