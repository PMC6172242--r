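#' Anti-termination reporter scaffold
#'
#' The reporter transcript for each probe is the concatenation, 5' to 3', of
#' a short leader (TSS onward), the probe-specific antisense segment, the RNA
#' sequestration element (RSE), the ribosome binding site (RBS), the
#' elongation switch (ES: tnaC leader peptide plus rut site, where
#' Rho-dependent termination acts when the probe fails to hybridize) and the
#' RNA elongation reporter (RER) whose read-through marks successful
#' hybridization. Defaults are synthetic, non-repetitive part sequences whose
#' lengths put the three termination landmarks of the transcript-length model
#' at ~80 nt (within the ES), ~140 nt (around the end of the ES) and 200 nt
#' (full-length read-through) for a 12-nt probe.
#'
#' @param leader,rse,rbs,es,rer part sequences (RNA; T accepted).
#' @return an object of class `reporter_scaffold`.
#' @export
reporter_scaffold <- function(
    leader = "GACAGA",
    rse = "UUGACUUGCGGAUUGACAGG",
    rbs = "CCAGGGCUUGAU",
    es = paste0("UCAGGACACCCCACAUAGCAGUAAUCUCUUGAGCGGAGCCGGCCGAUUUAUGACUUCC",
                "UGACGACGACCUGAUACUCAGCGGAGUCC"),
    rer = "CUAUGCAAUCGGGCAAUUCAGCAUGUAUCCUGCGCACGAAACAAGUCGUCACCACCUGCGAUC") {
  parts <- list(leader = normalize_rna(leader), rse = normalize_rna(rse),
                rbs = normalize_rna(rbs), es = normalize_rna(es),
                rer = normalize_rna(rer))
  structure(parts, class = "reporter_scaffold")
}

#' @export
print.reporter_scaffold <- function(x, ...) {
  lens <- vapply(x, nchar, 0L)
  cat("Reporter scaffold parts (nt):",
      paste(names(lens), lens, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Build the per-probe reference library
#'
#' One reference transcript per probe: leader + antisense probe + RSE + RBS +
#' ES + RER, with the transcription start site at position 1. The probe
#' segment must occur exactly once in its own reference (it is the 5'
#' identity barcode of the transcript).
#'
#' @param probes data.frame with columns `probe_id` and `probe_seq` (optional
#'   `taRNA_id`, `start`, `end` are carried through).
#' @param scaffold a [reporter_scaffold()].
#' @return data.frame with one row per probe: `probe_id`, `probe_seq`,
#'   `ref_seq`, `probe_start`, `probe_end` (probe interval on the reference,
#'   1-based closed), `tss`, `ref_length`, plus any carried columns.
#' @export
build_reference_library <- function(probes, scaffold = reporter_scaffold()) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "probe_seq") %in% names(probes)))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  probe_seq <- normalize_rna(probes$probe_seq)
  refs <- probes
  refs$probe_seq <- probe_seq
  refs$ref_seq <- paste0(scaffold$leader, probe_seq, scaffold$rse,
                         scaffold$rbs, scaffold$es, scaffold$rer)
  refs$probe_start <- nchar(scaffold$leader) + 1L
  refs$probe_end <- refs$probe_start + nchar(probe_seq) - 1L
  refs$tss <- 1L
  refs$ref_length <- nchar(refs$ref_seq)
  hits <- vapply(seq_len(nrow(refs)), function(i)
    length(gregexpr(refs$probe_seq[i], refs$ref_seq[i], fixed = TRUE)[[1]]), 0L)
  if (any(hits != 1L))
    stop("probe sequence not unique within its reference: ",
         paste(refs$probe_id[hits != 1L], collapse = ", "))
  rownames(refs) <- NULL
  refs
}

# find the single reference whose prefix equals r1 (TSS-anchored exact match).
# Returns per-unique-R1: reference row index (NA if none), number of matches.
match_r1_prefix <- function(ur1, refs) {
  nmatch <- integer(length(ur1))
  ridx <- rep(NA_integer_, length(ur1))
  len <- nchar(ur1)
  for (i in seq_len(nrow(refs))) {
    hit <- len <= refs$ref_length[i] & substring(refs$ref_seq[i], 1L, len) == ur1
    nmatch <- nmatch + hit
    ridx[hit] <- i
  }
  ridx[nmatch != 1L] <- NA_integer_
  list(ref = ridx, nmatch = nmatch)
}

#' Assign paired reads to probes and transcript end positions
#'
#' Built-in exact matcher replacing an external aligner for error-free reads:
#' the 5' read (R1) is assigned to a reference if and only if it matches the
#' TSS-anchored reference prefix exactly and its footprint overlaps the
#' antisense probe segment by at least `min_probe_overlap` nucleotides
#' (default 7, inclusive); an R1 whose prefix matches more than one reference
#' is discarded as multi-mapped. The mate (R2) is then exact-matched within
#' the same reference (its reverse complement must occur exactly once) to fix
#' the transcript end position.
#'
#' @param pairs data.frame with columns `read_id`, `r1`, `r2`.
#' @param refs reference library from [build_reference_library()].
#' @param min_probe_overlap minimum R1/probe-segment overlap in nt.
#' @return list with `assignments` (data.frame `read_id`, `probe_id`, `end`)
#'   and `log` (named counts: total, assigned, unmatched_r1, multimapped,
#'   short_probe_overlap, unmatched_r2, ambiguous_r2). The counts partition
#'   the input reads.
#' @export
process_read_pairs <- function(pairs, refs, min_probe_overlap = 7L) {
  stopifnot(is.data.frame(pairs),
            all(c("read_id", "r1", "r2") %in% names(pairs)))
  n <- nrow(pairs)
  log <- c(total = n, assigned = 0L, unmatched_r1 = 0L, multimapped = 0L,
           short_probe_overlap = 0L, unmatched_r2 = 0L, ambiguous_r2 = 0L)
  if (n == 0L)
    return(list(assignments = data.frame(read_id = character(0),
                                         probe_id = character(0),
                                         end = integer(0)),
                log = as.list(log)))
  r1 <- normalize_rna(pairs$r1)
  r2 <- normalize_rna(pairs$r2)

  # R1: dedupe before matching (simulated libraries have few distinct reads)
  ur1 <- unique(r1)
  m <- match_r1_prefix(ur1, refs)
  u_status <- ifelse(m$nmatch == 0L, "unmatched_r1",
                     ifelse(m$nmatch > 1L, "multimapped", "ok"))
  ok <- u_status == "ok"
  ov <- rep(NA_integer_, length(ur1))
  ov[ok] <- pmin(nchar(ur1[ok]), refs$probe_end[m$ref[ok]]) -
    refs$probe_start[m$ref[ok]] + 1L
  u_status[ok & ov < min_probe_overlap] <- "short_probe_overlap"

  idx <- match(r1, ur1)
  status <- u_status[idx]
  refrow <- ifelse(status == "ok", m$ref[idx], NA_integer_)

  # R2: dedupe on (reference, sequence); reverse complement must occur once
  end <- rep(NA_integer_, n)
  live <- which(status == "ok")
  if (length(live)) {
    key <- paste(refrow[live], r2[live])
    ukey <- !duplicated(key)
    ukref <- refrow[live][ukey]
    ukr2 <- r2[live][ukey]
    uend <- rep(NA_integer_, length(ukr2))
    ustat <- character(length(ukr2))
    rc <- reverse_complement(ukr2)
    for (i in seq_along(ukr2)) {
      hit <- gregexpr(rc[i], refs$ref_seq[ukref[i]], fixed = TRUE)[[1]]
      if (hit[1] == -1L) ustat[i] <- "unmatched_r2"
      else if (length(hit) > 1L) ustat[i] <- "ambiguous_r2"
      else { ustat[i] <- "ok"; uend[i] <- hit[1] + nchar(rc[i]) - 1L }
    }
    k <- match(key, key[ukey])
    status[live] <- ustat[k]
    end[live] <- uend[k]
  }

  for (s in c("unmatched_r1", "multimapped", "short_probe_overlap",
              "unmatched_r2", "ambiguous_r2"))
    log[s] <- sum(status == s)
  keep <- status == "ok"
  log["assigned"] <- sum(keep)
  list(assignments = data.frame(read_id = pairs$read_id[keep],
                                probe_id = refs$probe_id[refrow[keep]],
                                end = end[keep]),
       log = as.list(log))
}

#' Transcript-length histograms per probe
#'
#' Transcript length is the number of nucleotides between the observed TSS
#' and the transcription end site, `end - tss + 1`. Reads ending upstream of
#' the TSS are dropped and counted.
#'
#' @param assignments result of [process_read_pairs()] or [load_mapped_bed()]
#'   (the list, or its `assignments` data.frame).
#' @param refs reference library from [build_reference_library()].
#' @return data.frame `probe_id`, `length`, `count`, with attribute
#'   `dropped` (reads ending before the TSS).
#' @export
length_histograms <- function(assignments, refs) {
  if (is.list(assignments) && !is.data.frame(assignments))
    assignments <- assignments$assignments
  if (nrow(assignments) == 0L)
    return(structure(data.frame(probe_id = character(0), length = integer(0),
                                count = integer(0)), dropped = 0L))
  ridx <- match(assignments$probe_id, refs$probe_id)
  if (anyNA(ridx)) stop("assignment to unknown probe id")
  len <- assignments$end - refs$tss[ridx] + 1L
  bad <- len < 1L
  agg <- stats::aggregate(
    list(count = rep(1L, sum(!bad))),
    by = list(probe_id = assignments$probe_id[!bad], length = len[!bad]),
    FUN = sum)
  agg <- agg[order(agg$probe_id, agg$length), c("probe_id", "length", "count")]
  rownames(agg) <- NULL
  structure(agg, dropped = sum(bad))
}

#' Read a paired FASTQ run into a read-pair table
#'
#' Mates are joined on the read identifier (anything before the first
#' whitespace, with a trailing `/1` or `/2` stripped). Orphan reads are
#' dropped and counted in the `orphans` attribute.
#'
#' @param r1_path,r2_path FASTQ files for the 5' and 3' mates.
#' @return data.frame `read_id`, `r1`, `r2` suitable for
#'   [process_read_pairs()].
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  clean <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  s1 <- Biostrings::readBStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readBStringSet(r2_path, format = "fastq")
  id1 <- clean(names(s1)); id2 <- clean(names(s2))
  common <- intersect(id1, id2)
  pairs <- data.frame(read_id = common,
                      r1 = as.character(s1)[match(common, id1)],
                      r2 = as.character(s2)[match(common, id2)])
  structure(pairs, orphans = (length(s1) - length(common)) +
              (length(s2) - length(common)))
}

#' Load externally mapped reads from a BED file
#'
#' Entry point for reads mapped by an external aligner and exported as BED6
#' (0-based half-open intervals; the name field carries the read id; `+`
#' strand rows are 5' mates, `-` strand rows are 3' mates; the chromosome
#' field is the probe/reference id). The same filtering contract as
#' [process_read_pairs()] is applied on interval coordinates: probe-segment
#' overlap of the 5'-mate footprint >= `min_probe_overlap`, 5' mates mapping
#' to more than one reference discarded as multi-mapped, and both mates
#' required on the same reference.
#'
#' @param path BED6 file.
#' @param refs reference library from [build_reference_library()].
#' @param pairing optional data.frame `r1_id`, `r2_id` mapping mate ids when
#'   the two mates do not share one id.
#' @param min_probe_overlap minimum overlap in nt.
#' @return same structure as [process_read_pairs()].
#' @export
load_mapped_bed <- function(path, refs, pairing = NULL, min_probe_overlap = 7L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 6L |
                 vapply(fields, function(f)
                   length(f) >= 3L && (is.na(suppressWarnings(as.integer(f[2]))) ||
                                         is.na(suppressWarnings(as.integer(f[3])))), TRUE))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": ", lines[bad[1]])
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(ref = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),  # 1-based closed
                   end = GenomicRanges::end(gr),
                   read_id = gr$name,
                   strand = as.character(GenomicRanges::strand(gr)))
  n_total <- length(unique(sub("/[12]$", "", df$read_id)))
  log <- c(total = n_total, assigned = 0L, unmatched_r1 = 0L,
           multimapped = 0L, short_probe_overlap = 0L, unmatched_r2 = 0L,
           ambiguous_r2 = 0L, unknown_reference = 0L)
  df$read_id <- sub("/[12]$", "", df$read_id)
  if (!is.null(pairing))
    df$read_id[df$strand == "-"] <-
      pairing$r1_id[match(df$read_id[df$strand == "-"], pairing$r2_id)]
  known <- df$ref %in% refs$probe_id
  log["unknown_reference"] <- length(unique(df$read_id[!known]))
  df <- df[known, , drop = FALSE]
  r1 <- df[df$strand == "+", , drop = FALSE]
  r2 <- df[df$strand == "-", , drop = FALSE]
  # multi-mapped: a 5' mate reported on more than one reference
  multi <- unique(r1$read_id[duplicated(r1$read_id)])
  log["multimapped"] <- length(multi)
  r1 <- r1[!r1$read_id %in% multi, , drop = FALSE]
  ridx <- match(r1$ref, refs$probe_id)
  ov <- pmin(r1$end, refs$probe_end[ridx]) -
    pmax(r1$start, refs$probe_start[ridx]) + 1L
  short <- ov < min_probe_overlap
  log["short_probe_overlap"] <- sum(short)
  r1 <- r1[!short, , drop = FALSE]
  key <- paste(r2$read_id, r2$ref)
  j <- match(paste(r1$read_id, r1$ref), key)
  log["unmatched_r2"] <- sum(is.na(j))
  keep <- !is.na(j)
  assignments <- data.frame(read_id = r1$read_id[keep],
                            probe_id = r1$ref[keep],
                            end = r2$end[j[keep]])
  log["assigned"] <- nrow(assignments)
  log["unmatched_r1"] <- n_total - log["assigned"] - log["multimapped"] -
    log["short_probe_overlap"] - log["unmatched_r2"] - log["unknown_reference"]
  list(assignments = assignments, log = as.list(log))
}

#' Write / read a probe table (TSV)
#'
#' Plain-TSV interchange format for probe panels: columns `probe_id`,
#' `taRNA_id`, `start`, `end`, `probe_seq` and optionally `nu`, `v`.
#'
#' @param probes probe data.frame (e.g. the `panel` of [design_probes()]).
#' @param path file path.
#' @return `path` invisibly / the probe data.frame.
#' @export
write_probe_table <- function(probes, path) {
  cols <- intersect(c("probe_id", "taRNA_id", "start", "end", "probe_seq",
                      "nu", "v"), names(probes))
  write.table(probes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "probe_seq") %in% names(df)))
  df
}
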