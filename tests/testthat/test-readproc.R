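test_that("reference library concatenates scaffold parts around each probe", {
  sc <- reporter_scaffold()
  probes <- data.frame(probe_id = c("a", "b"),
                       probe_seq = c("ACGUACGUACGU", "GGAUCCAUGGAU"))
  refs <- build_reference_library(probes, sc)
  part_len <- sum(vapply(sc, nchar, 0L))
  expect_equal(refs$ref_length, rep(part_len + 12L, 2))
  # references differ only in the probe segment
  expect_equal(substr(refs$ref_seq[1], 1, 6), substr(refs$ref_seq[2], 1, 6))
  expect_equal(substring(refs$ref_seq[1], 19), substring(refs$ref_seq[2], 19))
  expect_equal(substring(refs$ref_seq[1], refs$probe_start[1], refs$probe_end[1]),
               "ACGUACGUACGU")

  expect_error(build_reference_library(
    data.frame(probe_id = c("a", "a"), probe_seq = c("ACGUACGUACGU", "ACGUACGUACGU"))),
    "duplicate")
  # probe equal to a scaffold substring occurs twice in its reference
  expect_error(build_reference_library(
    data.frame(probe_id = "bad", probe_seq = substr(sc$es, 1, 12)), sc),
    "not unique")
})

test_that("the 7-nt probe-overlap rule is applied inclusively", {
  refs <- build_reference_library(
    data.frame(probe_id = c("a", "b"),
               probe_seq = c("ACGUACGUACGU", "GGAUCCAUGGAU")))
  ref <- refs$ref_seq[1]
  end <- 150L
  r2 <- reverse_complement(substring(ref, end - 40L, end))
  # probe segment starts at 7; R1 of length 13 covers exactly 7 probe nt
  keep <- process_read_pairs(
    data.frame(read_id = "r", r1 = substr(ref, 1, 13), r2 = r2), refs)
  expect_equal(keep$log$assigned, 1)
  expect_equal(keep$assignments$end, end)
  expect_equal(keep$assignments$probe_id, "a")
  # one nucleotide less: 6-nt overlap, discarded
  drop <- process_read_pairs(
    data.frame(read_id = "r", r1 = substr(ref, 1, 12), r2 = r2), refs)
  expect_equal(drop$log$assigned, 0)
  expect_equal(drop$log$short_probe_overlap, 1)
})

test_that("scaffold-only reads are discarded as multi-mapped", {
  refs <- build_reference_library(
    data.frame(probe_id = c("a", "b"),
               probe_seq = c("ACGUACGUACGU", "GGAUCCAUGGAU")))
  r2 <- reverse_complement(substring(refs$ref_seq[1], 120, 160))
  res <- process_read_pairs(
    data.frame(read_id = "r", r1 = substr(refs$ref_seq[1], 1, 5), r2 = r2),
    refs)
  expect_equal(res$log$multimapped, 1)
  expect_equal(res$log$assigned, 0)
})

test_that("read accounting conserves every input pair", {
  set.seed(8)
  refs <- build_reference_library(random_probe_table(4))
  truth <- simulate_true_accessibilities(4, seed = 12)
  h <- simulate_histograms(truth, sim_config(), refs$probe_id, reads = 100)
  pairs <- simulate_read_pairs(h, refs)
  # corrupt some reads: unmatched R1, foreign R2
  pairs$r1[1:3] <- strrep("G", 40)
  pairs$r2[4:5] <- strrep("C", 40)
  res <- process_read_pairs(pairs, refs)
  lg <- res$log
  expect_equal(lg$total, nrow(pairs))
  expect_equal(lg$assigned + lg$unmatched_r1 + lg$multimapped +
                 lg$short_probe_overlap + lg$unmatched_r2 + lg$ambiguous_r2,
               lg$total)
  expect_equal(lg$unmatched_r1, 3)
  expect_equal(lg$unmatched_r2, 2)
})

test_that("length histograms aggregate end positions relative to the TSS", {
  refs <- build_reference_library(random_probe_table(1))
  a <- data.frame(read_id = c("r1", "r2", "r3"), probe_id = "p01",
                  end = c(200L, 100L, 200L))
  h <- length_histograms(a, refs)
  expect_equal(h$length, c(100, 200))
  expect_equal(h$count, c(1, 2))

  empty <- length_histograms(
    data.frame(read_id = character(0), probe_id = character(0),
               end = integer(0)), refs)
  expect_equal(nrow(empty), 0)
})

test_that("simulated FASTQ round-trips through the matcher exactly", {
  set.seed(5)
  refs <- build_reference_library(random_probe_table(5))
  truth <- simulate_true_accessibilities(5, seed = 3)
  h0 <- simulate_histograms(truth, sim_config(), refs$probe_id, reads = 150)
  pairs <- simulate_read_pairs(h0, refs)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  emit_paired_fastq(pairs, r1, r2)
  back <- read_paired_fastq(r1, r2)
  expect_equal(attr(back, "orphans"), 0)
  h1 <- length_histograms(process_read_pairs(back, refs), refs)
  h0 <- h0[order(h0$probe_id, h0$length), ]
  rownames(h0) <- NULL
  expect_equal(h1[, c("probe_id", "length", "count")], h0)
})

test_that("externally mapped BED input follows the same filtering contract", {
  refs <- build_reference_library(
    data.frame(probe_id = c("a", "b"),
               probe_seq = c("ACGUACGUACGU", "GGAUCCAUGGAU")))
  bed <- tempfile(fileext = ".bed")
  # probe segment occupies 1-based [7, 18]; BED is 0-based half-open.
  writeLines(c(
    "a\t0\t13\tr1\t60\t+",    # covers 7 probe nt -> keep
    "a\t140\t190\tr1\t60\t-", # mate fixes end = 190
    "a\t0\t12\tr2\t60\t+",    # 6-nt overlap -> short
    "a\t150\t180\tr2\t60\t-",
    "a\t0\t30\tr3\t60\t+",    # 5' mate on two references -> multi-mapped
    "b\t0\t30\tr3\t60\t+",
    "a\t100\t150\tr3\t60\t-",
    "chrX\t0\t30\tr4\t60\t+"  # unknown reference -> dropped
  ), bed)
  res <- load_mapped_bed(bed, refs)
  expect_equal(res$assignments$read_id, "r1")
  expect_equal(res$assignments$end, 190)
  expect_equal(res$log$short_probe_overlap, 1)
  expect_equal(res$log$multimapped, 1)
  expect_equal(res$log$unknown_reference, 1)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("a\t0\t13\tr1\t60\t+", "a\tnot_a_number\t10"), bad)
  expect_error(load_mapped_bed(bad, refs), "line 2")
})

test_that("probe tables survive a TSV round trip", {
  probes <- random_probe_table(3)
  probes$taRNA_id <- "s1"; probes$start <- c(1, 10, 19); probes$end <- c(12, 21, 30)
  path <- tempfile(fileext = ".tsv")
  write_probe_table(probes, path)
  back <- read_probe_table(path)
  expect_equal(back$probe_id, probes$probe_id)
  expect_equal(back$probe_seq, probes$probe_seq)
  expect_equal(back$start, probes$start)
})
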