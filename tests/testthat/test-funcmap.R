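test_that("YUNR scan matches the exhaustive 4-mer enumeration", {
  expect_equal(yunr_scan("CUGA")$matches$start, 1)
  expect_equal(nrow(yunr_scan("AAAA")$matches), 0)
  expect_equal(nrow(yunr_scan("AUU")$matches), 0)  # too short to scan

  # oracle: enumerate all 256 4-mers and count motif matches
  bases <- c("A", "C", "G", "U")
  mers <- expand.grid(bases, bases, bases, bases, stringsAsFactors = FALSE)
  hits <- sum(apply(mers, 1, function(b)
    b[1] %in% c("C", "U") && b[2] == "U" && b[4] %in% c("A", "G")))
  expect_equal(hits, 16)
  expect_equal(yunr_scan("ACGUACGU")$p_match, hits / 256)
  sc <- yunr_scan("ACGUACGU")
  expect_equal(sc$p_any, 1 - (1 - 1 / 16)^sc$n_scanned)

  # sequence-composition background changes the match p-value
  pyrich <- yunr_scan(paste0("CUGA", strrep("AG", 18)), background = "sequence")
  expect_lt(pyrich$p_match, 1 / 16)
})

test_that("functional region selection applies window and extremeness rules", {
  prof <- data.frame(region = paste0("r", 1:5),
                     start = c(10, 30, 48, 60, 90),
                     end = c(18, 38, 56, 68, 98),
                     accessibility = c(0.9, 0.6, 0.95, 0.5, 0.1))
  sel <- select_functional_regions(prof, L = 100)
  # r1: 5' window + extreme high; r5: 3' window + extreme low;
  # r3 is extreme but mid-transcript, r2/r4 are mid-accessibility
  expect_setequal(sel$region, c("r1", "r5"))
  r1 <- sel[sel$region == "r1", ]
  expect_true(r1$extreme_high && r1$window_5prime && !r1$window_3prime)
  r5 <- sel[sel$region == "r5", ]
  expect_true(r5$extreme_low && r5$window_3prime)

  # at most max_n regions, most extreme first
  prof2 <- data.frame(start = c(1, 5, 10, 15, 92),
                      end = c(9, 13, 18, 23, 100),
                      accessibility = c(0.99, 0.95, 0.05, 0.9, 0.97))
  sel2 <- select_functional_regions(prof2, L = 100, max_n = 3)
  expect_equal(nrow(sel2), 3)
  expect_equal(sel2$accessibility, c(0.99, 0.97, 0.05))

  expect_error(select_functional_regions(prof[0, ], L = 100), "empty")
})

test_that("the 5' window extends when the 3' window has no candidate", {
  prof <- data.frame(start = c(30, 60), end = c(38, 68),
                     accessibility = c(0.9, 0.5))
  # start 30 is outside the 20-nt 5' window of L = 100 but inside the
  # extended 40-nt window; no 3' candidate exists
  sel <- select_functional_regions(prof, L = 100)
  expect_equal(sel$start, 30)
})

test_that("mid-accessibility clustering falls back to the YUNR tie-break", {
  seq <- paste0("AAGA", "CUGA", strrep("AG", 16))  # 40 nt, C/U rare
  prof <- data.frame(start = c(1, 11, 25), end = c(10, 20, 34),
                     accessibility = c(0.6, 0.4, 0.5))
  sel <- select_functional_regions(prof, L = 40, seq = seq)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$start, 1)  # 5'-most region holding a significant motif
  expect_true(sel$yunr_tiebreak)

  # without a sequence the tie-break cannot run
  expect_warning(none <- select_functional_regions(prof, L = 40), "YUNR")
  expect_equal(nrow(none), 0)
})

test_that("prediction filtering requires five shared nucleotides", {
  regions <- data.frame(start = 16, end = 30)
  preds <- data.frame(srna_start = c(10, 10, 18), srna_end = c(20, 20, 25))
  regions4 <- data.frame(start = 17, end = 30)
  expect_true(informed_filter(preds[1, ], regions))        # overlap 5
  expect_false(informed_filter(preds[1, ], regions4))      # overlap 4
  expect_true(informed_filter(preds[3, ], regions))        # contained

  # enlarging a region never drops a kept prediction
  set.seed(13)
  for (r in 1:20) {
    preds <- data.frame(srna_start = sample(1:50, 8, TRUE))
    preds$srna_end <- preds$srna_start + sample(5:15, 8, TRUE)
    reg <- data.frame(start = 20, end = 35)
    big <- data.frame(start = 18, end = 38)
    kept <- informed_filter(preds, reg)
    expect_true(all(informed_filter(preds, big)[kept]))
  }
})

test_that("categorization partitions tested candidates and yields PPVs", {
  preds <- data.frame(mrna = paste0("g", 1:50), rank = 1:50,
                      srna_start = 1, srna_end = 9)
  informed <- rep(FALSE, 50)
  informed[c(4, 46)] <- TRUE
  outcomes <- data.frame(mrna = c("g4", "g46", "g1", "g2", "g3"),
                         binding = c("yes", "Yes (weak)", "no", "no", "no"))
  res <- categorize_and_ppv(preds, informed, outcomes, top_n = 5)
  expect_equal(res$rows$category[res$rows$mrna == "g4"], "both")
  expect_equal(res$rows$category[res$rows$mrna == "g46"], "informed")
  expect_equal(res$rows$category[res$rows$mrna == "g1"], "top_ranked")
  expect_equal(unname(res$ppv["informed"]), 1)   # weak counts positive
  expect_equal(unname(res$ppv["top_ranked"]), 0)
  # every tested row gets exactly one category
  expect_true(all(res$rows$category %in% c("both", "informed", "top_ranked")))
  expect_error(categorize_and_ppv(preds, informed,
                                  data.frame(mrna = "nope", binding = "yes")),
               "unknown mRNA")
})

test_that("the bundled validation benchmark tallies correctly", {
  rows <- load_validated_targets()
  tl <- tally_validation(rows)
  expect_equal(tl$confirmed, 13)
  expect_equal(tl$informed_only, 6)
  expect_equal(tl$top_only, 1)
  expect_equal(tl$both, 6)
  expect_equal(unname(tl$max_confirmed_rank["SroG"]), 76)
  expect_equal(unname(tl$max_confirmed_rank["SroE"]), 46)
  expect_equal(unname(tl$max_confirmed_rank["Tpke70"]), 29)

  # order invariance and printed-label aliases
  set.seed(2)
  shuf <- rows[sample(nrow(rows)), ]
  shuf$category <- sub("^top_ranked$", "Top-ranked", shuf$category)
  shuf$category <- sub("^both$", "Both", shuf$category)
  shuf$binding <- sub("^weak$", "Yes (weak)", shuf$binding)
  expect_equal(tally_validation(shuf)[1:4], tl[1:4])

  empty <- tally_validation(rows[0, ])
  expect_equal(empty$confirmed, 0)
  expect_equal(empty$n_tested, 0)
})

test_that("prediction tables are parsed through header aliases", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id1,E,start2,end2,start1,end1",
               "lacZ,-12.1,3,11,-20,-12",
               "araC,-10.5,14,22,5,13"), path)
  pred <- read_prediction_table(path)
  expect_equal(pred$mrna, c("lacZ", "araC"))
  expect_equal(pred$rank, c(1, 2))  # ranked by energy
  expect_equal(pred$srna_start, c(3, 14))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id1,E", "lacZ,-12.1"), bad)
  expect_error(read_prediction_table(bad), "required")
})
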