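test_that("repeat-number thresholds gate detection per class", {
  expect_length(scanSSRs(c(a = strrep("A", 12))), 1L)
  expect_length(scanSSRs(c(a = strrep("A", 11))), 0L)
  expect_length(scanSSRs(c(a = strrep("AG", 8))), 1L)
  expect_length(scanSSRs(c(a = strrep("AG", 7))), 0L)
  expect_length(scanSSRs(c(a = strrep("ACGTAG", 5))), 1L)
  gr <- scanSSRs(c(a = strrep("A", 12)))
  expect_equal(start(gr), 1L)
  expect_equal(end(gr), 12L)
  expect_equal(mcols(gr)$nRepeats, 12L)
})

test_that("a planted dinucleotide tract is reported at minimal period", {
  gr <- scanSSRs(c(toy = paste0("GG", strrep("AT", 8), "C")))
  expect_length(gr, 1L)
  expect_equal(start(gr), 3L)
  expect_equal(end(gr), 18L)
  expect_identical(mcols(gr)$motif, "AT")
  expect_identical(mcols(gr)$canonicalMotif, "AT")
  expect_equal(mcols(gr)$motifLength, 2L)
  expect_equal(mcols(gr)$nRepeats, 8L)   # never (ATAT)4
})

test_that("a trailing partial unit terminates the tract", {
  # (AGC)5 plus a dangling "AG"
  gr <- scanSSRs(c(a = paste0("TT", strrep("AGC", 5), "AG", "TT")))
  expect_equal(mcols(gr)$nRepeats, 5L)
  expect_equal(end(gr) - start(gr) + 1L,
               mcols(gr)$motifLength * mcols(gr)$nRepeats)
})

test_that("N bases break repeat tracts and empty input gives empty output", {
  expect_length(scanSSRs(c(a = paste0(strrep("A", 6), "N",
                                      strrep("A", 6)))), 0L)
  expect_length(scanSSRs(c(a = "")), 0L)
  expect_length(scanSSRs(c(a = "ACGT")), 0L)
  expect_error(scanSSRs(c(a = "ACGX")), "alphabet")
})

test_that("scanner equals the brute-force oracle on random and planted DNA", {
  set.seed(421)
  for (rep in 1:12) {
    n <- 4000L
    s <- random_dna(n)
    # splice in a few tandem arrays with arbitrary (messy) junctions
    for (j in 1:6) {
      k <- sample(1:6, 1)
      motif <- random_dna(k)
      units <- sample(5:15, 1)
      tract <- strrep(motif, units)
      at <- sample(seq_len(n - nchar(tract)), 1)
      substr(s, at, at + nchar(tract) - 1L) <- tract
    }
    expect_identical(scan_frame(scanSSRs(c(x = s), flagCompounds = FALSE)),
                     oracle_scan(s))
  }
})

test_that("reported tracts are maximal and motifs primitive", {
  set.seed(99)
  s <- random_dna(3000)
  for (j in 1:8) {
    tract <- strrep(random_dna(sample(1:3, 1)), 14)
    at <- sample(seq_len(3000 - nchar(tract)), 1)
    substr(s, at, at + nchar(tract) - 1L) <- tract
  }
  gr <- scanSSRs(c(x = s), flagCompounds = FALSE)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_along(gr)) {
    a <- start(gr)[i]; k <- mcols(gr)$motifLength[i]
    b <- a + k * mcols(gr)$nRepeats[i] - 1L
    motif <- mcols(gr)$motif[i]
    # the tract really is the motif repeated
    expect_identical(substr(s, a, b), strrep(motif, mcols(gr)$nRepeats[i]))
    # left extension breaks periodicity
    if (a > 1L) expect_false(ch[a - 1L] %in% BASES &&
                               ch[a - 1L] == ch[a - 1L + k])
    # primitive motif
    if (k > 1L) {
      expect_true(all(vapply(seq_len(k - 1L), function(p) {
        k %% p != 0L ||
          !identical(strrep(substr(motif, 1L, p), k %/% p), motif)
      }, logical(1))))
    }
  }
})

test_that("compound flagging is symmetric and transitive along chains", {
  two <- scanSSRs(c(s = paste0(strrep("AT", 8), strrep("AG", 8))))
  expect_true(all(mcols(two)$compound))
  spaced <- scanSSRs(c(s = paste0(strrep("AT", 8), strrep("C", 2),
                                  random_dna(48, seed = 5),
                                  strrep("AG", 8))))
  spaced <- spaced[mcols(spaced)$motifLength == 2L]
  expect_false(any(mcols(spaced)$compound))
  three <- scanSSRs(c(s = paste0(strrep("AT", 8), strrep("AG", 8),
                                 strrep("ACT", 6))))
  expect_length(three, 3L)
  expect_true(all(mcols(three)$compound))
  # a wider allowed gap links tracts across a short spacer
  gapped <- scanSSRs(c(s = paste0(strrep("AT", 8), "CCG",
                                  strrep("AG", 8))), compoundGap = 5L)
  expect_true(all(mcols(gapped)$compound))
})

test_that("class summaries conserve totals and handle edge cases", {
  gr <- scanSSRs(c(a = paste0(strrep("A", 13), "CCGG", strrep("AG", 9),
                              "TTCC", strrep("AAC", 7))))
  sm <- summarizeClasses(gr)
  expect_equal(sm$total, length(gr))
  expect_equal(sum(sm$classes$count), length(gr))
  expect_equal(sum(sm$motifs$count), length(gr))
  expect_equal(sum(sm$byRepeatCount$count), length(gr))
  one <- summarizeClasses(scanSSRs(c(a = strrep("A", 20))))
  expect_equal(one$classes$percent[one$classes$class == "mono"], 100)
  empty <- summarizeClasses(scanSSRs(c(a = "ACGT")))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$classes$count == 0L))
  expect_true(all(empty$classes$percent == 0))
})

test_that("SSR tables round-trip through TSV", {
  gr <- scanSSRs(c(sc1 = paste0("GG", strrep("AT", 8), strrep("C", 14))))
  path <- tempfile(fileext = ".tsv")
  writeSSRTable(gr, path)
  back <- readSSRTable(path)
  expect_identical(scan_frame(back), scan_frame(gr))
  expect_identical(mcols(back)$compound, mcols(gr)$compound)
})
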