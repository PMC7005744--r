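test_that("GA-rich scanning finds the canonical element and rejects non-purine runs", {
  h <- scan_ga_rich("CCGAAGGAGACC")
  expect_equal(nrow(h), 1L)
  expect_equal(h$matched, "GAAGGAGA")
  expect_equal(h$width, 8L)
  expect_equal(h$offset, 2L)
  expect_equal(nrow(scan_ga_rich("CCCCCCTTTT")), 0L)
  # homopolymers fail the composition rule
  expect_equal(nrow(scan_ga_rich("AAAAAAAAAA")), 0L)
  expect_equal(nrow(scan_ga_rich("GGGGGGGGGG")), 0L)
  # a single A among G's is still not GA-rich (needs two of each)
  expect_equal(nrow(scan_ga_rich("GGGAGGGGG")), 0L)
})

test_that("hits tile greedily from the left without overlap", {
  h <- scan_ga_rich("GAGAGAGAGAGA")
  expect_equal(h$offset, 0L)
  expect_equal(h$width, 9L)  # widest window first, remainder too short
  # widest window first, then resume past it: GAAGGAGAA (9), gap, GAAGGA (6)
  h2 <- scan_ga_rich(paste0("GAAGGA", "GAAGGA", "TT", "GAAGGA"))
  expect_equal(h2$offset, c(0L, 14L))
  expect_equal(h2$width, c(9L, 6L))
  # no two hits overlap
  expect_true(all(diff(h2$offset) >= h2$width[-nrow(h2)]))
})

test_that("every hit indexes a substring equal to its match", {
  set.seed(9)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.35, 0.15, 0.35, 0.15)), collapse = "")
    h <- scan_ga_rich(s)
    if (nrow(h)) {
      expect_identical(substring(s, h$offset + 1, h$offset + h$width),
                       h$matched)
      expect_true(all(h$offset + h$width <= nchar(s)))
      expect_true(all(h$width >= 6 & h$width <= 9))
    }
  }
})

test_that("scanning is strand-consistent under double reverse complement", {
  s <- "CCGAAGGAGACCTTGAGAGAGG"
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  expect_identical(scan_ga_rich(s), scan_ga_rich(rc2))
})

test_that("hit regions are assigned by offset relative to the exon window", {
  # 10 nt flanks around a 10 nt exon; plant motifs in each region
  s <- paste0("GAAGGATTTT", "CCGAAGGACC", "TTTTGAAGGA")
  h <- scan_ga_rich(s, exon_offset = 10L, exon_length = 10L)
  expect_equal(h$region, c("upstream_flank", "exon", "downstream_flank"))
})

motif_fixture <- function() {
  # two genes, one + and one -, exon at known coordinates
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 500), collapse = ""),
    chr2 = paste(rep("TGCA", 500), collapse = "")))
  ev <- rbind(
    toy_cassette_event("CE:chr1:+:600-700:500-800", chrom = "chr1",
                       core = c(600, 700)),
    toy_cassette_event("CE:chr2:-:600-700:500-800", chrom = "chr2",
                       core = c(600, 700)),
    toy_cassette_event("CE:chr1:+:1200-1300:1100-1400", chrom = "chr1",
                       core = c(1200, 1300)),
    toy_cassette_event("CE:chr1:+:1500-1600:1400-1700", chrom = "chr1",
                       core = c(1500, 1600)))
  ev$strand[2] <- "-"
  list(genome = genome, events = ev)
}

test_that("motif sets extract flanked sense-strand sequences and filter controls", {
  fx <- motif_fixture()
  mk_oe <- function(deltas) {
    df <- data.frame(event_id = fx$events$event_id,
                     event_type = "cassette_exon", contrast_id = "oe",
                     inclusion_t = 50, skipping_t = 50, inclusion_c = 50,
                     skipping_c = 50, si_treatment = 0.5, si_control = 0.5,
                     delta_si = deltas, total_junction_reads = 100,
                     p_value = 0.5, fdr = 0.5, tested = TRUE,
                     passes_filters = FALSE, stringsAsFactors = FALSE)
    class(df) <- c("contrast_result", "data.frame")
    df
  }
  # event 3 responds to overexpression (|dSI| = 0.12): excluded from controls
  oe <- mk_oe(c(0.3, -0.3, 0.12, 0.01))
  # the single eligible control cannot size-match two positives: warned
  expect_warning(
    seqs <- build_motif_sets(fx$events$event_id[1:2], fx$events, oe,
                             fx$genome, flank = 250L, seed = 3L),
    "control pool")
  expect_equal(sort(unique(seqs$set_label)), c("control", "positive"))
  pos <- seqs[seqs$set_label == "positive", ]
  expect_equal(nchar(pos$sequence), rep(100 + 500, 2))
  expect_equal(pos$exon_offset, rep(250L, 2))
  # plus strand: window copied directly
  w <- as.character(Biostrings::subseq(fx$genome[["chr1"]], 351, 950))
  expect_equal(pos$sequence[pos$event_id == fx$events$event_id[1]], w)
  # minus strand: reverse complement of the genomic window
  w2 <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(fx$genome[["chr2"]], 351, 950)))
  expect_equal(pos$sequence[pos$event_id == fx$events$event_id[2]], w2)
  # only the unresponsive event 4 is control-eligible
  ctrl <- seqs[seqs$set_label == "control", ]
  expect_equal(ctrl$event_id, fx$events$event_id[4])
  # seeded draw is reproducible
  seqs2 <- suppressWarnings(
    build_motif_sets(fx$events$event_id[1:2], fx$events, oe,
                     fx$genome, flank = 250L, seed = 3L))
  expect_identical(seqs, seqs2)
})

test_that("planted motifs are recovered as positive/control enrichment", {
  # pyrimidine-rich background so chance GA-rich windows are rare
  set.seed(31)
  bg <- function() paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE,
                                prob = c(0.1, 0.4, 0.1, 0.4)), collapse = "")
  n <- 40L
  pos <- vapply(seq_len(n), function(i) {
    s <- bg()
    at <- sample(1:180, 1)  # inside the upstream flank
    paste0(substr(s, 1, at - 1), "GAAGGAGA", substr(s, at + 8, 600))
  }, character(1))
  ctrl <- vapply(seq_len(n), function(i) bg(), character(1))
  seqs <- data.frame(
    event_id = c(sprintf("p%02d", seq_len(n)), sprintf("c%02d", seq_len(n))),
    set_label = rep(c("positive", "control"), each = n),
    sequence = c(pos, ctrl),
    exon_offset = 250L, exon_length = 100L, truncated = FALSE,
    stringsAsFactors = FALSE)
  hits <- scan_motif_sets(seqs)
  fpos <- motif_fraction(hits, seqs$event_id[seqs$set_label == "positive"])
  fctrl <- motif_fraction(hits, seqs$event_id[seqs$set_label == "control"])
  expect_equal(fpos$fraction, 1)  # every planted sequence scans positive
  expect_gt(fpos$fraction - fctrl$fraction, 0.6)
  expect_true(all(hits$region[hits$set_label == "positive" &
                                hits$offset < 188] == "upstream_flank"))
})

test_that("motif fractions mirror simple tallies", {
  hits <- data.frame(event_id = c("a", "a", "b"))
  expect_equal(motif_fraction(hits, c("a", "b", "c"))$fraction, 2 / 3)
  expect_equal(motif_fraction(hits, character(0))$fraction, NA_real_)
  expect_equal(motif_fraction(hits[0, , drop = FALSE], c("a", "b"))$fraction, 0)
})
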