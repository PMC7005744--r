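test_that("CIGAR walk yields one junction per N gap with correct coordinates", {
  j <- extract_junctions(100, "20M100N30M")
  expect_equal(j$donor, 120)
  expect_equal(j$acceptor, 220)
  expect_equal(nrow(extract_junctions(0, "50M")), 0L)
  # insertions do not consume reference
  j2 <- extract_junctions(0, "10M5I10M200N20M")
  expect_equal(j2$donor, 20)
  expect_equal(j2$acceptor, 220)
  # soft clips do not consume reference either
  j3 <- extract_junctions(10, "5S10M50N10M3S")
  expect_equal(c(j3$donor, j3$acceptor), c(20, 70))
  # deletions do
  j4 <- extract_junctions(0, "10M2D10M50N10M")
  expect_equal(c(j4$donor, j4$acceptor), c(22, 72))
  expect_error(extract_junctions(0, "10M3Q"), "invalid CIGAR")
})

test_that("junction extraction matches a brute-force reference walk on random CIGARs", {
  set.seed(42)
  for (i in 1:300) {
    cigar <- random_cigar()
    pos <- sample(0:5000, 1)
    got <- extract_junctions(pos, cigar)
    ref <- junctions_oracle(pos, cigar)
    expect_equal(got$donor, ref$donor, info = cigar)
    expect_equal(got$acceptor, ref$acceptor, info = cigar)
  }
})

test_that("junction extraction agrees with GenomicAlignments on random CIGARs", {
  skip_if_not_installed("GenomicAlignments")
  set.seed(43)
  for (i in 1:100) {
    cigar <- random_cigar()
    pos <- sample(1:5000, 1)
    got <- extract_junctions(pos - 1, cigar)  # package is 0-based
    rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, ops = "N")[[1]]
    expect_equal(got$donor, BiocGenerics::start(rng) - 1, info = cigar)
    expect_equal(got$acceptor, BiocGenerics::end(rng), info = cigar)
  }
})

toy_index <- function() {
  build_splice_index(toy_models(c(100, 300, 500), c(200, 400, 600)))
}

test_that("reads classify into the three groups with stated precedence", {
  idx <- toy_index()
  # spliced across the annotated intron -> junction read
  expect_equal(classify_read("chr1", 150, "50M100N50M", idx),
               "exon_exon_junction")
  # unspliced fully inside an intron -> intronic
  expect_equal(classify_read("chr1", 220, "50M", idx), "fully_intronic")
  # unspliced spanning the exon/intron boundary at 200 -> bridging
  expect_equal(classify_read("chr1", 150, "100M", idx),
               "exon_intron_bridging")
  # fully exonic reads match no group
  expect_equal(classify_read("chr1", 110, "50M", idx), "unclassified")
  # overhang rule: 5 nt on one side of the boundary is not enough, and the
  # read is not fully intronic either
  expect_equal(classify_read("chr1", 195, "11M", idx, min_overhang = 6L),
               "unclassified")
  expect_equal(classify_read("chr1", 194, "12M", idx, min_overhang = 6L),
               "exon_intron_bridging")
  # unknown chromosome is unclassified, not an error
  expect_equal(classify_read("chrX", 150, "100M", idx), "unclassified")
})

write_sam <- function(path, records,
                      header = c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000")) {
  writeLines(c(header, records), path)
  path
}

sam_rec <- function(qname, pos0, cigar, flag = 0, mapq = 60, rname = "chr1") {
  rl <- sum(as.numeric(regmatches(
    cigar, gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos0 + 1, mapq, cigar, strrep("A", rl))
}

test_that("count_sample counts fragments, applies filters, and tallies QC", {
  idx <- toy_index()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, c(
    sam_rec("r1", 150, "50M100N50M"),
    sam_rec("r2", 150, "50M100N50M"),
    sam_rec("r3", 150, "50M100N50M"),
    sam_rec("pair1", 150, "50M100N50M", flag = 99),   # both mates span the
    sam_rec("pair1", 140, "60M100N40M", flag = 147),  # same junction: 1 fragment
    sam_rec("lowq", 150, "50M100N50M", mapq = 5),     # filtered
    sam_rec("intron1", 220, "50M")                    # group 3
  ))
  tab <- count_sample(sam, idx, sample_id = "s1")
  expect_equal(tab$junctions$count, 4L)  # r1 r2 r3 + pair1 once
  expect_equal(tab$junctions$donor, 200)
  expect_equal(tab$junctions$acceptor, 300)
  qc <- tab$qc
  expect_equal(unname(qc["reads_seen"]), 7)
  expect_equal(unname(qc["filtered"]), 1)
  expect_equal(unname(qc["passed"]), 6)
  # partition: passed reads distribute over the four classes
  expect_equal(unname(qc["passed"]),
               unname(qc["exon_exon_junction"] + qc["exon_intron_bridging"] +
                        qc["fully_intronic"] + qc["unclassified"]))
  # intron depth from the single intronic read
  expect_equal(nrow(tab$intron_depth), 1L)
  expect_equal(tab$intron_depth$covered_fraction, 50 / 100)
  expect_equal(tab$intron_depth$mean_depth, 50 / 100)
})

test_that("counting is idempotent and additive over disjoint SAM files", {
  idx <- toy_index()
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(s1, c(sam_rec("a1", 150, "50M100N50M"),
                  sam_rec("a2", 150, "50M100N50M")))
  write_sam(s2, c(sam_rec("b1", 350, "50M100N50M")))
  t1a <- count_sample(s1, idx)
  t1b <- count_sample(s1, idx)
  expect_identical(t1a$junctions, t1b$junctions)
  both <- withr::local_tempfile(fileext = ".sam")
  write_sam(both, c(sam_rec("a1", 150, "50M100N50M"),
                    sam_rec("a2", 150, "50M100N50M"),
                    sam_rec("b1", 350, "50M100N50M")))
  tb <- count_sample(both, idx)
  t2 <- count_sample(s2, idx)
  merged <- merge(t1a$junctions, t2$junctions,
                  by = c("chrom", "donor", "acceptor"), all = TRUE)
  merged$total <- ifelse(is.na(merged$count.x), 0, merged$count.x) +
    ifelse(is.na(merged$count.y), 0, merged$count.y)
  expect_equal(tb$junctions$count,
               merged$total[order(merged$donor, merged$acceptor)])
})

test_that("empty SAM streams produce an empty table with a warning", {
  idx <- toy_index()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, character(0))
  expect_warning(tab <- count_sample(sam, idx), "empty SAM")
  expect_equal(nrow(tab$junctions), 0L)
})

test_that("SJ tables parse with coordinate conversion and strand policy", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines("chr1\t201\t300\t1\t1\t1\t15\t3\t25", f)
  tab <- read_sj_table(f)
  expect_equal(tab$junctions$donor, 200)
  expect_equal(tab$junctions$acceptor, 300)
  expect_equal(tab$junctions$strand, "+")
  expect_equal(tab$junctions$count, 15L)  # unique reads only
  tab2 <- read_sj_table(f, keep_multi = TRUE)
  expect_equal(tab2$junctions$count, 18L)

  # strand code 0: resolved from annotation, else dropped
  writeLines(c("chr1\t201\t300\t0\t0\t1\t7\t0\t20",
               "chr1\t901\t950\t0\t0\t0\t9\t0\t20"), f)
  idx <- toy_index()
  tab3 <- read_sj_table(f, index = idx)
  expect_equal(nrow(tab3$junctions), 1L)
  expect_equal(tab3$junctions$strand, "+")
  tab4 <- read_sj_table(f)
  expect_equal(nrow(tab4$junctions), 0L)

  writeLines("chr1\t201\t300\t1", f)
  expect_error(read_sj_table(f), "expected 9 columns")
  writeLines(character(0), f)
  expect_warning(tab5 <- read_sj_table(f), "empty SJ table")
  expect_equal(nrow(tab5$junctions), 0L)
})

test_that("count tables round-trip through their TSV files byte-identically", {
  idx <- toy_index()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, c(sam_rec("r1", 150, "50M100N50M"),
                   sam_rec("r2", 220, "50M"),
                   sam_rec("r3", 150, "100M")))
  tab <- count_sample(sam, idx, sample_id = "sX")
  p1 <- file.path(withr::local_tempdir(), "a")
  p2 <- file.path(withr::local_tempdir(), "b")
  write_junction_counts(tab, p1)
  back <- read_junction_counts(p1)
  expect_equal(back$sample_id, "sX")
  expect_equal(back$junctions, tab$junctions)
  expect_equal(back$bridging, tab$bridging)
  write_junction_counts(back, p2)
  for (suffix in c(".junctions.tsv", ".bridging.tsv", ".introns.tsv")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
})
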