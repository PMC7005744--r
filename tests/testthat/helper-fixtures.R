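# Shared fixtures, all built in code.

# two-isoform gene: t1 has exons A(100,200) B(300,400) C(500,600) on '+',
# t2 skips B. GTF coordinates are 1-based inclusive.
write_toy_gtf <- function(path, strand = "+") {
  attr1 <- 'gene_id "gA"; transcript_id "gA.t1";'
  attr2 <- 'gene_id "gA"; transcript_id "gA.t2";'
  lines <- c(
    sprintf("chr1\ttoy\texon\t101\t200\t.\t%s\t.\t%s", strand, attr1),
    sprintf("chr1\ttoy\texon\t301\t400\t.\t%s\t.\t%s", strand, attr1),
    sprintf("chr1\ttoy\texon\t501\t600\t.\t%s\t.\t%s", strand, attr1),
    sprintf("chr1\ttoy\texon\t101\t200\t.\t%s\t.\t%s", strand, attr2),
    sprintf("chr1\ttoy\texon\t501\t600\t.\t%s\t.\t%s", strand, attr2)
  )
  writeLines(lines, path)
  path
}

# transcript_models built directly (0-based half-open), bypassing GTF
toy_models <- function(starts, ends, strand = "+", chrom = "chr1",
                       gene_id = "gA", transcript_id = "gA.t1",
                       cds_start = NA_real_) {
  ord <- if (strand == "-") rev(seq_along(starts)) else seq_along(starts)
  structure(list(
    transcripts = data.frame(transcript_id = transcript_id, gene_id = gene_id,
                             chrom = chrom, strand = strand,
                             cds_start = cds_start, cds_end = NA_real_,
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = transcript_id, gene_id = gene_id,
                       chrom = chrom, strand = strand, start = starts,
                       end = ends, exon_rank = ord, stringsAsFactors = FALSE)
  ), class = "transcript_models")
}

# minimal junction_counts table from a junction spec
toy_counts <- function(junctions = NULL, bridging = NULL, intron_depth = NULL,
                       sample_id = "s1") {
  structure(list(
    sample_id = sample_id,
    junctions = junctions %||% data.frame(
      chrom = character(), donor = numeric(), acceptor = numeric(),
      strand = character(), count = integer(), stringsAsFactors = FALSE),
    bridging = bridging %||% data.frame(
      chrom = character(), pos = numeric(), count = integer(),
      stringsAsFactors = FALSE),
    intron_depth = intron_depth %||% data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      covered_fraction = numeric(), mean_depth = numeric(),
      stringsAsFactors = FALSE),
    qc = c(reads_seen = 0)
  ), class = "junction_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one cassette event row in the interchange schema
toy_cassette_event <- function(event_id = "CE:chr1:+:300-400:200-500",
                               chrom = "chr1", strand = "+",
                               core = c(300, 400),
                               incl = "200-300;400-500", skip = "200-500") {
  df <- data.frame(event_id = event_id, event_type = "cassette_exon",
                   gene_id = "gA", chrom = chrom, strand = strand,
                   core_start = core[1], core_end = core[2],
                   inclusion_junctions = incl, skipping_junctions = skip,
                   annotated = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("splicing_events", "data.frame")
  df
}

# event_quant rows built directly for differential tests
toy_quant <- function(event_id, incl, skip, sample_id = "s1",
                      event_type = "cassette_exon") {
  total <- incl + skip
  df <- data.frame(event_id = event_id, sample_id = sample_id,
                   event_type = event_type, inclusion_reads = incl,
                   skipping_reads = skip,
                   si = ifelse(total > 0, incl / total, NA_real_),
                   total_junction_reads = total,
                   ir_covered_fraction = NA_real_, ir_mean_depth = NA_real_,
                   stringsAsFactors = FALSE)
  class(df) <- c("event_quant", "data.frame")
  df
}

# independent Fisher oracle: enumerate the conditional support and sum
# probabilities computed from first principles with lchoose
fisher_oracle <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  p <- exp(logp)
  obs <- p[xs == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# quadratic-time BH reference: q_i = min over j with p_j >= p_i of p_j*m/rank_j
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# brute-force junction oracle: expand the CIGAR to per-base reference
# coordinates and report gaps introduced by N operations
junctions_oracle <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ops <- substring(toks, nchar(toks))
  lens <- as.numeric(substring(toks, 1, nchar(toks) - 1))
  ref <- pos
  donors <- acceptors <- numeric(0)
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "D")) {
      ref <- ref + lens[i]
    } else if (ops[i] == "N") {
      donors <- c(donors, ref)
      ref <- ref + lens[i]
      acceptors <- c(acceptors, ref)
    }
  }
  data.frame(donor = donors, acceptor = acceptors)
}

random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- character(0)
  last <- ""
  for (i in seq_len(n_ops)) {
    pool <- setdiff(c("M", "I", "D", "N", "S"), last)
    op <- sample(pool, 1)
    ops <- c(ops, paste0(sample(1:80, 1), op))
    last <- op
  }
  # alignments must start and end with an aligned block
  paste0(sample(10:50, 1), "M", paste(ops, collapse = ""),
         sample(10:50, 1), "M")
}
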