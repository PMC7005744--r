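#' Configuration for the synthetic splicing dataset generator
#'
#' Bundles and validates the parameters of the generator, which emulates the
#' perturbation study design: a panel of multi-exon genes each carrying one
#' cassette exon, sequenced junction counts drawn from binomial (or
#' beta-binomial) sampling around true PSI values, and a knockdown plus an
#' overexpression sample per regulator, each compared against its own
#' control, with a designated subset of events shifted in opposite directions
#' between knockdown and overexpression.
#'
#' @param seed Integer RNG seed; fully determines every generated artifact.
#' @param n_genes Number of genes (one cassette event each).
#' @param exons_per_gene Integer range (min, max), at least 3.
#' @param exon_length,intron_length Length ranges in nt.
#' @param n_events_shifted Number of truly regulated cassette events.
#' @param delta_psi Injected |dPSI| for shifted events (default 0.3).
#' @param base_psi_range True-PSI range for unshifted events.
#' @param shifted_psi_range Baseline PSI range for shifted events; must keep
#'   PSI +/- delta_psi inside [0.02, 0.98].
#' @param depth Mean junction fragments per event per sample.
#' @param depth_model \code{"poisson"} (default) or \code{"fixed"}.
#' @param overdispersion Beta-binomial overdispersion rho in [0, 1); 0 gives
#'   pure binomial sampling.
#' @param regulators Regulator names; each contributes a KD and an OE sample.
#' @param read_length Read length for SAM emission (default 100).
#' @param bridging_depth Mean bridging fragments per intron boundary.
#' @param intronic_depth Mean fully-intronic fragments per intron.
#' @param frameshift_fraction Fraction of cassette exons whose length is not
#'   a multiple of 3.
#' @param ga_motif_fraction Fraction of genes with a GA-rich element planted
#'   in the upstream flank of the cassette exon.
#' @param gene_gap Intergenic spacing in nt (must exceed the motif flank).
#' @param chrom Chromosome name of the synthetic genome.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, exons_per_gene = c(4L, 8L),
                       exon_length = c(90L, 300L), intron_length = c(150L, 400L),
                       n_events_shifted = 20L, delta_psi = 0.3,
                       base_psi_range = c(0.05, 0.95),
                       shifted_psi_range = c(0.35, 0.65),
                       depth = 100, depth_model = c("poisson", "fixed"),
                       overdispersion = 0, regulators = c("ADAR1", "ADAR2"),
                       read_length = 100L, bridging_depth = 4,
                       intronic_depth = 2, frameshift_fraction = 0.5,
                       ga_motif_fraction = 0.5, gene_gap = 600L,
                       chrom = "chrSim") {
  depth_model <- match.arg(depth_model)
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, exons_per_gene[1L] >= 3,
            exons_per_gene[2L] >= exons_per_gene[1L],
            n_events_shifted <= n_genes, delta_psi >= 0,
            depth > 0, overdispersion >= 0, overdispersion < 1,
            read_length >= 20, gene_gap >= 300)
  if (exon_length[1L] < read_length / 2) {
    stop("minimum exon length must be at least read_length/2 for SAM emission")
  }
  if (intron_length[1L] < read_length + 16) {
    stop("minimum intron length too small for intronic read placement")
  }
  lo <- shifted_psi_range[1L] - delta_psi
  hi <- shifted_psi_range[2L] + delta_psi
  if (lo < 0.02 || hi > 0.98) {
    stop("shifted_psi_range +/- delta_psi must stay within [0.02, 0.98]")
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_samples <- function(cfg) {
  c("scr", "EV",
    paste0(rep(cfg$regulators, each = 2L), c("_KD", "_OE")))
}

derive_seed <- function(seed, k) (as.integer(seed) %% 2013265920L) + k

#' Generate a synthetic annotation and genome
#'
#' Lays out \code{n_genes} genes with one designated cassette exon each on a
#' single synthetic chromosome, two isoforms per gene (cassette included /
#' skipped), canonical GT..AG intron dinucleotides, a start codon on the
#' first coding exon, and a GA-rich element (GAAGGAGA) planted in the
#' upstream intronic flank of a seeded subset of cassette exons.
#'
#' @param cfg A \code{sim_config}.
#' @return An object of class \code{sim_annotation}: list with \code{config},
#'   \code{genes} (per-gene layout: exon coordinates, cassette index,
#'   frameshift and motif flags, inclusion/skipping junctions),
#'   \code{genome} (a \code{DNAStringSet}) and \code{models}
#'   (a \code{transcript_models} with both isoforms per gene).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 0L))
  motif <- "GAAGGAGA"
  genes <- vector("list", cfg$n_genes)
  cursor <- cfg$gene_gap
  fs_flags <- stats::runif(cfg$n_genes) < cfg$frameshift_fraction
  motif_flags <- stats::runif(cfg$n_genes) < cfg$ga_motif_fraction

  for (g in seq_len(cfg$n_genes)) {
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]), 1L)
    elens <- sample(seq(cfg$exon_length[1L], cfg$exon_length[2L]), n_ex,
                    replace = TRUE)
    ilens <- sample(seq(cfg$intron_length[1L], cfg$intron_length[2L]),
                    n_ex - 1L, replace = TRUE)
    ci <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
    # force the cassette length mod 3 per the frameshift flag
    r <- elens[ci] %% 3L
    if (fs_flags[g] && r == 0L) elens[ci] <- elens[ci] + 1L
    if (!fs_flags[g] && r != 0L) elens[ci] <- elens[ci] + (3L - r)

    starts <- ends <- integer(n_ex)
    pos <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + elens[i]
      pos <- ends[i] + if (i < n_ex) ilens[i] else 0L
    }
    cursor <- pos + cfg$gene_gap
    genes[[g]] <- list(
      gene_id = sprintf("g%04d", g), chrom = cfg$chrom, strand = strand,
      exon_start = starts, exon_end = ends, cassette_index = ci,
      frameshift = fs_flags[g], has_motif = motif_flags[g],
      j_up = c(ends[ci - 1L], starts[ci]),
      j_dn = c(ends[ci], starts[ci + 1L]),
      j_skip = c(ends[ci - 1L], starts[ci + 1L])
    )
  }
  glen <- cursor + cfg$gene_gap
  bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))

  put <- function(s, at) {  # at: 0-based start
    bases[(at + 1L):(at + nchar(s))] <<- strsplit(s, "")[[1L]]
  }
  for (gn in genes) {
    n_ex <- length(gn$exon_start)
    for (i in seq_len(n_ex - 1L)) {  # canonical splice dinucleotides
      d <- gn$exon_end[i]; a <- gn$exon_start[i + 1L]
      if (gn$strand == "+") { put("GT", d); put("AG", a - 2L) }
      else { put("CT", d); put("AC", a - 2L) }
    }
    if (gn$has_motif) {
      ci <- gn$cassette_index
      if (gn$strand == "+") {
        put(motif, gn$exon_start[ci] - 60L - nchar(motif))
      } else {
        put(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(motif))), gn$exon_end[ci] + 60L)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- cfg$chrom

  structure(list(config = cfg, genes = genes, genome = genome,
                 models = sim_models(cfg, genes)),
            class = "sim_annotation")
}

# transcript_models with the inclusion (t1) and skip (t2) isoform per gene
sim_models <- function(cfg, genes) {
  exrows <- list(); txrows <- list()
  for (gn in genes) {
    n_ex <- length(gn$exon_start)
    mk <- function(tid, idx) {
      ord <- if (gn$strand == "-") rev(seq_along(idx)) else seq_along(idx)
      data.frame(transcript_id = tid, gene_id = gn$gene_id, chrom = gn$chrom,
                 strand = gn$strand, start = gn$exon_start[idx],
                 end = gn$exon_end[idx], exon_rank = ord,
                 stringsAsFactors = FALSE)
    }
    t1 <- paste0(gn$gene_id, ".t1")
    t2 <- paste0(gn$gene_id, ".t2")
    exrows[[length(exrows) + 1L]] <- mk(t1, seq_len(n_ex))
    exrows[[length(exrows) + 1L]] <- mk(t2, setdiff(seq_len(n_ex),
                                                    gn$cassette_index))
    cds <- if (gn$strand == "+") gn$exon_start[1L] + 3
           else gn$exon_end[n_ex] - 4
    txrows[[length(txrows) + 1L]] <- data.frame(
      transcript_id = c(t1, t2), gene_id = gn$gene_id, chrom = gn$chrom,
      strand = gn$strand, cds_start = cds, cds_end = NA_real_,
      stringsAsFactors = FALSE)
  }
  ex <- do.call(rbind, exrows)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  structure(list(transcripts = do.call(rbind, txrows), exons = ex),
            class = "transcript_models")
}

#' Write the synthetic annotation as GTF and FASTA
#'
#' @param ann A \code{sim_annotation}.
#' @param gtf,fasta Output paths.
#' @return Invisibly, a character vector with the two paths.
#' @export
write_sim_annotation <- function(ann, gtf, fasta) {
  lines <- character(0)
  for (gn in ann$genes) {
    for (iso in c("t1", "t2")) {
      idx <- if (iso == "t1") seq_along(gn$exon_start)
             else setdiff(seq_along(gn$exon_start), gn$cassette_index)
      tid <- paste0(gn$gene_id, ".", iso)
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gn$gene_id, tid)
      lines <- c(lines, sprintf(
        "%s\tspliceSI_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        gn$chrom, min(gn$exon_start[idx]) + 1L, max(gn$exon_end[idx]),
        gn$strand, attrs))
      lines <- c(lines, sprintf(
        "%s\tspliceSI_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
        gn$chrom, gn$exon_start[idx] + 1L, gn$exon_end[idx], gn$strand, attrs))
      n_ex <- length(gn$exon_start)
      sc0 <- if (gn$strand == "+") gn$exon_start[1L] + 3L
             else gn$exon_end[n_ex] - 6L
      lines <- c(lines, sprintf(
        "%s\tspliceSI_sim\tstart_codon\t%d\t%d\t.\t%s\t.\t%s",
        gn$chrom, sc0 + 1L, sc0 + 3L, gn$strand, attrs))
    }
  }
  writeLines(lines, gtf)
  Biostrings::writeXStringSet(ann$genome, fasta)
  invisible(c(gtf = gtf, fasta = fasta))
}

#' Draw the ground-truth PSI table
#'
#' Assigns every cassette event a baseline PSI, selects
#' \code{n_events_shifted} events as truly regulated (round-robin across
#' regulators, random knockdown direction) and shifts their PSI by
#' \code{+sign * delta_psi} in the knockdown sample and \code{-sign *
#' delta_psi} in the overexpression sample of their regulator, so knockdown
#' and overexpression always move in opposite directions. Controls and the
#' other regulator's samples keep the baseline.
#'
#' @param cfg A \code{sim_config}.
#' @param ann The matching \code{sim_annotation}.
#' @return A \code{sim_truth} data.frame: \code{event_id}, \code{gene_id},
#'   \code{sample_id}, \code{true_psi}, \code{shifted}, \code{sign}
#'   (knockdown direction; 0 for null events), \code{regulator}.
#' @export
sim_truth <- function(cfg, ann) {
  set.seed(derive_seed(cfg$seed, 1L))
  ng <- length(ann$genes)
  base <- stats::runif(ng, cfg$base_psi_range[1L], cfg$base_psi_range[2L])
  shifted_idx <- sort(sample.int(ng, cfg$n_events_shifted))
  base[shifted_idx] <- stats::runif(length(shifted_idx),
                                    cfg$shifted_psi_range[1L],
                                    cfg$shifted_psi_range[2L])
  sgn <- integer(ng)
  sgn[shifted_idx] <- sample(c(-1L, 1L), length(shifted_idx), replace = TRUE)
  reg <- rep(NA_character_, ng)
  reg[shifted_idx] <- rep_len(cfg$regulators, length(shifted_idx))

  samples <- sim_samples(cfg)
  rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    gn <- ann$genes[[g]]
    eid <- cassette_event_id(gn)
    psi <- rep(base[g], length(samples))
    names(psi) <- samples
    if (g %in% shifted_idx) {
      psi[paste0(reg[g], "_KD")] <- base[g] + sgn[g] * cfg$delta_psi
      psi[paste0(reg[g], "_OE")] <- base[g] - sgn[g] * cfg$delta_psi
    }
    rows[[g]] <- data.frame(
      event_id = eid, gene_id = gn$gene_id, sample_id = samples,
      true_psi = unname(psi), shifted = g %in% shifted_idx,
      sign = sgn[g], regulator = reg[g], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sim_truth", "data.frame")
  out
}

cassette_event_id <- function(gn) {
  ci <- gn$cassette_index
  sprintf("CE:%s:%s:%d-%d:%d-%d", gn$chrom, gn$strand,
          gn$exon_start[ci], gn$exon_end[ci], gn$j_skip[1L], gn$j_skip[2L])
}

#' Simulate per-sample junction count tables
#'
#' For every cassette event and sample, the total junction depth is drawn
#' (Poisson around \code{depth}, or fixed), the inclusion total is binomial
#' (or beta-binomial under \code{overdispersion}) around the event's true
#' PSI, and the inclusion total is split evenly at random between the two
#' flanking junctions. Constitutive junctions receive Poisson(\code{depth})
#' counts; intron boundaries receive Poisson bridging counts and introns
#' fully-intronic read spans, which also drive the intron coverage/depth
#' summaries.
#'
#' @param cfg A \code{sim_config}.
#' @param ann The matching \code{sim_annotation}.
#' @param truth The \code{sim_truth} table.
#' @return Named list of \code{junction_counts}, one per sample. Each table
#'   carries the intronic read spans (element \code{intronic_spans}) so that
#'   SAM emission can reproduce it read for read.
#' @export
simulate_counts <- function(cfg, ann, truth) {
  set.seed(derive_seed(cfg$seed, 2L))
  samples <- sim_samples(cfg)
  rl <- cfg$read_length
  idx <- build_splice_index(ann$models)
  out <- stats::setNames(vector("list", length(samples)), samples)

  draw_total <- function(n) {
    if (cfg$depth_model == "fixed") rep(round(cfg$depth), n)
    else stats::rpois(n, cfg$depth)
  }
  draw_incl <- function(total, psi) {
    if (cfg$overdispersion > 0) {
      nu <- 1 / cfg$overdispersion - 1
      p <- stats::rbeta(length(total), psi * nu, (1 - psi) * nu)
      stats::rbinom(length(total), total, p)
    } else {
      stats::rbinom(length(total), total, psi)
    }
  }

  for (s in samples) {
    tpsi <- truth$true_psi[truth$sample_id == s]
    jrows <- list(); brows <- list(); spans <- list()
    total <- draw_total(length(ann$genes))
    incl <- draw_incl(total, tpsi)
    # the inclusion isoform spans two junctions, so it yields 2*incl
    # junction reads, split at random between the flanking junctions;
    # their mean is then exactly the binomial inclusion proportion
    up <- stats::rbinom(length(total), 2L * incl, 0.5)
    for (g in seq_along(ann$genes)) {
      gn <- ann$genes[[g]]
      n_ex <- length(gn$exon_start)
      dn <- 2L * incl[g] - up[g]
      skip <- total[g] - incl[g]
      jl <- data.frame(
        donor = c(gn$j_up[1L], gn$j_dn[1L], gn$j_skip[1L]),
        acceptor = c(gn$j_up[2L], gn$j_dn[2L], gn$j_skip[2L]),
        count = c(up[g], dn, skip))
      # constitutive introns: everything but the two flanking the cassette
      ci <- gn$cassette_index
      const <- setdiff(seq_len(n_ex - 1L), c(ci - 1L, ci))
      if (length(const)) {
        jl <- rbind(jl, data.frame(
          donor = gn$exon_end[const], acceptor = gn$exon_start[const + 1L],
          count = stats::rpois(length(const), cfg$depth)))
      }
      jl <- jl[jl$count > 0, , drop = FALSE]
      if (nrow(jl)) {
        jl$chrom <- gn$chrom; jl$strand <- gn$strand
        jrows[[length(jrows) + 1L]] <- jl
      }
      if (cfg$bridging_depth > 0) {
        bnd <- unique(c(gn$exon_end[-n_ex], gn$exon_start[-1L]))
        bc <- stats::rpois(length(bnd), cfg$bridging_depth)
        keep <- bc > 0
        if (any(keep)) {
          brows[[length(brows) + 1L]] <- data.frame(
            chrom = gn$chrom, pos = bnd[keep], count = bc[keep])
        }
      }
      if (cfg$intronic_depth > 0) {
        for (i in seq_len(n_ex - 1L)) {
          istart <- gn$exon_end[i]; iend <- gn$exon_start[i + 1L]
          k <- stats::rpois(1L, cfg$intronic_depth)
          if (k > 0 && iend - istart >= rl + 16L) {
            p0 <- istart + 8L +
              sample.int(iend - istart - rl - 15L, k, replace = TRUE) - 1L
            spans[[length(spans) + 1L]] <- data.frame(
              chrom = gn$chrom, start = p0, end = p0 + rl)
          }
        }
      }
    }
    junctions <- if (length(jrows)) {
      d <- do.call(rbind, jrows)
      d <- d[order(d$chrom, d$donor, d$acceptor),
             c("chrom", "donor", "acceptor", "strand", "count")]
      d$count <- as.integer(d$count)
      rownames(d) <- NULL
      d
    } else empty_junction_df()
    bridging <- if (length(brows)) {
      d <- do.call(rbind, brows)
      d <- stats::aggregate(count ~ chrom + pos, d, sum)
      d <- d[order(d$chrom, d$pos), c("chrom", "pos", "count")]
      d$count <- as.integer(d$count)
      rownames(d) <- NULL
      d
    } else data.frame(chrom = character(), pos = numeric(), count = integer())
    span_df <- if (length(spans)) do.call(rbind, spans) else NULL
    tab <- structure(list(
      sample_id = s, junctions = junctions, bridging = bridging,
      intron_depth = compute_intron_depth(span_df, idx),
      qc = c(reads_seen = sum(junctions$count) + sum(bridging$count) +
               if (is.null(span_df)) 0L else nrow(span_df)),
      intronic_spans = span_df
    ), class = "junction_counts")
    out[[s]] <- tab
  }
  out
}

#' Write the ground-truth table
#'
#' @param truth A \code{sim_truth} data.frame.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(format_num_df(as.data.frame(truth)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA", stringsAsFactors = FALSE)
  class(df) <- c("sim_truth", "data.frame")
  df
}

#' Emit a simulated sample as a SAM file
#'
#' Writes plain-text single-end SAM whose alignments reproduce the sample's
#' count table exactly: every junction count becomes that many spliced reads
#' anchored half-and-half across the junction, every bridging count that
#' many unspliced reads centered on the boundary, and the stored intronic
#' spans become fully intronic reads. Re-counting the file with
#' \code{\link{count_sample}} recovers the table.
#'
#' @param table A \code{junction_counts} from \code{\link{simulate_counts}}.
#' @param ann The \code{sim_annotation} (for the genome and read sequences).
#' @param path Output SAM path.
#' @return \code{path}, invisibly.
#' @export
write_sim_sam <- function(table, ann, path) {
  rl <- ann$config$read_length
  anchor <- rl %/% 2L
  genome <- ann$genome
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       unname(chrom_len))), con)
  qual <- strrep("I", rl)
  emit <- function(qname, chrom, pos0, cigar, seq) {
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            qname, chrom, pos0 + 1L, cigar, seq, qual)
  }
  gseq <- function(chrom, from0, to0) {  # 0-based half-open
    as.character(Biostrings::subseq(genome[[chrom]], from0 + 1L, to0))
  }
  lines <- character(0)
  j <- table$junctions
  for (i in seq_len(nrow(j))) {
    gap <- j$acceptor[i] - j$donor[i]
    cigar <- sprintf("%dM%dN%dM", anchor, gap, rl - anchor)
    seq <- paste0(gseq(j$chrom[i], j$donor[i] - anchor, j$donor[i]),
                  gseq(j$chrom[i], j$acceptor[i], j$acceptor[i] + rl - anchor))
    k <- seq_len(j$count[i])
    lines <- c(lines, emit(sprintf("%s_j%d_%d", table$sample_id, i, k),
                           j$chrom[i], j$donor[i] - anchor, cigar, seq))
  }
  b <- table$bridging
  for (i in seq_len(nrow(b))) {
    pos0 <- b$pos[i] - anchor
    seq <- gseq(b$chrom[i], pos0, pos0 + rl)
    k <- seq_len(b$count[i])
    lines <- c(lines, emit(sprintf("%s_b%d_%d", table$sample_id, i, k),
                           b$chrom[i], pos0, sprintf("%dM", rl), seq))
  }
  sp <- table$intronic_spans
  if (!is.null(sp) && nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      lines <- c(lines, emit(sprintf("%s_i%d", table$sample_id, i),
                             sp$chrom[i], sp$start[i], sprintf("%dM", rl),
                             gseq(sp$chrom[i], sp$start[i], sp$end[i])))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a junction table in the STAR SJ.out.tab dialect
#'
#' @param table A \code{junction_counts}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sj_tab <- function(table, path) {
  j <- table$junctions
  code <- c("+" = 1L, "-" = 2L, "*" = 0L)[j$strand]
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   j$chrom, j$donor + 1L, j$acceptor, unname(code), 0L, 1L,
                   j$count, 0L, 50L)
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic transcript reproducing the exon-skip AS-NMD geometry
#'
#' Constructs, entirely in code, a six-exon plus-strand transcript whose
#' cassette (third) exon has length 100 (a frameshifting skip) and whose
#' skipped isoform acquires its first in-frame stop codon near the start of
#' exon 5, exactly 368 nt upstream of the last exon-exon junction, with the
#' annotated stop at the end of exon 6 — the geometry of the RELL2 exon-3
#' skipping example. The construction is verified internally.
#'
#' @return list with \code{models} (a \code{transcript_models}),
#'   \code{genome} (\code{DNAStringSet}), \code{skip_index} (3) and
#'   \code{expected} (list: \code{ptc_position} 471,
#'   \code{distance} 368, \code{frameshift} TRUE).
#' @export
synthetic_asnmd_transcript <- function() {
  elens <- c(200L, 150L, 100L, 120L, 369L, 249L)
  ilen <- 200L
  cds_offset <- 12L
  n <- sum(elens)
  # repeating GCA background: no stop in any frame except where planted
  mrna <- strsplit(strrep("GCA", ceiling(n / 3) + 1L), "")[[1L]][1:n]
  put <- function(s, at) mrna[(at + 1L):(at + nchar(s))] <<- strsplit(s, "")[[1L]]
  put("ATG", cds_offset)   # start codon
  put("TAA", 571L)         # stop in the shifted frame, early in exon 5
  put("TAA", n - 3L)       # annotated stop at the end of exon 6
  mrna <- paste(mrna, collapse = "")

  gstart <- 500L
  starts <- ends <- integer(6L)
  pos <- gstart
  for (i in 1:6) {
    starts[i] <- pos; ends[i] <- pos + elens[i]
    pos <- ends[i] + ilen
  }
  glen <- pos + 500L
  set.seed(20260920L)
  bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  cum <- cumsum(c(0L, elens))
  for (i in 1:6) {
    bases[(starts[i] + 1L):ends[i]] <-
      strsplit(substr(mrna, cum[i] + 1L, cum[i + 1L]), "")[[1L]]
  }
  for (i in 1:5) {  # canonical dinucleotides
    bases[ends[i] + 1:2] <- c("G", "T")
    bases[starts[i + 1L] - 1:0] <- c("A", "G")
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrNMD"

  models <- structure(list(
    transcripts = data.frame(
      transcript_id = "NMD1.t1", gene_id = "NMD1", chrom = "chrNMD",
      strand = "+", cds_start = gstart + cds_offset, cds_end = NA_real_,
      stringsAsFactors = FALSE),
    exons = data.frame(
      transcript_id = "NMD1.t1", gene_id = "NMD1", chrom = "chrNMD",
      strand = "+", start = starts, end = ends, exon_rank = 1:6,
      stringsAsFactors = FALSE)
  ), class = "transcript_models")

  # internal verification of the constructed geometry
  proj <- project_skip(models, "NMD1.t1", 3L, genome)
  chk <- call_nmd(proj)
  stopifnot(chk$ptc_position == 471, chk$distance_to_last_junction == 368,
            chk$frameshift, chk$nmd_sensitive)

  list(models = models, genome = genome, skip_index = 3L,
       expected = list(ptc_position = 471, distance = 368, frameshift = TRUE))
}
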