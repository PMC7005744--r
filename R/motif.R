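#' Build positive and control sequence sets for motif analysis
#'
#' Assembles the two sequence sets used to look for splicing-regulatory
#' motifs around regulated cassette exons: the positive set contains the
#' high-confidence regulated cassette exons with \code{flank} nucleotides of
#' flanking sequence on both sides; the control set is a size-matched seeded
#' random sample of cassette exons that did not respond to either
#' overexpression contrast (|dSI| < \code{dsi_cutoff} in all of them).
#' Sequences are sense-strand: minus-strand exons are reverse-complemented,
#' so downstream scanning searches only the given strand.
#'
#' @param calls A \code{bidirectional_calls} object (typically relaxed mode)
#'   or a character vector of event ids forming the positive set.
#' @param events The \code{splicing_events} table the ids refer to.
#' @param oe_results A \code{contrast_result} or list of them for the
#'   overexpression contrasts, used to select unresponsive controls.
#' @param genome A \code{Biostrings::DNAStringSet}.
#' @param flank Flank length in nt (default 250).
#' @param dsi_cutoff Control events must have |dSI| below this in every
#'   overexpression contrast (default 0.10).
#' @param seed Optional integer seed for the size-matched control draw.
#' @return An \code{event_sequences} data.frame: \code{event_id},
#'   \code{set_label} ("positive"/"control"), \code{sequence},
#'   \code{exon_offset}, \code{exon_length} (0-based position and length of
#'   the exon within the sequence) and \code{truncated} (window clipped at a
#'   chromosome end). Events whose exon lies outside the genome are dropped
#'   with a warning.
#' @export
build_motif_sets <- function(calls, events, oe_results, genome, flank = 250L,
                             dsi_cutoff = 0.10, seed = NULL) {
  pos_ids <- if (inherits(calls, "bidirectional_calls")) calls$event_id else calls
  ce <- events[events$event_type == "cassette_exon", , drop = FALSE]
  pos <- ce[ce$event_id %in% pos_ids, , drop = FALSE]

  if (inherits(oe_results, "contrast_result")) oe_results <- list(oe_results)
  quiet <- rep(TRUE, nrow(ce))
  for (res in oe_results) {
    idx <- match(ce$event_id, res$event_id)
    d <- res$delta_si[idx]
    quiet <- quiet & !is.na(d) & abs(d) < dsi_cutoff
  }
  ctrl_pool <- ce[quiet & !(ce$event_id %in% pos$event_id), , drop = FALSE]
  n_ctrl <- min(nrow(pos), nrow(ctrl_pool))
  if (n_ctrl < nrow(pos)) {
    warning("control pool (", nrow(ctrl_pool),
            ") smaller than positive set (", nrow(pos), ")")
  }
  if (!is.null(seed)) {
    ctrl <- local_seed_do(seed, function()
      ctrl_pool[sample.int(nrow(ctrl_pool), n_ctrl), , drop = FALSE])
  } else {
    ctrl <- ctrl_pool[sample.int(nrow(ctrl_pool), n_ctrl), , drop = FALSE]
  }

  grab <- function(df, label) {
    if (!nrow(df)) {
      return(data.frame(event_id = character(), set_label = character(),
                        sequence = character(), exon_offset = integer(),
                        exon_length = integer(), truncated = logical(),
                        stringsAsFactors = FALSE))
    }
    rows <- lapply(seq_len(nrow(df)), function(i) {
      ch <- df$chrom[i]
      if (!ch %in% names(genome)) return(NULL)
      clen <- length(genome[[ch]])
      if (df$core_start[i] >= clen || df$core_end[i] <= 0) {
        warning("event ", df$event_id[i], " outside genome bounds; dropped")
        return(NULL)
      }
      w1 <- max(0, df$core_start[i] - flank)
      w2 <- min(clen, df$core_end[i] + flank)
      s <- Biostrings::subseq(genome[[ch]], start = w1 + 1L, end = w2)
      exon_off <- df$core_start[i] - w1
      if (df$strand[i] == "-") {
        s <- Biostrings::reverseComplement(s)
        exon_off <- (w2 - w1) - (exon_off + (df$core_end[i] - df$core_start[i]))
      }
      data.frame(event_id = df$event_id[i], set_label = label,
                 sequence = toupper(as.character(s)),
                 exon_offset = as.integer(exon_off),
                 exon_length = as.integer(df$core_end[i] - df$core_start[i]),
                 truncated = (w1 > df$core_start[i] - flank) ||
                   (w2 < df$core_end[i] + flank),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  }
  out <- rbind(grab(pos, "positive"), grab(ctrl, "control"))
  rownames(out) <- NULL
  class(out) <- c("event_sequences", "data.frame")
  out
}

local_seed_do <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Write motif sequence sets as FASTA
#'
#' Emits one FASTA per set label (\code{<prefix>.positive.fa},
#' \code{<prefix>.control.fa}), ready for external motif discovery.
#'
#' @param seqs An \code{event_sequences} data.frame.
#' @param prefix Output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_motif_fasta <- function(seqs, prefix) {
  for (lab in unique(seqs$set_label)) {
    d <- seqs[seqs$set_label == lab, , drop = FALSE]
    ss <- Biostrings::DNAStringSet(d$sequence)
    names(ss) <- d$event_id
    Biostrings::writeXStringSet(ss, paste0(prefix, ".", lab, ".fa"))
  }
  invisible(prefix)
}

#' Scan a sequence for GA-rich motif windows
#'
#' Default GA-rich rule: a window of width \code{min_width} to
#' \code{max_width} containing only purines (A/G) with at least \code{min_g}
#' G and \code{min_a} A — wide enough to capture GAAGGAGA-like elements while
#' excluding homopolymer runs. Hits are maximal windows taken greedily,
#' non-overlapping, from the left: at each position the widest qualifying
#' window is emitted and scanning resumes past it.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param min_width,max_width Window width bounds (defaults 6 and 9).
#' @param min_g,min_a Minimum G and A counts per window (defaults 2).
#' @param exon_offset,exon_length Optional 0-based exon position within the
#'   sequence; when given, each hit is assigned a region
#'   (\code{upstream_flank} / \code{exon} / \code{downstream_flank}) by its
#'   start offset.
#' @return data.frame with columns \code{offset} (0-based), \code{width},
#'   \code{matched} and \code{region}.
#' @export
scan_ga_rich <- function(sequence, min_width = 6L, max_width = 9L,
                         min_g = 2L, min_a = 2L,
                         exon_offset = NA_integer_, exon_length = NA_integer_) {
  stopifnot(nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_a <- chars == "A"
  is_g <- chars == "G"
  ca <- cumsum(is_a); cg <- cumsum(is_g)
  nA <- function(i, j) ca[j] - if (i > 1L) ca[i - 1L] else 0L
  nG <- function(i, j) cg[j] - if (i > 1L) cg[i - 1L] else 0L
  offs <- widths <- integer(0)
  i <- 1L
  while (i <= n - min_width + 1L) {
    hit_w <- 0L
    for (w in seq(min(max_width, n - i + 1L), min_width)) {
      j <- i + w - 1L
      pur <- nA(i, j) + nG(i, j)
      if (pur == w && nA(i, j) >= min_a && nG(i, j) >= min_g) {
        hit_w <- w
        break
      }
    }
    if (hit_w) {
      offs <- c(offs, i - 1L)  # 0-based
      widths <- c(widths, hit_w)
      i <- i + hit_w
    } else {
      i <- i + 1L
    }
  }
  if (!length(offs)) {
    return(data.frame(offset = integer(), width = integer(),
                      matched = character(), region = character(),
                      stringsAsFactors = FALSE))
  }
  region <- rep(NA_character_, length(offs))
  if (!is.na(exon_offset) && !is.na(exon_length)) {
    region <- ifelse(offs < exon_offset, "upstream_flank",
                     ifelse(offs >= exon_offset + exon_length,
                            "downstream_flank", "exon"))
  }
  data.frame(offset = offs, width = widths,
             matched = substring(sequence, offs + 1L, offs + widths),
             region = region, stringsAsFactors = FALSE)
}

#' Scan a motif sequence set and tabulate hits
#'
#' Applies \code{\link{scan_ga_rich}} to every sequence of an
#' \code{event_sequences} table.
#'
#' @param seqs An \code{event_sequences} data.frame.
#' @param ... Passed to \code{\link{scan_ga_rich}}.
#' @return data.frame of hits with \code{event_id} and \code{set_label}
#'   prepended.
#' @export
scan_motif_sets <- function(seqs, ...) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    h <- scan_ga_rich(seqs$sequence[i], exon_offset = seqs$exon_offset[i],
                      exon_length = seqs$exon_length[i], ...)
    if (!nrow(h)) return(NULL)
    cbind(data.frame(event_id = seqs$event_id[i],
                     set_label = seqs$set_label[i],
                     stringsAsFactors = FALSE), h)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(event_id = character(), set_label = character(),
                      offset = integer(), width = integer(),
                      matched = character(), region = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fraction of events carrying at least one motif hit
#'
#' @param hits Hit table with an \code{event_id} column (e.g. from
#'   \code{\link{scan_motif_sets}}).
#' @param event_ids Character vector: the full event set scanned.
#' @return list with \code{n_with_hit}, \code{n_total} and \code{fraction}
#'   (\code{NA} for an empty event set).
#' @export
motif_fraction <- function(hits, event_ids) {
  n_total <- length(event_ids)
  n_hit <- sum(event_ids %in% unique(hits$event_id))
  list(n_with_hit = n_hit, n_total = n_total,
       fraction = if (n_total) n_hit / n_total else NA_real_)
}
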