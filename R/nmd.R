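#' Project a transcript with one cassette exon skipped
#'
#' Builds the mature mRNA that results from skipping one internal exon of a
#' transcript model: the remaining exon sequences are concatenated in
#' transcription order (reverse-complemented for minus-strand genes), the
#' exon-exon junction positions are recomputed in mRNA coordinates, and the
#' annotated start codon is carried over when its exon survives the skip.
#'
#' @param models A \code{transcript_models} object.
#' @param transcript_id Transcript to project.
#' @param exon_index Index (transcription order) of the exon to skip; must be
#'   internal.
#' @param genome A \code{Biostrings::DNAStringSet} (names = chromosomes).
#' @return An object of class \code{isoform_projection}: list with
#'   \code{parent_transcript_id}, \code{skipped_exon_index},
#'   \code{skipped_exon_length}, \code{mrna} (character), \code{mrna_full}
#'   (the unskipped mRNA), \code{junction_positions} (0-based mRNA
#'   coordinates of the first base after each junction),
#'   \code{cds_offset} (0-based mRNA coordinate of the start codon, \code{NA}
#'   with \code{cds_lost = TRUE} when the start codon sat on the skipped
#'   exon) and \code{frameshift} (skipped length not divisible by 3).
#' @export
project_skip <- function(models, transcript_id, exon_index, genome) {
  stopifnot(inherits(models, "transcript_models"))
  ex <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$exon_rank), , drop = FALSE]
  n <- nrow(ex)
  if (exon_index <= 1L || exon_index >= n) {
    stop("exon_index must name an internal exon (2..", n - 1L, ")")
  }
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  strand <- tx$strand

  exon_seq <- function(d) {
    s <- Biostrings::subseq(genome[[d$chrom]], start = d$start + 1L, end = d$end)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }
  seqs <- vapply(seq_len(n), function(i) exon_seq(ex[i, ]), character(1L))
  lens <- ex$end - ex$start

  mrna_full <- paste(seqs, collapse = "")
  keep <- setdiff(seq_len(n), exon_index)
  mrna <- paste(seqs[keep], collapse = "")
  jpos <- cumsum(lens[keep])
  jpos <- jpos[-length(jpos)]

  # map the annotated start codon into mRNA coordinates of the skipped form
  cds_offset <- NA_real_
  cds_lost <- FALSE
  if (!is.na(tx$cds_start)) {
    host <- which(ex$start <= tx$cds_start & tx$cds_start < ex$end)
    if (length(host) == 1L) {
      if (host == exon_index) {
        cds_lost <- TRUE
      } else {
        within <- if (strand == "+") tx$cds_start - ex$start[host]
                  else ex$end[host] - 1 - tx$cds_start
        pos_in_keep <- match(host, keep)
        cds_offset <- sum(lens[keep][seq_len(pos_in_keep - 1L)]) + within
      }
    }
  }
  # frameshift is meaningful for exons fully inside the CDS; the flag
  # reports the arithmetic either way
  structure(list(
    parent_transcript_id = transcript_id,
    skipped_exon_index = exon_index,
    skipped_exon_length = lens[exon_index],
    mrna = mrna,
    mrna_full = mrna_full,
    junction_positions = jpos,
    cds_offset = cds_offset,
    cds_lost = cds_lost,
    frameshift = (lens[exon_index] %% 3) != 0
  ), class = "isoform_projection")
}

#' @export
print.isoform_projection <- function(x, ...) {
  cat("isoform_projection of", x$parent_transcript_id, "- skipped exon",
      x$skipped_exon_index, "(", x$skipped_exon_length, "nt )\n")
  cat("  mRNA", nchar(x$mrna), "nt,", length(x$junction_positions),
      "junction(s), cds_offset",
      if (is.na(x$cds_offset)) "undefined" else x$cds_offset,
      if (x$frameshift) "- frameshifting skip" else "", "\n")
  invisible(x)
}

stop_codons <- c("TAA", "TAG", "TGA")

#' Call NMD sensitivity of a skipped isoform
#'
#' Translates the projected mRNA from the start codon in codon steps, takes
#' the first stop codon reached as the (premature) termination codon, and
#' applies the exon-junction-complex rule: the transcript is predicted
#' NMD-sensitive when the stop lies more than \code{rule_threshold}
#' nucleotides upstream of the last exon-exon junction (default 50 nt, the
#' canonical rule). A stop in the last exon has non-positive distance and is
#' never NMD-sensitive.
#'
#' @param proj An \code{isoform_projection} with a defined \code{cds_offset}.
#' @param rule_threshold Distance rule in nt (default 50).
#' @return An object of class \code{nmd_call}: list with \code{ptc_position}
#'   (0-based mRNA coordinate of the first in-frame stop, \code{NA} when no
#'   stop is found), \code{distance_to_last_junction} (positive = stop
#'   upstream of the last junction), \code{nmd_sensitive},
#'   \code{frameshift} and \code{no_stop_found}.
#' @export
call_nmd <- function(proj, rule_threshold = 50) {
  stopifnot(inherits(proj, "isoform_projection"))
  if (is.na(proj$cds_offset)) {
    stop("cds_offset undefined (start codon lost or unannotated); ",
         "cannot call NMD")
  }
  mrna <- proj$mrna
  n <- nchar(mrna)
  ptc <- NA_real_
  at <- proj$cds_offset
  while (at + 3 <= n) {
    codon <- substr(mrna, at + 1, at + 3)
    if (codon %in% stop_codons) { ptc <- at; break }
    at <- at + 3
  }
  last_j <- if (length(proj$junction_positions)) {
    max(proj$junction_positions)
  } else NA_real_
  dist <- if (!is.na(ptc) && !is.na(last_j)) last_j - ptc else NA_real_
  structure(list(
    ptc_position = ptc,
    distance_to_last_junction = dist,
    nmd_sensitive = !is.na(dist) && dist > rule_threshold,
    frameshift = proj$frameshift,
    no_stop_found = is.na(ptc)
  ), class = "nmd_call")
}

#' @export
print.nmd_call <- function(x, ...) {
  if (x$no_stop_found) {
    cat("nmd_call: no in-frame stop codon found (not NMD-sensitive)\n")
  } else {
    cat("nmd_call: first stop at mRNA position", x$ptc_position, "-",
        x$distance_to_last_junction, "nt upstream of the last junction;",
        if (x$nmd_sensitive) "NMD-sensitive" else "not NMD-sensitive", "\n")
  }
  invisible(x)
}
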