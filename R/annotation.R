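#' Parse a GTF file into transcript models
#'
#' Reads exon (and, when present, start/stop codon) records from a GTF file
#' and assembles per-transcript exon models. Internal coordinates are 0-based
#' half-open throughout the package; the GTF convention (1-based inclusive)
#' is converted at this boundary. Both Ensembl and GENCODE attribute dialects
#' are accepted (anything \code{rtracklayer} understands).
#'
#' Transcripts whose exon records mix strands are rejected with a warning;
#' transcript records lacking any exon are dropped with a warning.
#'
#' @param path Path to a GTF file.
#' @return An object of class \code{transcript_models}: a list with
#'   \describe{
#'     \item{transcripts}{data.frame with columns \code{transcript_id},
#'       \code{gene_id}, \code{chrom}, \code{strand}, \code{cds_start},
#'       \code{cds_end}. \code{cds_start} is the 0-based genomic coordinate
#'       of the first transcribed base of the start codon (\code{NA} when
#'       unannotated); \code{cds_end} the first transcribed base of the stop
#'       codon.}
#'     \item{exons}{data.frame with columns \code{transcript_id},
#'       \code{gene_id}, \code{chrom}, \code{strand}, \code{start},
#'       \code{end}, \code{exon_rank} (transcription order, 1 = 5'-most).}
#'   }
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    stop("GTF records lack gene_id/transcript_id attributes: ", path)
  }
  feat <- data.frame(
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ex <- feat[feat$type == "exon" & !is.na(feat$transcript_id), , drop = FALSE]

  # strand consistency: reject transcripts mixing strands
  ns <- tapply(ex$strand, ex$transcript_id, function(s) length(unique(s)))
  bad <- names(ns)[ns > 1L]
  if (length(bad)) {
    warning("rejecting ", length(bad),
            " transcript(s) with inconsistent exon strands: ",
            paste(utils::head(bad, 5L), collapse = ", "))
    ex <- ex[!(ex$transcript_id %in% bad), , drop = FALSE]
  }

  # transcript records without exons are dropped with a warning
  tx_declared <- unique(feat$transcript_id[feat$type == "transcript" &
                                             !is.na(feat$transcript_id)])
  orphan <- setdiff(tx_declared, unique(ex$transcript_id))
  if (length(orphan)) {
    warning("dropping ", length(orphan), " transcript(s) without exons: ",
            paste(utils::head(orphan, 5L), collapse = ", "))
  }
  if (!nrow(ex)) stop("no exon records in GTF: ", path)

  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  # transcription order: genomic order on '+', reversed on '-'
  ex$exon_rank <- NA_integer_
  for (idx in split(seq_len(nrow(ex)), ex$transcript_id)) {
    n <- length(idx)
    ex$exon_rank[idx] <- if (ex$strand[idx[1L]] == "-") rev(seq_len(n)) else seq_len(n)
  }

  tx_ids <- unique(ex$transcript_id)
  first <- ex[!duplicated(ex$transcript_id), , drop = FALSE]
  rownames(first) <- first$transcript_id
  tx <- data.frame(
    transcript_id = tx_ids,
    gene_id = first[tx_ids, "gene_id"],
    chrom = first[tx_ids, "chrom"],
    strand = first[tx_ids, "strand"],
    cds_start = NA_real_,
    cds_end = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(tx) <- tx$transcript_id

  # start/stop codon anchors: first transcribed base of the codon
  anchor <- function(rows) {
    if (!nrow(rows)) return(NULL)
    vapply(split(rows, rows$transcript_id), function(d) {
      if (d$strand[1L] == "+") min(d$start) else max(d$end) - 1
    }, numeric(1L))
  }
  sc <- anchor(feat[feat$type == "start_codon", , drop = FALSE])
  st <- anchor(feat[feat$type == "stop_codon", , drop = FALSE])
  if (!is.null(sc)) {
    keep <- intersect(names(sc), tx$transcript_id)
    tx[keep, "cds_start"] <- sc[keep]
  }
  if (!is.null(st)) {
    keep <- intersect(names(st), tx$transcript_id)
    tx[keep, "cds_end"] <- st[keep]
  }
  # fall back to CDS span when codon features are absent
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    for (tid in setdiff(unique(cds$transcript_id), names(sc %||% character()))) {
      if (!tid %in% tx$transcript_id || !is.na(tx[tid, "cds_start"])) next
      d <- cds[cds$transcript_id == tid, , drop = FALSE]
      tx[tid, "cds_start"] <- if (d$strand[1L] == "+") min(d$start) else max(d$end) - 1
    }
  }

  rownames(ex) <- NULL
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = ex), class = "transcript_models")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# light pre-validation so a malformed line is reported by number
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1L))
  bad <- which(body)[nf < 8L]
  if (length(bad)) {
    stop("malformed GTF line ", bad[1L], " in ", path,
         " (expected >= 8 tab-separated fields)")
  }
  invisible(TRUE)
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$transcripts), "transcript(s),",
      nrow(x$exons), "exon record(s),",
      length(unique(x$transcripts$gene_id)), "gene(s)\n")
  invisible(x)
}

# introns implied by consecutive exons, per transcript, as 0-based half-open
# intervals (donor = genomic left boundary, acceptor = genomic right boundary)
transcript_introns <- function(models) {
  ex <- models$exons
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  out <- lapply(split(ex, ex$transcript_id), function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    data.frame(
      transcript_id = d$transcript_id[1L],
      gene_id = d$gene_id[1L],
      chrom = d$chrom[1L],
      strand = d$strand[1L],
      donor = d$end[-n],
      acceptor = d$start[-1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      donor = numeric(), acceptor = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

junc_key <- function(chrom, donor, acceptor) paste(chrom, donor, acceptor, sep = ":")

fmt_junctions <- function(d, a) paste(paste0(d, "-", a), collapse = ";")

#' Enumerate candidate alternative-splicing events from transcript models
#'
#' Produces the four event types quantified by the splicing index: cassette
#' exons, retained introns, and alternative 5'/3' splice sites. Cassette
#' candidates are enumerated per gene across isoforms: every internal exon
#' flanked by two annotated introns is a candidate, and its \code{annotated}
#' flag records whether some isoform of the gene actually skips it (i.e. the
#' skipping junction is itself annotated). Every annotated intron yields an
#' intron-retention candidate. Pairs of annotated junctions of a gene sharing
#' one boundary and differing at the other yield alternative 5' or 3' splice
#' site candidates (which of the two depends on the strand).
#'
#' Event identifiers are deterministic functions of coordinates, so the same
#' input always yields a byte-identical event table.
#'
#' @param models A \code{transcript_models} object from \code{\link{parse_gtf}}.
#' @return A \code{splicing_events} data.frame with columns \code{event_id},
#'   \code{event_type}, \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{core_start}, \code{core_end}, \code{inclusion_junctions},
#'   \code{skipping_junctions} (semicolon-joined \code{donor-acceptor} pairs,
#'   0-based half-open) and \code{annotated}.
#' @export
enumerate_events <- function(models) {
  stopifnot(inherits(models, "transcript_models"))
  ex <- models$exons
  rows <- list()

  for (gid in sort(unique(ex$gene_id))) {
    gex <- ex[ex$gene_id == gid, , drop = FALSE]
    chrom <- gex$chrom[1L]
    strand <- gex$strand[1L]
    gintr <- transcript_introns(
      structure(list(exons = gex), class = "transcript_models"))
    ann_j <- unique(junc_key(gintr$chrom, gintr$donor, gintr$acceptor))

    eid <- type <- inclj <- skipj <- character(0)
    cs <- ce <- numeric(0)
    annotated <- logical(0)
    add <- function(.eid, .type, .cs, .ce, .inclj, .skipj, .ann) {
      eid <<- c(eid, .eid); type <<- c(type, .type)
      cs <<- c(cs, .cs); ce <<- c(ce, .ce)
      inclj <<- c(inclj, .inclj); skipj <<- c(skipj, .skipj)
      annotated <<- c(annotated, .ann)
    }

    # --- cassette exons: internal exons of each isoform, deduped per gene
    seen <- character()
    for (d in split(gex, gex$transcript_id)) {
      d <- d[order(d$start), , drop = FALSE]
      n <- nrow(d)
      if (n < 3L) next
      for (i in 2:(n - 1L)) {
        key <- paste(d$end[i - 1L], d$start[i], d$end[i], d$start[i + 1L])
        if (key %in% seen) next
        seen <- c(seen, key)
        skip_d <- d$end[i - 1L]; skip_a <- d$start[i + 1L]
        add(sprintf("CE:%s:%s:%d-%d:%d-%d", chrom, strand,
                    d$start[i], d$end[i], skip_d, skip_a),
            "cassette_exon", d$start[i], d$end[i],
            fmt_junctions(c(d$end[i - 1L], d$end[i]),
                          c(d$start[i], d$start[i + 1L])),
            fmt_junctions(skip_d, skip_a),
            junc_key(chrom, skip_d, skip_a) %in% ann_j)
      }
    }

    # --- intron retention: every distinct annotated intron
    ji <- unique(gintr[c("donor", "acceptor")])
    ji <- ji[order(ji$donor, ji$acceptor), , drop = FALSE]
    for (k in seq_len(nrow(ji))) {
      add(sprintf("IR:%s:%s:%d-%d", chrom, strand, ji$donor[k], ji$acceptor[k]),
          "intron_retention", ji$donor[k], ji$acceptor[k], "",
          fmt_junctions(ji$donor[k], ji$acceptor[k]), TRUE)
    }

    # --- alternative splice sites: junction pairs sharing one boundary.
    # Genomic-left boundary shared => the right boundary varies: that is the
    # 3'ss on '+' and the 5'ss on '-'; and vice versa.
    if (nrow(ji) >= 2L) {
      for (shared in c("donor", "acceptor")) {
        other <- if (shared == "donor") "acceptor" else "donor"
        for (grp in split(ji, ji[[shared]])) {
          if (nrow(grp) < 2L) next
          grp <- grp[order(grp[[other]]), , drop = FALSE]
          for (i in 1:(nrow(grp) - 1L)) for (j in (i + 1L):nrow(grp)) {
            a <- grp[i, ]; b <- grp[j, ]   # a is the shorter intron
            if ((b$acceptor - b$donor) < (a$acceptor - a$donor)) { tmp <- a; a <- b; b <- tmp }
            varies_right <- shared == "donor"
            atype <- if (xor(varies_right, strand == "-")) "alt_3ss" else "alt_5ss"
            core <- sort(c(a[[other]], b[[other]]))
            add(sprintf("%s:%s:%s:%d-%d:%d-%d",
                        if (atype == "alt_5ss") "A5" else "A3", chrom, strand,
                        a$donor, a$acceptor, b$donor, b$acceptor),
                atype, core[1L], core[2L],
                fmt_junctions(a$donor, a$acceptor),
                fmt_junctions(b$donor, b$acceptor), TRUE)
          }
        }
      }
    }

    if (length(eid)) {
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = eid, event_type = type, gene_id = gid, chrom = chrom,
        strand = strand, core_start = cs, core_end = ce,
        inclusion_junctions = inclj, skipping_junctions = skipj,
        annotated = annotated, stringsAsFactors = FALSE)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    event_id = character(), event_type = character(), gene_id = character(),
    chrom = character(), strand = character(), core_start = numeric(),
    core_end = numeric(), inclusion_junctions = character(),
    skipping_junctions = character(), annotated = logical(),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("splicing_events", "data.frame")
  out
}

#' @export
print.splicing_events <- function(x, ...) {
  cat("splicing_events:", nrow(x), "event(s)\n")
  if (nrow(x)) print(table(x$event_type))
  invisible(x)
}

#' Write / read a splicing-event table
#'
#' Tab-separated interchange format with a header; coordinates stay in the
#' internal 0-based half-open convention. \code{read_events(write_events(x))}
#' reproduces \code{x} exactly, and rewriting the file is byte-identical.
#'
#' @param events A \code{splicing_events} data.frame.
#' @param path Output (input) file path.
#' @return \code{write_events} returns \code{path} invisibly;
#'   \code{read_events} returns a \code{splicing_events} data.frame.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$annotated <- ifelse(df$annotated, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 5L),
                                         "numeric", "numeric",
                                         "character", "character", "character"),
                          na.strings = NULL, quote = "")
  df$annotated <- df$annotated == "true"
  class(df) <- c("splicing_events", "data.frame")
  df
}

#' Build a splice-site index for read classification
#'
#' Collects the annotated exons, introns and junctions of a set of transcript
#' models into lookup tables used by \code{\link{classify_read}} and
#' \code{\link{count_sample}}.
#'
#' @param models A \code{transcript_models} object.
#' @return An object of class \code{splice_index}: list with \code{exons}
#'   and \code{introns} (unique 0-based half-open intervals) and
#'   \code{junctions} (unique \code{chrom:donor:acceptor} keys).
#' @export
build_splice_index <- function(models) {
  stopifnot(inherits(models, "transcript_models"))
  exu <- unique(models$exons[c("chrom", "start", "end", "strand")])
  intr <- transcript_introns(models)
  inu <- unique(intr[c("chrom", "donor", "acceptor", "strand")])
  names(inu) <- c("chrom", "start", "end", "strand")
  rownames(exu) <- rownames(inu) <- NULL
  structure(list(
    exons = exu,
    introns = inu,
    junctions = unique(junc_key(intr$chrom, intr$donor, intr$acceptor))
  ), class = "splice_index")
}
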