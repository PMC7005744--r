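#' Extract splice junctions from a CIGAR string
#'
#' Walks the reference-consuming operations of a spliced alignment and returns
#' one junction per \code{N} operation. \code{M}, \code{D}, \code{=} and
#' \code{X} consume reference; \code{I}, \code{S}, \code{H} and \code{P} do
#' not. The donor is the 0-based reference coordinate where the gap begins
#' (exclusive end of the left aligned block) and the acceptor the coordinate
#' where it ends (start of the right block), so \code{donor < acceptor}
#' always and the pair is exactly the intron as a half-open interval.
#'
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @return data.frame with columns \code{donor}, \code{acceptor},
#'   \code{left_anchor}, \code{right_anchor} (reference lengths of the
#'   aligned blocks flanking the gap). Zero rows for unspliced alignments.
#' @export
extract_junctions <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  ref <- pos
  block <- 0
  donors <- acceptors <- lefts <- numeric(0)
  pending <- integer(0)  # indices of junctions waiting for their right anchor
  rights <- numeric(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X", "D")) {
      ref <- ref + len
      block <- block + len
    } else if (op == "N") {
      if (length(pending)) {
        rights[pending] <- block
        pending <- integer(0)
      }
      donors <- c(donors, ref)
      acceptors <- c(acceptors, ref + len)
      lefts <- c(lefts, block)
      rights <- c(rights, NA_real_)
      pending <- length(donors)
      ref <- ref + len
      block <- 0
    }
    # I, S, H, P: no reference consumed, block unchanged
  }
  if (length(pending)) rights[pending] <- block
  data.frame(donor = donors, acceptor = acceptors,
             left_anchor = lefts, right_anchor = rights)
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(data.frame(op = character(), len = numeric()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("invalid CIGAR: ", cigar)
  }
  data.frame(op = substring(toks, nchar(toks)),
             len = as.numeric(substring(toks, 1L, nchar(toks) - 1L)))
}

# reference length consumed by an alignment
cigar_reference_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

#' Classify a read into the three junction-analysis groups
#'
#' Reads are classified by their position relative to annotated splice sites:
#' spliced reads whose gap matches an annotated or plausible
#' (\code{donor < acceptor}) junction are exon-exon junction reads (group 1);
#' unspliced reads covering an annotated exon-intron boundary with at least
#' \code{min_overhang} aligned nucleotides on each side are bridging reads
#' (group 2); unspliced reads falling entirely inside an annotated intron are
#' fully intronic (group 3); everything else is unclassified. The classes are
#' mutually exclusive with precedence junction > bridging > intronic.
#'
#' @param chrom Reference name of the alignment.
#' @param pos 0-based leftmost reference position.
#' @param cigar CIGAR string.
#' @param index A \code{splice_index} from \code{\link{build_splice_index}}.
#' @param min_overhang Minimum aligned overlap (nt) on each side of a
#'   boundary for bridging reads (default 6).
#' @return One of \code{"exon_exon_junction"}, \code{"exon_intron_bridging"},
#'   \code{"fully_intronic"}, \code{"unclassified"}.
#' @export
classify_read <- function(chrom, pos, cigar, index, min_overhang = 6L) {
  j <- extract_junctions(pos, cigar)
  if (nrow(j)) {
    ok <- junc_key(chrom, j$donor, j$acceptor) %in% index$junctions |
      j$acceptor > j$donor
    if (any(ok)) return("exon_exon_junction")
    return("unclassified")
  }
  span_start <- pos
  span_end <- pos + cigar_reference_length(cigar)
  intr <- index$introns[index$introns$chrom == chrom, , drop = FALSE]
  if (nrow(intr)) {
    bnd <- unique(c(intr$start, intr$end))
    if (any(span_start <= bnd - min_overhang & span_end >= bnd + min_overhang)) {
      return("exon_intron_bridging")
    }
    if (any(span_start >= intr$start & span_end <= intr$end)) {
      return("fully_intronic")
    }
  }
  "unclassified"
}

read_sam_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = numeric(),
                      mapq = integer(), cigar = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1L))
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1L],
         " of body: fewer than 11 fields")
  }
  data.frame(
    qname = vapply(f, `[[`, "", 1L),
    flag = as.integer(vapply(f, `[[`, "", 2L)),
    rname = vapply(f, `[[`, "", 3L),
    pos = as.numeric(vapply(f, `[[`, "", 4L)) - 1,  # to 0-based
    mapq = as.integer(vapply(f, `[[`, "", 5L)),
    cigar = vapply(f, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

#' Count junction, bridging and intronic evidence for one sample
#'
#' Streams a plain-text SAM file, applies the QC filters, classifies every
#' passing read (see \code{\link{classify_read}}) and aggregates a per-sample
#' \code{junction_counts} table. Counting is fragment-level: a junction (or
#' boundary) supported by both mates of a pair is counted once. Intron
#' coverage and mean depth are computed from fully intronic reads only.
#'
#' @param sam Path to a SAM file.
#' @param index A \code{splice_index}.
#' @param sample_id Sample identifier stored in the table.
#' @param filters List of QC thresholds: \code{min_mapq} (default 20),
#'   \code{min_overhang} (default 6, junction anchors and bridging overlap),
#'   \code{require_primary} (default TRUE), \code{drop_duplicates} (default
#'   TRUE).
#' @return An object of class \code{junction_counts}: list with
#'   \code{sample_id}; \code{junctions} (chrom, donor, acceptor, strand,
#'   count); \code{bridging} (chrom, pos, count) keyed by intron boundary;
#'   \code{intron_depth} (chrom, start, end, covered_fraction, mean_depth);
#'   and a \code{qc} vector (reads_seen, filtered, passed and per-class
#'   tallies).
#' @export
count_sample <- function(sam, index, sample_id = basename(sam),
                         filters = list()) {
  f <- utils::modifyList(list(min_mapq = 20L, min_overhang = 6L,
                              require_primary = TRUE, drop_duplicates = TRUE),
                         filters)
  rec <- read_sam_records(sam)
  qc <- c(reads_seen = nrow(rec), filtered = 0, passed = 0, bad_cigar = 0,
          exon_exon_junction = 0, exon_intron_bridging = 0,
          fully_intronic = 0, unclassified = 0)
  if (!nrow(rec)) warning("empty SAM stream: ", sam)

  keep <- rep(TRUE, nrow(rec))
  keep <- keep & !bitwAnd(rec$flag, 4L)                   # mapped
  if (f$require_primary) {
    keep <- keep & !bitwAnd(rec$flag, 256L) & !bitwAnd(rec$flag, 2048L)
  }
  if (f$drop_duplicates) keep <- keep & !bitwAnd(rec$flag, 1024L)
  keep <- keep & rec$mapq >= f$min_mapq
  cig_ok <- vapply(rec$cigar, function(cg)
    !inherits(try(parse_cigar(cg), silent = TRUE), "try-error") & cg != "*",
    logical(1L), USE.NAMES = FALSE)
  qc["bad_cigar"] <- sum(keep & !cig_ok)
  keep <- keep & cig_ok
  qc["filtered"] <- qc["reads_seen"] - sum(keep)
  qc["passed"] <- sum(keep)
  rec <- rec[keep, , drop = FALSE]

  jfrag <- list(); bfrag <- list()
  intronic <- list()
  for (i in seq_len(nrow(rec))) {
    cls <- classify_read(rec$rname[i], rec$pos[i], rec$cigar[i], index,
                         min_overhang = f$min_overhang)
    qc[cls] <- qc[cls] + 1
    if (cls == "exon_exon_junction") {
      j <- extract_junctions(rec$pos[i], rec$cigar[i])
      j <- j[j$left_anchor >= f$min_overhang &
               j$right_anchor >= f$min_overhang, , drop = FALSE]
      if (nrow(j)) {
        jfrag[[length(jfrag) + 1L]] <- data.frame(
          fragment = rec$qname[i],
          key = junc_key(rec$rname[i], j$donor, j$acceptor),
          stringsAsFactors = FALSE)
      }
    } else if (cls == "exon_intron_bridging") {
      span_end <- rec$pos[i] + cigar_reference_length(rec$cigar[i])
      intr <- index$introns[index$introns$chrom == rec$rname[i], , drop = FALSE]
      bnd <- unique(c(intr$start, intr$end))
      hit <- bnd[rec$pos[i] <= bnd - f$min_overhang &
                   span_end >= bnd + f$min_overhang]
      if (length(hit)) {
        bfrag[[length(bfrag) + 1L]] <- data.frame(
          fragment = rec$qname[i],
          key = paste(rec$rname[i], hit, sep = ":"),
          stringsAsFactors = FALSE)
      }
    } else if (cls == "fully_intronic") {
      intronic[[length(intronic) + 1L]] <- data.frame(
        chrom = rec$rname[i], start = rec$pos[i],
        end = rec$pos[i] + cigar_reference_length(rec$cigar[i]),
        stringsAsFactors = FALSE)
    }
  }

  # fragment-level deduplication: a (fragment, key) pair counts once
  tab_frag <- function(lst) {
    if (!length(lst)) return(integer(0))
    d <- unique(do.call(rbind, lst))
    table(d$key)
  }
  jt <- tab_frag(jfrag)
  junctions <- if (length(jt)) {
    parts <- strsplit(names(jt), ":", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, "", 1L),
               donor = as.numeric(vapply(parts, `[[`, "", 2L)),
               acceptor = as.numeric(vapply(parts, `[[`, "", 3L)),
               strand = "*", count = as.integer(jt),
               stringsAsFactors = FALSE)
  } else empty_junction_df()
  junctions <- junctions[order(junctions$chrom, junctions$donor,
                               junctions$acceptor), , drop = FALSE]
  rownames(junctions) <- NULL

  bt <- tab_frag(bfrag)
  bridging <- if (length(bt)) {
    parts <- strsplit(names(bt), ":", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, "", 1L),
               pos = as.numeric(vapply(parts, `[[`, "", 2L)),
               count = as.integer(bt), stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), pos = numeric(), count = integer())
  bridging <- bridging[order(bridging$chrom, bridging$pos), , drop = FALSE]
  rownames(bridging) <- NULL

  intron_depth <- compute_intron_depth(
    if (length(intronic)) do.call(rbind, intronic) else NULL, index)

  structure(list(sample_id = sample_id, junctions = junctions,
                 bridging = bridging, intron_depth = intron_depth, qc = qc),
            class = "junction_counts")
}

empty_junction_df <- function() {
  data.frame(chrom = character(), donor = numeric(), acceptor = numeric(),
             strand = character(), count = integer(), stringsAsFactors = FALSE)
}

compute_intron_depth <- function(spans, index) {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    covered_fraction = numeric(), mean_depth = numeric(),
                    stringsAsFactors = FALSE)
  if (is.null(spans) || !nrow(spans)) return(out)
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, , drop = FALSE]
    intr <- index$introns[index$introns$chrom == ch, , drop = FALSE]
    if (!nrow(intr)) next
    cov <- IRanges::coverage(IRanges::IRanges(start = s$start + 1L, end = s$end))
    for (k in seq_len(nrow(intr))) {
      i1 <- intr$start[k] + 1L; i2 <- intr$end[k]
      v <- as.integer(window_coverage(cov, i1, i2))
      out <- rbind(out, data.frame(
        chrom = ch, start = intr$start[k], end = intr$end[k],
        covered_fraction = mean(v > 0), mean_depth = mean(v),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[out$mean_depth > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

window_coverage <- function(cov, from, to) {
  n <- length(cov)
  if (from > n) return(integer(to - from + 1L))
  v <- as.integer(cov)[from:min(to, n)]
  c(v, integer(max(0L, to - n)))
}

#' Read a STAR-style splice-junction table
#'
#' Parses the nine-column \code{SJ.out.tab} dialect (chrom, 1-based intron
#' start, 1-based intron end, strand code 0/1/2, motif code, annotated flag,
#' unique reads, multi-mapping reads, max overhang) into a
#' \code{junction_counts} table. Coordinates are converted to the internal
#' 0-based half-open convention; unique-read counts are used unless
#' \code{keep_multi}. Junctions with strand code 0 have their strand resolved
#' from the annotation index when supplied, and are dropped otherwise.
#'
#' @param path Path to an SJ.out.tab file.
#' @param sample_id Sample identifier.
#' @param index Optional \code{splice_index} used to resolve undefined strands.
#' @param keep_multi Add the multi-mapping read column to the counts
#'   (default FALSE).
#' @return A \code{junction_counts} object (bridging/intron depth empty).
#' @export
read_sj_table <- function(path, sample_id = basename(path), index = NULL,
                          keep_multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty SJ table: ", path)
    return(structure(list(sample_id = sample_id,
                          junctions = empty_junction_df(),
                          bridging = data.frame(chrom = character(),
                                                pos = numeric(),
                                                count = integer()),
                          intron_depth = compute_intron_depth(NULL, NULL),
                          qc = c(reads_seen = 0)),
                     class = "junction_counts"))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1L))
  if (any(nf != 9L)) {
    stop("SJ table parse error at line ", which(nf != 9L)[1L], " of ", path,
         ": expected 9 columns, got ", nf[which(nf != 9L)[1L]])
  }
  m <- do.call(rbind, f)
  strand <- c("0" = "*", "1" = "+", "2" = "-")[m[, 4L]]
  d <- data.frame(chrom = m[, 1L],
                  donor = as.numeric(m[, 2L]) - 1,   # 1-based intron start
                  acceptor = as.numeric(m[, 3L]),    # 1-based inclusive end
                  strand = unname(strand),
                  count = as.integer(m[, 7L]) +
                    if (keep_multi) as.integer(m[, 8L]) else 0L,
                  stringsAsFactors = FALSE)
  undef <- d$strand == "*"
  if (any(undef)) {
    if (!is.null(index)) {
      key <- junc_key(d$chrom, d$donor, d$acceptor)
      resolvable <- undef & key %in% index$junctions
      if (any(resolvable)) {
        ann <- index$introns
        akey <- junc_key(ann$chrom, ann$start, ann$end)
        d$strand[resolvable] <- ann$strand[match(key[resolvable], akey)]
      }
      d <- d[!(undef & !resolvable), , drop = FALSE]
    } else {
      d <- d[!undef, , drop = FALSE]
    }
  }
  rownames(d) <- NULL
  structure(list(sample_id = sample_id, junctions = d,
                 bridging = data.frame(chrom = character(), pos = numeric(),
                                       count = integer()),
                 intron_depth = compute_intron_depth(NULL, NULL),
                 qc = c(reads_seen = sum(d$count))),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("junction_counts for sample", x$sample_id, "\n")
  cat(" ", nrow(x$junctions), "junction(s),", nrow(x$bridging),
      "bridging boundary(ies),", nrow(x$intron_depth), "intron depth row(s)\n")
  if (length(x$qc)) {
    cat("  qc:", paste(names(x$qc), round(unname(x$qc), 2), sep = "=",
                       collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read per-sample count tables
#'
#' Writes the three component tables of a \code{junction_counts} object to
#' \code{<prefix>.junctions.tsv}, \code{<prefix>.bridging.tsv} and
#' \code{<prefix>.introns.tsv}, each starting with a versioned header line,
#' plus a QC JSON sidecar \code{<prefix>.qc.json}. Reading the files back
#' and rewriting them is byte-identical.
#'
#' @param x A \code{junction_counts} object.
#' @param prefix Output path prefix.
#' @return \code{write_junction_counts} returns \code{prefix} invisibly;
#'   \code{read_junction_counts} returns a \code{junction_counts} object.
#' @export
write_junction_counts <- function(x, prefix) {
  hdr <- paste0("#spliceSI_counts_v1\tsample=", x$sample_id)
  wt <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(format_num_df(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  wt(x$junctions, paste0(prefix, ".junctions.tsv"))
  wt(x$bridging, paste0(prefix, ".bridging.tsv"))
  wt(x$intron_depth, paste0(prefix, ".introns.tsv"))
  jsonlite::write_json(as.list(x$qc), paste0(prefix, ".qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) format(v, digits = 15L),
                         character(1L))
    }
  }
  df
}

#' @rdname write_junction_counts
#' @export
read_junction_counts <- function(prefix) {
  rd <- function(path, classes) {
    hdr <- readLines(path, n = 1L)
    if (!startsWith(hdr, "#spliceSI_counts_v1")) {
      stop("unrecognized count-table header in ", path)
    }
    sample_id <- sub("^#spliceSI_counts_v1\tsample=", "", hdr)
    df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                            colClasses = classes, quote = "",
                            na.strings = NULL)
    list(sample_id = sample_id, df = df)
  }
  j <- rd(paste0(prefix, ".junctions.tsv"),
          c("character", "numeric", "numeric", "character", "integer"))
  b <- rd(paste0(prefix, ".bridging.tsv"),
          c("character", "numeric", "integer"))
  d <- rd(paste0(prefix, ".introns.tsv"),
          c("character", "numeric", "numeric", "numeric", "numeric"))
  qc <- unlist(jsonlite::read_json(paste0(prefix, ".qc.json"),
                                   simplifyVector = TRUE))
  structure(list(sample_id = j$sample_id, junctions = j$df, bridging = b$df,
                 intron_depth = d$df, qc = qc),
            class = "junction_counts")
}
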