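#' Quantify splicing events against a per-sample count table
#'
#' Computes, for every event and one sample, the inclusion and skipping read
#' counts and the splicing index SI = inclusion / (inclusion + skipping).
#' The counts entering the ratio are adjusted per event type:
#' \itemize{
#'   \item cassette exon: inclusion = rounded (half-to-even) combination of
#'     the two flanking inclusion-junction counts (default arithmetic mean),
#'     skipping = the skipping-junction count;
#'   \item alternative 5'/3' splice site: inclusion = count of the
#'     event-defining (longer-exon, shorter-intron) junction, skipping = the
#'     alternative junction count;
#'   \item intron retention: inclusion = rounded mean of the bridging counts
#'     at the two intron boundaries, skipping = the spliced-junction count,
#'     with the intron's covered fraction and mean depth carried along as QC
#'     side-car fields.
#' }
#' Rounding keeps counts integral so they can enter Fisher 2x2 tables.
#' SI is \code{NA} when inclusion + skipping = 0.
#'
#' @param events A \code{splicing_events} data.frame.
#' @param table A \code{junction_counts} object for one sample.
#' @param combiner How to combine the two cassette inclusion junctions:
#'   \code{"mean"} (default), \code{"sum"} or \code{"min"}.
#' @return An \code{event_quant} data.frame: \code{event_id},
#'   \code{sample_id}, \code{event_type}, \code{inclusion_reads},
#'   \code{skipping_reads}, \code{si}, \code{total_junction_reads},
#'   \code{ir_covered_fraction}, \code{ir_mean_depth}.
#' @export
quantify_events <- function(events, table, combiner = c("mean", "sum", "min")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(table, "junction_counts"))
  jc <- table$junctions
  jmap <- stats::setNames(jc$count, junc_key(jc$chrom, jc$donor, jc$acceptor))
  bmap <- stats::setNames(table$bridging$count,
                          paste(table$bridging$chrom, table$bridging$pos,
                                sep = ":"))
  dmap <- table$intron_depth
  jcount <- function(chrom, jstr) {
    if (!nzchar(jstr)) return(numeric(0))
    pairs <- strsplit(strsplit(jstr, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    keys <- vapply(pairs, function(p) junc_key(chrom, p[1L], p[2L]),
                   character(1L))
    v <- jmap[keys]
    v[is.na(v)] <- 0
    unname(v)
  }
  bcount <- function(chrom, pos) {
    v <- bmap[paste(chrom, pos, sep = ":")]
    if (is.na(v)) 0 else unname(v)
  }
  combine <- switch(combiner, mean = function(v) round(mean(v)),
                    sum = function(v) sum(v), min = function(v) min(v))

  n <- nrow(events)
  incl <- skip <- numeric(n)
  irc <- ird <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    type <- events$event_type[i]
    ch <- events$chrom[i]
    sk <- sum(jcount(ch, events$skipping_junctions[i]))
    if (type == "cassette_exon") {
      incl[i] <- combine(jcount(ch, events$inclusion_junctions[i]))
      skip[i] <- sk
    } else if (type == "intron_retention") {
      br <- c(bcount(ch, events$core_start[i]), bcount(ch, events$core_end[i]))
      incl[i] <- round(mean(br))
      skip[i] <- sk
      if (nrow(dmap)) {
        hit <- which(dmap$chrom == ch & dmap$start == events$core_start[i] &
                       dmap$end == events$core_end[i])
        if (length(hit)) {
          irc[i] <- dmap$covered_fraction[hit[1L]]
          ird[i] <- dmap$mean_depth[hit[1L]]
        }
      }
    } else {  # alt_5ss / alt_3ss
      incl[i] <- sum(jcount(ch, events$inclusion_junctions[i]))
      skip[i] <- sk
    }
  }
  total <- incl + skip
  out <- data.frame(
    event_id = events$event_id,
    sample_id = table$sample_id,
    event_type = events$event_type,
    inclusion_reads = incl,
    skipping_reads = skip,
    si = ifelse(total > 0, incl / total, NA_real_),
    total_junction_reads = total,
    ir_covered_fraction = irc,
    ir_mean_depth = ird,
    stringsAsFactors = FALSE
  )
  class(out) <- c("event_quant", "data.frame")
  out
}

#' Percent spliced in from band intensities
#'
#' The RT-PCR analogue of the splicing index: the inclusion-band intensity
#' divided by the sum of inclusion- and skipping-band intensities.
#'
#' @param inclusion_intensity,skipping_intensity Non-negative band
#'   intensities.
#' @return PSI as a fraction in \code{[0, 1]}; \code{NA} when both
#'   intensities are zero.
#' @export
psi_from_band_intensities <- function(inclusion_intensity, skipping_intensity) {
  stopifnot(all(inclusion_intensity >= 0), all(skipping_intensity >= 0))
  total <- inclusion_intensity + skipping_intensity
  ifelse(total > 0, inclusion_intensity / total, NA_real_)
}

#' Write / read event quantifications
#'
#' Long-format TSV with one row per event per sample. Round-trips exactly.
#'
#' @param quant An \code{event_quant} data.frame (rows from several samples
#'   may be concatenated).
#' @param path File path.
#' @return \code{write_quant} returns \code{path} invisibly;
#'   \code{read_quant} an \code{event_quant} data.frame.
#' @export
write_quant <- function(quant, path) {
  utils::write.table(format_num_df(as.data.frame(quant)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant
#' @export
read_quant <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA",
                          colClasses = c("character", "character", "character",
                                         rep("numeric", 6L)))
  class(df) <- c("event_quant", "data.frame")
  df
}
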