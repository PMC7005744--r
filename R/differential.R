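#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for a 2x2 contingency table of junction counts,
#' computed by summing the hypergeometric probabilities (conditional on the
#' observed margins) of every table whose probability does not exceed that of
#' the observed table — the minimum-likelihood convention used by mainstream
#' exact-test implementations. Probability ties are compared with a 1e-7
#' relative tolerance so that symmetric tables sum both tails exactly.
#'
#' The whole conditional support is evaluated in one vectorized pass, so the
#' test is cheap enough to run over thousands of events per contrast.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts, rows = condition (treatment, control), columns = (inclusion,
#'   skipping).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers")
  }
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  m1 <- a + b          # row 1 margin
  m2 <- cc + d         # row 2 margin
  k <- a + cc          # column 1 margin
  if (m1 + m2 == 0) stop("at least one margin must be positive")
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, m2, k)
  obs <- dens[support == a]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} capped at 1, and return in
#' the original order. Thin wrapper over \code{stats::p.adjust(method =
#' "BH")} kept as the package's single FDR entry point.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential splicing for one contrast
#'
#' Pools replicate quantifications within each arm by summing inclusion and
#' skipping counts per event, computes the SI difference
#' (treatment - control), a two-sided Fisher exact p-value on the pooled 2x2
#' table, and Benjamini-Hochberg FDR across all tested events of the
#' contrast (all event types jointly). An event passes the filters when its
#' total junction reads reach \code{t_reads}, |dSI| reaches \code{t_dsi} and
#' FDR is strictly below \code{t_fdr} — the defaults are the screening rule
#' total junction reads >= 15, |dSI| >= 10\%, FDR < 0.2.
#'
#' Events whose SI is undefined (zero junction coverage) in either arm are
#' not tested: they are reported with \code{tested = FALSE} and never pass.
#' The per-event read total entering the >= 15 rule is, by default, the
#' minimum of the two per-arm totals (the conservative reading: each arm must
#' carry the evidence); \code{total_rule = "sum"} uses the grand total
#' instead.
#'
#' @param quant_t,quant_c \code{event_quant} rows for the treatment and
#'   control arms; several samples per arm are pooled.
#' @param contrast_id Label for this contrast (e.g. "ADAR1-KD-vs-ctrl").
#' @param t_reads,t_dsi,t_fdr Filter thresholds (defaults 15, 0.10, 0.2).
#' @param total_rule \code{"min"} (default) or \code{"sum"}.
#' @return A \code{contrast_result} data.frame with one row per event:
#'   pooled counts per arm, \code{si_treatment}, \code{si_control},
#'   \code{delta_si}, \code{total_junction_reads}, \code{p_value},
#'   \code{fdr}, \code{tested}, \code{passes_filters}.
#' @export
call_contrast <- function(quant_t, quant_c, contrast_id = "contrast",
                          t_reads = 15, t_dsi = 0.10, t_fdr = 0.2,
                          total_rule = c("min", "sum")) {
  total_rule <- match.arg(total_rule)
  pool <- function(q) {
    incl <- tapply(q$inclusion_reads, q$event_id, sum)
    skip <- tapply(q$skipping_reads, q$event_id, sum)
    type <- tapply(q$event_type, q$event_id, `[`, 1L)
    data.frame(event_id = names(incl), event_type = as.vector(type),
               inclusion = as.vector(incl), skipping = as.vector(skip),
               stringsAsFactors = FALSE)
  }
  pt <- pool(quant_t); pc <- pool(quant_c)
  ids <- sort(union(pt$event_id, pc$event_id))
  it <- match(ids, pt$event_id); ic <- match(ids, pc$event_id)
  g <- function(v, idx) ifelse(is.na(idx), 0, v[idx])
  incl_t <- g(pt$inclusion, it); skip_t <- g(pt$skipping, it)
  incl_c <- g(pc$inclusion, ic); skip_c <- g(pc$skipping, ic)
  tot_t <- incl_t + skip_t; tot_c <- incl_c + skip_c
  si_t <- ifelse(tot_t > 0, incl_t / tot_t, NA_real_)
  si_c <- ifelse(tot_c > 0, incl_c / tot_c, NA_real_)
  tested <- tot_t > 0 & tot_c > 0
  delta <- si_t - si_c
  total <- if (total_rule == "min") pmin(tot_t, tot_c) else tot_t + tot_c

  p <- rep(NA_real_, length(ids))
  for (i in which(tested)) {
    p[i] <- fisher_exact_2x2(matrix(round(c(incl_t[i], skip_t[i],
                                            incl_c[i], skip_c[i])),
                                    nrow = 2L, byrow = TRUE))
  }
  fdr <- rep(NA_real_, length(ids))
  fdr[tested] <- bh_fdr(p[tested])

  passes <- tested & !is.na(fdr) &
    passes_splicing_filters(total, delta, ifelse(is.na(fdr), 1, fdr),
                            t_reads, t_dsi, t_fdr)
  type <- ifelse(is.na(it), pc$event_type[ic], pt$event_type[it])

  out <- data.frame(
    event_id = ids, event_type = type, contrast_id = contrast_id,
    inclusion_t = incl_t, skipping_t = skip_t,
    inclusion_c = incl_c, skipping_c = skip_c,
    si_treatment = si_t, si_control = si_c, delta_si = delta,
    total_junction_reads = total, p_value = p, fdr = fdr,
    tested = tested, passes_filters = passes,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(t_reads = t_reads, t_dsi = t_dsi, t_fdr = t_fdr)
  attr(out, "total_rule") <- total_rule
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("contrast_result '", x$contrast_id[1L], "': ", nrow(x), " event(s), ",
      sum(x$tested), " tested, ", sum(x$passes_filters), " passing filters\n",
      sep = "")
  cat("  thresholds: total reads >= ", th["t_reads"], ", |dSI| >= ",
      th["t_dsi"], ", FDR < ", th["t_fdr"], "\n", sep = "")
  invisible(x)
}

#' @method summary contrast_result
#' @export
summary.contrast_result <- function(object, ...) {
  pass <- object[object$passes_filters, , drop = FALSE]
  out <- list(contrast_id = object$contrast_id[1L],
              n_events = nrow(object), n_tested = sum(object$tested),
              n_pass = nrow(pass),
              by_type = table(pass$event_type),
              delta_si_range = if (nrow(pass)) range(pass$delta_si) else NULL)
  class(out) <- "summary.contrast_result"
  out
}

#' @export
print.summary.contrast_result <- function(x, ...) {
  cat("Contrast", x$contrast_id, "-", x$n_pass, "of", x$n_tested,
      "tested events pass filters\n")
  if (x$n_pass) {
    print(x$by_type)
    cat("dSI range among passing events: [",
        round(x$delta_si_range[1L], 3), ", ",
        round(x$delta_si_range[2L], 3), "]\n", sep = "")
  }
  invisible(x)
}

#' Screening rule for differential splicing candidates
#'
#' The printed selection rule applied per event and contrast: total junction
#' reads at least \code{t_reads} (boundary included), |dSI| at least
#' \code{t_dsi} (boundary included; compared with a 1e-9 epsilon so
#' integer-count ratios sitting exactly on the boundary, such as
#' \code{60/100 - 50/100}, behave per the printed inequality), and FDR
#' strictly below \code{t_fdr} (boundary excluded).
#'
#' @param total_junction_reads,delta_si,fdr Per-event statistics (vectors).
#' @param t_reads,t_dsi,t_fdr Thresholds (defaults 15, 0.10, 0.2).
#' @return Logical vector.
#' @export
passes_splicing_filters <- function(total_junction_reads, delta_si, fdr,
                                    t_reads = 15, t_dsi = 0.10, t_fdr = 0.2) {
  total_junction_reads >= t_reads &
    abs(delta_si) >= t_dsi - 1e-9 &
    fdr < t_fdr
}

sign0 <- function(x) ifelse(is.na(x), 0, sign(x))

#' Join knockdown and overexpression contrasts bidirectionally
#'
#' A splicing change is called high-confidence only when silencing and
#' overexpressing the regulator move the event in opposite directions. In
#' \code{strict} mode every supplied knockdown and every supplied
#' overexpression contrast must pass the per-contrast filters and all
#' knockdown dSI values must share one sign opposite to all overexpression
#' dSI values. In \code{relaxed} mode at least one (KD, OE) pair must be
#' opposite-signed with both members passing — the variant used to build the
#' motif-analysis positive set. Events with dSI exactly zero are never
#' called. Supplying one \code{contrast_result} per replicate implements the
#' "all replicates must agree in sign" reading of strict mode.
#'
#' @param kd,oe A \code{contrast_result} or list of them (knockdown /
#'   overexpression arms).
#' @param mode \code{"strict"} or \code{"relaxed"}.
#' @return A \code{bidirectional_calls} data.frame with one row per called
#'   event: per-side dSI and FDR values (semicolon-joined when several
#'   contrasts), and \code{pairs}, the KD|OE contrast pairs satisfying the
#'   rule.
#' @export
join_bidirectional <- function(kd, oe, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  as_list <- function(x) if (inherits(x, "contrast_result")) list(x) else x
  kd <- as_list(kd); oe <- as_list(oe)
  if (!length(kd) || !length(oe)) {
    stop("at least one knockdown and one overexpression contrast required")
  }
  stopifnot(all(vapply(c(kd, oe), inherits, logical(1L), "contrast_result")))

  ids <- sort(unique(unlist(lapply(c(kd, oe), `[[`, "event_id"))))
  get <- function(res, field) {
    v <- res[[field]][match(ids, res$event_id)]
    v
  }
  kd_delta <- sapply(kd, get, "delta_si"); dim(kd_delta) <- c(length(ids), length(kd))
  oe_delta <- sapply(oe, get, "delta_si"); dim(oe_delta) <- c(length(ids), length(oe))
  kd_pass <- sapply(kd, get, "passes_filters"); dim(kd_pass) <- dim(kd_delta)
  oe_pass <- sapply(oe, get, "passes_filters"); dim(oe_pass) <- dim(oe_delta)
  kd_fdr <- sapply(kd, get, "fdr"); dim(kd_fdr) <- dim(kd_delta)
  oe_fdr <- sapply(oe, get, "fdr"); dim(oe_fdr) <- dim(oe_delta)
  kd_pass[is.na(kd_pass)] <- FALSE; oe_pass[is.na(oe_pass)] <- FALSE
  kd_ids <- vapply(kd, function(r) r$contrast_id[1L], character(1L))
  oe_ids <- vapply(oe, function(r) r$contrast_id[1L], character(1L))

  called <- logical(length(ids))
  pairs <- character(length(ids))
  for (i in seq_along(ids)) {
    ks <- sign0(kd_delta[i, ]); os <- sign0(oe_delta[i, ])
    if (mode == "strict") {
      ok <- all(kd_pass[i, ]) && all(oe_pass[i, ]) &&
        length(unique(ks)) == 1L && ks[1L] != 0 &&
        length(unique(os)) == 1L && os[1L] == -ks[1L]
      if (ok) {
        called[i] <- TRUE
        pairs[i] <- paste(as.vector(outer(kd_ids, oe_ids, paste, sep = "|")),
                          collapse = ";")
      }
    } else {
      hits <- character(0)
      for (a in seq_along(kd)) for (b in seq_along(oe)) {
        if (kd_pass[i, a] && oe_pass[i, b] && ks[a] != 0 && os[b] == -ks[a]) {
          hits <- c(hits, paste(kd_ids[a], oe_ids[b], sep = "|"))
        }
      }
      if (length(hits)) {
        called[i] <- TRUE
        pairs[i] <- paste(hits, collapse = ";")
      }
    }
  }

  sel <- which(called)
  joinnum <- function(m, rows) apply(m[rows, , drop = FALSE], 1L, function(v)
    paste(format(v, digits = 6L, trim = TRUE), collapse = ";"))
  out <- data.frame(
    event_id = ids[sel],
    kd_delta_si = if (length(sel)) joinnum(kd_delta, sel) else character(0),
    oe_delta_si = if (length(sel)) joinnum(oe_delta, sel) else character(0),
    kd_fdr = if (length(sel)) joinnum(kd_fdr, sel) else character(0),
    oe_fdr = if (length(sel)) joinnum(oe_fdr, sel) else character(0),
    direction_consistent = rep(TRUE, length(sel)),
    mode = rep(mode, length(sel)),
    pairs = pairs[sel],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_candidates") <- length(ids)
  class(out) <- c("bidirectional_calls", "data.frame")
  out
}

#' @export
print.bidirectional_calls <- function(x, ...) {
  cat("bidirectional_calls (", if (nrow(x)) x$mode[1L] else "-", " mode): ",
      nrow(x), " high-confidence event(s) of ",
      attr(x, "n_candidates") %||% NA, " candidates\n", sep = "")
  invisible(x)
}

#' Write a contrast result or call table to TSV
#'
#' @param x A \code{contrast_result} or \code{bidirectional_calls} object.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(format_num_df(as.data.frame(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
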