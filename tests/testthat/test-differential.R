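test_that("Fisher two-sided p matches hand-enumerable tables", {
  # margins (5,5,5,5): 6 admissible tables, the two extremes each 1/252
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  # the modal symmetric table sums everything
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2, byrow = TRUE)), 1)
  # an asymmetric table against the enumeration oracle
  expect_equal(fisher_exact_2x2(matrix(c(12, 3, 4, 11), 2, byrow = TRUE)),
               fisher_oracle(12, 3, 4, 11), tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("Fisher rejects malformed tables", {
  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3, -1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "margin")
})

test_that("BH adjustment matches the hand-computed step-up and a reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    # monotone transform: order of distinct p-values preserved
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("contrast calls compute delta SI, pooled Fisher p and joint FDR", {
  qt <- rbind(toy_quant("e1", 60, 40, "t_rep1"), toy_quant("e1", 30, 20, "t_rep2"),
              toy_quant("e2", 10, 90, "t_rep1"), toy_quant("e2", 12, 88, "t_rep2"))
  qc <- rbind(toy_quant("e1", 50, 50, "c_rep1"), toy_quant("e1", 25, 25, "c_rep2"),
              toy_quant("e2", 11, 89, "c_rep1"), toy_quant("e2", 10, 90, "c_rep2"))
  res <- call_contrast(qt, qc, "toy")
  expect_s3_class(res, "contrast_result")
  e1 <- res[res$event_id == "e1", ]
  # replicates pooled by summation: 90/60 vs 75/75
  expect_equal(e1$inclusion_t, 90)
  expect_equal(e1$skipping_t, 60)
  expect_equal(e1$delta_si, 90 / 150 - 75 / 150)
  expect_equal(e1$p_value,
               fisher_oracle(90, 60, 75, 75), tolerance = 1e-12)
  expect_equal(e1$total_junction_reads, 150)
  # FDR joint across the contrast's tested events
  expect_equal(res$fdr, bh_reference(res$p_value), tolerance = 1e-12)
})

test_that("swapping treatment and control negates delta SI and keeps p", {
  qt <- rbind(toy_quant("e1", 70, 30), toy_quant("e2", 20, 80))
  qc <- rbind(toy_quant("e1", 40, 60), toy_quant("e2", 25, 75))
  ab <- call_contrast(qt, qc, "fwd")
  ba <- call_contrast(qc, qt, "rev")
  expect_equal(ab$delta_si, -ba$delta_si)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("events with zero coverage in one arm are excluded from testing", {
  qt <- toy_quant(c("e1", "e2"), c(50, 0), c(50, 0))
  qc <- toy_quant(c("e1", "e2"), c(40, 30), c(60, 30))
  res <- call_contrast(qt, qc, "t")
  expect_false(res$tested[res$event_id == "e2"])
  expect_false(res$passes_filters[res$event_id == "e2"])
  expect_true(is.na(res$p_value[res$event_id == "e2"]))
})

test_that("the printed screening thresholds behave per their inequalities", {
  # read-total boundary: 14 excluded, 15 eligible
  expect_false(passes_splicing_filters(14, 0.5, 0.01))
  expect_true(passes_splicing_filters(15, 0.5, 0.01))
  # |dSI| boundary: 0.099 excluded, 0.100 eligible
  expect_false(passes_splicing_filters(100, 0.099, 0.01))
  expect_true(passes_splicing_filters(100, 0.100, 0.01))
  expect_true(passes_splicing_filters(100, -0.100, 0.01))
  # the boundary reached through integer-count ratios also passes
  expect_true(passes_splicing_filters(100, 60 / 100 - 50 / 100, 0.01))
  # FDR boundary: 0.2 excluded (strict <), 0.199 eligible
  expect_false(passes_splicing_filters(100, 0.5, 0.2))
  expect_true(passes_splicing_filters(100, 0.5, 0.199))
})

test_that("threshold boundaries propagate through call_contrast", {
  # arm totals (14, 30): the min rule fails the read filter regardless of p
  res <- call_contrast(toy_quant("e1", 14, 0), toy_quant("e1", 0, 30), "t")
  expect_equal(res$total_junction_reads, 14)
  expect_false(res$passes_filters)
  # same shape with 15 in the weak arm is eligible (p/FDR permitting)
  res2 <- call_contrast(toy_quant("e1", 15, 0), toy_quant("e1", 0, 30), "t")
  expect_equal(res2$total_junction_reads, 15)
  expect_true(res2$passes_filters)
  # delta exactly at 10 percentage points via integer counts
  res3 <- call_contrast(toy_quant("e1", 600, 400), toy_quant("e1", 500, 500), "t")
  expect_true(res3$passes_filters)
  res4 <- call_contrast(toy_quant("e1", 599, 401), toy_quant("e1", 500, 500), "t")
  expect_false(res4$passes_filters)  # |dSI| = 0.099
  # the sum rule admits events the min rule rejects
  res5 <- call_contrast(toy_quant("e1", 10, 0), toy_quant("e1", 0, 30), "t",
                        total_rule = "sum")
  expect_equal(res5$total_junction_reads, 40)
})

test_that("bidirectional join enforces opposite signs per mode", {
  mk <- function(id, delta, pass, cid) {
    df <- data.frame(event_id = id, event_type = "cassette_exon",
                     contrast_id = cid, inclusion_t = 50, skipping_t = 50,
                     inclusion_c = 50, skipping_c = 50,
                     si_treatment = 0.5 + delta, si_control = 0.5,
                     delta_si = delta, total_junction_reads = 100,
                     p_value = 0.001, fdr = 0.001, tested = TRUE,
                     passes_filters = pass, stringsAsFactors = FALSE)
    class(df) <- c("contrast_result", "data.frame")
    df
  }
  # opposite signs, both passing -> called in strict mode
  calls <- join_bidirectional(mk("e1", 0.12, TRUE, "kd"),
                              mk("e1", -0.15, TRUE, "oe"), mode = "strict")
  expect_equal(calls$event_id, "e1")
  expect_true(calls$direction_consistent)
  expect_equal(calls$pairs, "kd|oe")
  # same sign -> not called
  expect_equal(nrow(join_bidirectional(mk("e1", 0.12, TRUE, "kd"),
                                       mk("e1", 0.20, TRUE, "oe"),
                                       mode = "strict")), 0L)
  # zero delta has no sign -> never called
  expect_equal(nrow(join_bidirectional(mk("e1", 0, TRUE, "kd"),
                                       mk("e1", -0.2, TRUE, "oe"),
                                       mode = "relaxed")), 0L)
  # strict requires every contrast to pass; relaxed needs one opposite pair
  kd2 <- list(mk("e1", 0.12, TRUE, "kd1"), mk("e1", 0.10, FALSE, "kd2"))
  oe1 <- mk("e1", -0.15, TRUE, "oe")
  expect_equal(nrow(join_bidirectional(kd2, oe1, mode = "strict")), 0L)
  rel <- join_bidirectional(kd2, oe1, mode = "relaxed")
  expect_equal(rel$event_id, "e1")
  expect_equal(rel$pairs, "kd1|oe")
  # unknown mode and empty sides are argument errors
  expect_error(join_bidirectional(mk("e1", 0.1, TRUE, "kd"),
                                  mk("e1", -0.1, TRUE, "oe"), mode = "odd"))
  expect_error(join_bidirectional(list(), mk("e1", -0.1, TRUE, "oe")),
               "at least one")
})
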