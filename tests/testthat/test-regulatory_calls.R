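test_that("the call rule combines the fold-change band and significance", {
  # identical replicate vectors: no effect, no call
  same <- call_regulatory(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_equal(same$fc, 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$call, "none")

  # halved activity: call down, p equal to the hand-computed pooled t-test
  risk <- c(0.5, 0.52, 0.48); prot <- c(1.0, 1.02, 0.98)
  res <- call_regulatory(risk, prot)
  expect_equal(res$fc, 0.5)
  expect_equal(res$call, "down")
  sp2 <- (2 * stats::var(risk) + 2 * stats::var(prot)) / 4
  t_hand <- (mean(risk) - mean(prot)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(res$t, t_hand)
  expect_equal(res$p_value, p_hand)

  # fold change below the band but not significant: no call
  risk <- c(0.3, 1.28); prot <- c(0.7, 1.3)
  res <- call_regulatory(risk, prot)
  expect_lt(res$fc, 0.8)
  expect_gt(res$p_value, 0.05)
  expect_equal(res$call, "none")

  expect_error(call_regulatory(1, c(1, 2)), "2 replicates")
  expect_error(call_regulatory(c(1, -2, 3), c(1, 2, 3)), "> 0")
})

test_that("swapping alleles inverts the fold change and keeps p", {
  set.seed(77)
  for (k in 1:20) {
    a <- stats::rlnorm(3, 0, 0.3)
    b <- stats::rlnorm(3, 0, 0.3)
    fwd <- call_regulatory(a, b)
    rev <- call_regulatory(b, a)
    expect_equal(rev$fc, 1 / fwd$fc)
    expect_equal(rev$log2fc, -fwd$log2fc)
    expect_equal(rev$p_value, fwd$p_value)
  }
})

test_that("Welch association matches the textbook formula", {
  same <- welch_association(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  res <- welch_association(list(TT = c(1, 2, 3), CC = c(4, 5, 6)))
  v1 <- stats::var(c(1, 2, 3)) / 3; v2 <- stats::var(c(4, 5, 6)) / 3
  t_hand <- (2 - 5) / sqrt(v1 + v2)
  df_hand <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df_hand))

  # Welch-Satterthwaite df is smaller than the pooled df
  g1 <- c(0.9, 1.1); g2 <- c(0, 2, 4, 6)
  res <- welch_association(list(a = g1, b = g2))
  expect_lt(res$df, length(g1) + length(g2) - 2)

  three <- welch_association(list(AA = c(1, 2), AB = c(2, 3), BB = c(4, 5)))
  expect_equal(nrow(three), 3)
  expect_error(welch_association(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("the fold-change matrix reshapes calls with a significance mask", {
  calls <- data.frame(
    rsid = c("rs1", "rs1", "rs2", "rs2"),
    cell_line = c("L1", "L2", "L1", "L2"),
    fc = c(1, 0.5, 2, NA), log2fc = c(0, -1, 1, NA),
    t = c(0, -5, 5, NA), p_value = c(1, 0.01, 0.01, NA),
    call = c("none", "down", "up", NA), n_risk = 3, n_prot = 3,
    stringsAsFactors = FALSE)
  m <- fc_matrix(calls)
  expect_equal(m["rs1", "L1"], 0)
  expect_equal(m["rs1", "L2"], -1)
  expect_true(is.na(m["rs2", "L2"]))
  sig <- attr(m, "significant")
  expect_false(sig["rs1", "L1"])
  expect_true(sig["rs1", "L2"])
  expect_error(fc_matrix(rbind(calls, calls[1, ])), "duplicate")
})

test_that("a simulated halved risk allele is recovered across cell lines", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(5)))
  target_rs <- "rsTST001"
  risk_id <- cons$construct_id[cons$rsid_or_control == target_rs &
                                 cons$allele_role == "risk"]
  truth <- simulation_truth(setNames(0.5, risk_id), depth = 1e5, seed = 55)
  tab <- simulate_counts(cons, truth, cell_lines = c("MCF7", "T47D",
                                                     "BT-474"))
  act <- normalize_activity(tab)
  calls <- call_regulatory_all(act, cons)
  m <- fc_matrix(calls)
  expect_true(all(abs(m[target_rs, ] - (-1)) < 0.25))
  other <- setdiff(rownames(m), target_rs)
  expect_true(all(abs(m[other, ]) < 0.25))
  expect_true(all(calls$call[calls$rsid == target_rs] == "down"))
})

test_that("low-input alleles yield masked calls rather than errors", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(2)))
  truth <- simulation_truth(depth = 1e4, seed = 3)
  tab <- simulate_counts(cons, truth, cell_lines = "MCF7")
  # starve one allele's plasmid input below the filter
  cts <- tab$counts
  starved <- cons$construct_id[1]
  cts[starved, "plasmid"] <- 2L
  act <- normalize_activity(count_table(cts, tab$samples))
  calls <- call_regulatory_all(act, cons)
  starved_rs <- cons$rsid_or_control[1]
  expect_true(is.na(calls$call[calls$rsid == starved_rs]))
  expect_false(anyNA(calls$call[calls$rsid != starved_rs]))
})

test_that("a halved risk allele is detected in at least 95% of repeats", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(3)))
  risk_id <- cons$construct_id[cons$rsid_or_control == "rsTST001" &
                                 cons$allele_role == "risk"]
  hits <- vapply(seq_len(200), function(s) {
    truth <- simulation_truth(setNames(0.5, risk_id), depth = 1e5,
                              replicates = 3, seed = 5000 + s)
    act <- normalize_activity(simulate_counts(cons, truth,
                                              cell_lines = "MCF7"))
    calls <- call_regulatory_all(act, cons)
    calls$call[calls$rsid == "rsTST001"] == "down"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
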