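test_that("truth declaration enforces its invariants", {
  expect_error(simulation_truth(c(0.5)), "named")
  expect_error(simulation_truth(c(a = -1)), "> 0")
  expect_error(simulation_truth(replicates = 1), "2 replicates")
  expect_error(simulation_truth(read_error_rate = 0.2), "0.1")
  expect_warning(simulation_truth(depth = 0), "zero")
  expect_error(trace_truth(1.5), "\\[0, 1\\]")
})

test_that("count simulation is seeded, proportional and conserves structure", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(4)))
  truth <- simulation_truth(depth = 1e5, dispersion = 0.001, seed = 5)
  a <- simulate_counts(cons, truth, cell_lines = c("MCF7", "T47D"))
  b <- simulate_counts(cons, truth, cell_lines = c("MCF7", "T47D"))
  expect_identical(a$counts, b$counts)
  expect_equal(dim(a$counts), c(9, 7))
  expect_equal(sum(a$samples$material == "plasmid"), 1)

  # all multipliers 1: cDNA/plasmid proportion ratios near 1
  prop <- sweep(a$counts, 2, colSums(a$counts), "/")
  ratio <- prop[, -1] / prop[, 1]
  expect_true(all(abs(ratio - 1) < 0.2))

  # multiplier 2 at high depth, Poisson limit: mean ratio within 5% of 2
  target <- cons$construct_id[1]
  t2 <- simulation_truth(setNames(2, target), depth = 1e6, dispersion = 0,
                         seed = 6)
  tab <- simulate_counts(cons, t2, cell_lines = "MCF7")
  prop <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  # ratio of target vs the mean ratio of unperturbed constructs
  r <- prop[, -1, drop = FALSE] / prop[, 1]
  rel <- mean(r[target, ]) / mean(r[cons$construct_id != target &
                                      cons$allele_role != "control", ])
  expect_lt(abs(rel - 2) / 2, 0.05)

  # zero depth: all-zero cDNA, flagged by a warning
  t0 <- suppressWarnings(simulation_truth(depth = 0, seed = 1))
  expect_warning(z <- simulate_counts(cons, t0, cell_lines = "MCF7"),
                 "zero")
  expect_true(all(z$counts[, -1] == 0))
})

test_that("rendered FASTQ conserves read counts and is reproducible", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(2)))
  truth <- simulation_truth(depth = 500, read_error_rate = 0.01, seed = 9)
  tab <- simulate_counts(cons, truth, cell_lines = "MCF7")
  d <- tempfile(); dir.create(d)
  r1 <- file.path(d, "s_R1.fq"); r2 <- file.path(d, "s_R2.fq")
  n <- render_fastq(tab, cons, "MCF7_rep1", r1, r2, truth)
  expect_equal(n, sum(tab$counts[, "MCF7_rep1"]))
  reads <- Biostrings::readDNAStringSet(r1, format = "fastq")
  expect_equal(length(reads), n)
  arch <- dirseq_architecture()
  expect_true(all(Biostrings::width(reads) ==
                    nchar(arch$upstream_anchor) + 8 +
                    nchar(arch$downstream_anchor)))
  # same seed, same bytes
  r1b <- file.path(d, "b_R1.fq"); r2b <- file.path(d, "b_R2.fq")
  render_fastq(tab, cons, "MCF7_rep1", r1b, r2b, truth)
  expect_identical(unname(tools::md5sum(r1)), unname(tools::md5sum(r1b)))
  expect_identical(unname(tools::md5sum(r2)), unname(tools::md5sum(r2b)))
})

test_that("Ct simulation follows the efficiency model and recovers ratios", {
  design <- data.frame(sample = c("cal", "s"), amplicon = "GENE",
                       role = "target", quantity = c(1, 0.5))
  cts <- simulate_ct_table(design, noise_sd = 0, seed = 1)
  m <- tapply(cts$ct, cts$sample, mean)
  # halving the template costs exactly one cycle at efficiency 2
  expect_equal(unname(m["s"] - m["cal"]), 1)

  # Monte-Carlo recovery of a true ratio under noise
  full <- data.frame(sample = rep(c("cal", "s"), each = 2),
                     amplicon = rep(c("GENE", "REF"), 2),
                     role = rep(c("target", "reference"), 2),
                     quantity = c(1, 1, 0.7, 1))
  rqs <- vapply(seq_len(100), function(k) {
    tab <- simulate_ct_table(full, noise_sd = 0.2, seed = 2000 + k)
    ddct(tab, "GENE", "REF", calibrator = "cal")$rq[2]
  }, numeric(1))
  expect_lt(abs(mean(rqs) - 0.7) / 0.7, 0.05)
})

test_that("trace simulation hits requested fractions and round-trips disk", {
  tr <- simulate_trace(trace_truth(1, noise_sd = 0), "CCTCC", 3,
                       c("G", "A"))
  q <- allele_ratio(tr, 3, c("G", "A"))
  expect_equal(unname(q$ratios), c(1, 0))

  tr <- simulate_trace(trace_truth(0.5, noise_sd = 0), "CCTCC", 3,
                       c("G", "A"))
  q <- allele_ratio(tr, 3, c("G", "A"))
  expect_equal(unname(q$ratios), c(0.5, 0.5), tolerance = 1e-10)

  # columnar text format round trip
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$called_positions, tr$called_positions)
  expect_equal(back$called_sequence, tr$called_sequence)
  expect_equal(back$channels, tr$channels, tolerance = 1e-12)
})
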