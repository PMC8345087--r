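arch <- dirseq_architecture()
fragment_of <- function(cons, i) {
  paste0(arch$upstream_anchor, cons$sublib_tag[i], cons$barcode[i],
         arch$downstream_anchor)
}
revcomp <- function(x) vapply(x, function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
  character(1), USE.NAMES = FALSE)

test_that("pair merging recovers fragments and discards the irreconcilable", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(2)))
  frag <- fragment_of(cons, 1)
  res <- merge_pairs(frag, revcomp(frag))
  expect_equal(res$merged, frag)
  expect_equal(res$report$merged, 1)

  # mates from different fragments cannot be reconciled
  other <- paste(rep("A", nchar(frag)), collapse = "")
  res <- merge_pairs(frag, revcomp(other))
  expect_equal(length(res$merged), 0)
  expect_equal(res$report$discarded_no_overlap +
                 res$report$discarded_tie, 1)
  expect_equal(res$report$total, 1)

  expect_error(merge_pairs(c(frag, frag), revcomp(frag)), "out of step")
})

test_that("merge rate under sequencing error matches the binomial model", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(3)))
  truth <- simulation_truth(depth = 1000, read_error_rate = 0.005,
                            seed = 21)
  tab <- simulate_counts(cons, truth, cell_lines = "MCF7")
  d <- tempfile(); dir.create(d)
  r1 <- file.path(d, "R1.fq"); r2 <- file.path(d, "R2.fq")
  n <- render_fastq(tab, cons, "MCF7_rep1", r1, r2, truth)
  res <- merge_pairs(r1, r2, min_overlap = 20, max_mismatch = 2)
  # mates disagree at a position if exactly one mate erred, or both erred
  # to different bases; the pair merges if <= 2 such positions
  e <- truth$read_error_rate
  p_mm <- 2 * e * (1 - e) + e^2 * (2 / 3)
  L <- nchar(fragment_of(cons, 1))
  expected <- stats::pbinom(2, L, p_mm)
  expect_lt(abs(res$report$merged / n - expected), 0.02)
})

test_that("demultiplexing matches hand counts and conserves reads", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(2)))
  # hand-written reads: 3x construct 1, 2x construct 4, one mutated
  # barcode, one mangled anchor, one short fragment
  reads <- c(rep(fragment_of(cons, 1), 3), rep(fragment_of(cons, 4), 2))
  mut_bc <- fragment_of(cons, 2)
  bc_pos <- nchar(arch$upstream_anchor) + 7
  substr(mut_bc, bc_pos, bc_pos) <- setdiff(c("A", "C", "G", "T"),
    c(substr(mut_bc, bc_pos, bc_pos),
      cons$barcode))[1] # base making an unknown (tag, barcode) pair
  bad_anchor <- fragment_of(cons, 3)
  substr(bad_anchor, 1, 5) <- "GGGGG"
  reads <- c(reads, mut_bc, bad_anchor, "ACGT")
  res <- demultiplex_count(reads, cons)
  expect_equal(unname(res$counts[cons$construct_id[1]]), 3L)
  expect_equal(unname(res$counts[cons$construct_id[4]]), 2L)
  expect_equal(sum(res$counts) + res$unassigned, length(reads))
  expect_equal(res$unassigned, 3L)
  expect_error(demultiplex_count(reads, cons[0, ]), "empty construct")
})

test_that("demultiplexer agrees with the brute-force oracle under errors", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(3)))
  truth <- simulation_truth(depth = 2000, read_error_rate = 0.02,
                            seed = 31)
  tab <- simulate_counts(cons, truth, cell_lines = "MCF7")
  d <- tempfile(); dir.create(d)
  r1 <- file.path(d, "R1.fq"); r2 <- file.path(d, "R2.fq")
  render_fastq(tab, cons, "MCF7_rep1", r1, r2, truth)
  merged <- merge_pairs(r1, r2)$merged
  fast <- demultiplex_count(merged, cons)
  slow <- oracle_demux(merged, cons)
  expect_identical(fast$counts, slow$counts)
  expect_identical(fast$unassigned, slow$unassigned)
})

test_that("error-free reads round-trip to the exact simulated counts", {
  cons <- build_constructs(load_snp_manifest(tiny_manifest(3)))
  truth <- simulation_truth(depth = 5000, read_error_rate = 0, seed = 41)
  tab <- simulate_counts(cons, truth, cell_lines = "MCF7")
  d <- tempfile(); dir.create(d)
  r1 <- file.path(d, "R1.fq"); r2 <- file.path(d, "R2.fq")
  render_fastq(tab, cons, "MCF7_rep2", r1, r2, truth)
  q <- quantify_sample(r1, r2, cons)
  expect_identical(unname(q$counts[rownames(tab$counts)]),
                   unname(tab$counts[, "MCF7_rep2"]))
  expect_equal(q$unassigned, 0L)
})

test_that("activity normalization scales the control to exactly 1", {
  cts <- matrix(c(20, 20, 20, 10, 20, 40, 30, 60, 120), ncol = 3,
                dimnames = list(c("ctrl", "a", "b"),
                                c("plasmid", "s1", "s2")))
  tab <- toy_counts(cts)
  act <- normalize_activity(tab, control_id = "ctrl", min_input_count = 1)
  # cpm factors cancel: counts 10/20/40 over equal plasmid, control first
  expect_equal(unname(act$activity[, "s1"]), c(1, 2, 4))
  expect_equal(unname(act$activity[, "s2"]), c(1, 2, 4))
  expect_true(all(act$activity["ctrl", ] == 1))

  # scale invariance: scaling one sample's counts leaves activities alone
  cts2 <- cts; cts2[, "s1"] <- cts2[, "s1"] * 7L
  act2 <- normalize_activity(toy_counts(cts2), control_id = "ctrl",
                             min_input_count = 1)
  expect_equal(act2$activity, act$activity)

  # low-input constructs are excluded, not guessed at
  cts3 <- cts; cts3["b", "plasmid"] <- 3L
  act3 <- normalize_activity(toy_counts(cts3), control_id = "ctrl",
                             min_input_count = 10)
  expect_equal(unname(act3$flags["b"]), "low_input")
  expect_true(all(is.na(act3$activity["b", ])))

  expect_error(normalize_activity(tab, control_id = "nope"), "absent")
  cts4 <- cts; cts4["ctrl", "plasmid"] <- 0L
  expect_error(normalize_activity(toy_counts(cts4), control_id = "ctrl"),
               "zero plasmid")
})
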