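# Fixtures are built in code; nothing here reads files outside tempdir().

bundled_manifest <- function() {
  system.file("extdata", "snp_manifest_synthetic.tsv", package = "dirseq")
}

# write a small synthetic manifest with n SNPs; deterministic in `seed`
tiny_manifest <- function(n = 3, seed = 11, path = tempfile(fileext = ".tsv")) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n), function(i) {
    al <- sample(nt, 2)
    ctx <- paste(sample(nt, 61, replace = TRUE), collapse = "")
    substr(ctx, 31, 31) <- al[1]
    data.frame(rsid = sprintf("rsTST%03d", i), risk_allele = al[1],
               protective_allele = al[2], context = ctx, snp_offset = 30L,
               source = "test", stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# brute-force demultiplexing oracle: per-read loop over constructs with
# character-by-character anchor comparison
oracle_demux <- function(reads, constructs, max_anchor_mismatch = 2) {
  arch <- dirseq_architecture()
  up <- strsplit(arch$upstream_anchor, "")[[1]]
  ulen <- length(up)
  counts <- setNames(integer(nrow(constructs)), constructs$construct_id)
  unassigned <- 0L
  for (r in reads) {
    if (nchar(r) < ulen + 8) { unassigned <- unassigned + 1L; next }
    head_chars <- strsplit(substr(r, 1, ulen), "")[[1]]
    mm <- sum(head_chars != up)
    key <- substr(r, ulen + 1, ulen + 8)
    hit <- which(paste0(constructs$sublib_tag, constructs$barcode) == key)
    if (mm <= max_anchor_mismatch && length(hit) == 1) {
      counts[hit] <- counts[hit] + 1L
    } else {
      unassigned <- unassigned + 1L
    }
  }
  list(counts = counts, unassigned = unassigned)
}

# independent trapezoid integration written as an explicit loop
oracle_trapezoid <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# make a count table by hand
toy_counts <- function(counts, control_first = TRUE) {
  samples <- data.frame(
    sample = colnames(counts),
    cell_line = c(NA, rep("MCF7", ncol(counts) - 1)),
    replicate = c(NA, seq_len(ncol(counts) - 1)),
    material = c("plasmid", rep("cdna", ncol(counts) - 1)),
    stringsAsFactors = FALSE)
  count_table(counts, samples)
}
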