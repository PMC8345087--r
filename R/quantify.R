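# character matrix of single bases from equal-length strings
.seq_matrix <- function(x) {
  n <- length(x)
  if (n == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  len <- unique(nchar(x))
  stopifnot(length(len) == 1)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = len, byrow = TRUE)
}

#' Merge overlapping read pairs
#'
#' Aligns the reverse complement of mate 2 against mate 1 at every offset
#' providing at least `min_overlap` bases of overlap and counts
#' substitution mismatches in the overlap. A pair merges at the offset with
#' the fewest mismatches provided that count is at most `max_mismatch`; if
#' two offsets tie for the best score the pair is discarded rather than
#' guessed at. In the merged read, overlap positions take mate 1's base.
#'
#' @param r1,r2 FASTQ paths (mates in step), or character vectors of read
#'   sequences (mate 2 as sequenced, i.e. not yet reverse-complemented).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch Maximum substitutions tolerated in the overlap.
#' @return A list with `merged` (character vector of merged reads) and
#'   `report` (totals: `total`, `merged`, `discarded_no_overlap`,
#'   `discarded_tie`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20, max_mismatch = 2) {
  if (length(r1) == 1 && file.exists(r1)) {
    s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
    s2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  } else {
    s1 <- as.character(r1)
    s2 <- as.character(r2)
  }
  if (length(s1) != length(s2))
    .stopf("mate files out of step: %d vs %d reads", length(s1), length(s2))
  n <- length(s1)
  rep0 <- list(total = n, merged = 0L, discarded_no_overlap = 0L,
               discarded_tie = 0L)
  if (n == 0) return(list(merged = character(0), report = rep0))
  s2rc <- .revcomp(s2)
  if (length(unique(nchar(s1))) == 1 && length(unique(nchar(s2rc))) == 1) {
    res <- .merge_block(s1, s2rc, min_overlap, max_mismatch)
  } else {
    # mixed read lengths: process per length pair
    grp <- paste(nchar(s1), nchar(s2rc))
    res <- list(merged = character(n), ok = logical(n), tie = logical(n))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      b <- .merge_block(s1[idx], s2rc[idx], min_overlap, max_mismatch)
      res$merged[idx] <- b$merged
      res$ok[idx] <- b$ok
      res$tie[idx] <- b$tie
    }
  }
  rep0$merged <- sum(res$ok)
  rep0$discarded_tie <- sum(res$tie)
  rep0$discarded_no_overlap <- n - rep0$merged - rep0$discarded_tie
  list(merged = res$merged[res$ok], report = rep0)
}

# vectorized merge for constant-width mate blocks; s2rc already
# reverse-complemented. offset o >= 0: s2rc starts at position o+1 of s1.
.merge_block <- function(s1, s2rc, min_overlap, max_mismatch) {
  n <- length(s1)
  L1 <- nchar(s1[1]); L2 <- nchar(s2rc[1])
  M1 <- .seq_matrix(s1); M2 <- .seq_matrix(s2rc)
  offsets <- seq(-(L2 - min_overlap), L1 - min_overlap)
  mm <- matrix(NA_integer_, nrow = n, ncol = length(offsets))
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    if (o >= 0) {
      ov <- min(L1 - o, L2)
      a <- M1[, (o + 1):(o + ov), drop = FALSE]
      b <- M2[, 1:ov, drop = FALSE]
    } else {
      ov <- min(L2 + o, L1)
      a <- M1[, 1:ov, drop = FALSE]
      b <- M2[, (-o + 1):(-o + ov), drop = FALSE]
    }
    mm[, k] <- as.integer(rowSums(a != b))
  }
  best <- do.call(pmin, as.data.frame(mm))
  nbest <- rowSums(mm == best)
  ok <- best <= max_mismatch & nbest == 1
  tie <- best <= max_mismatch & nbest > 1
  merged <- character(n)
  if (any(ok)) {
    k_best <- max.col(-mm, ties.method = "first")
    o_best <- offsets[k_best]
    w <- which(ok)
    merged[w] <- vapply(w, function(i) {
      o <- o_best[i]
      if (o >= 0) {
        tail_len <- max(0L, (o + L2) - L1)
        if (tail_len > 0)
          paste0(s1[i], substr(s2rc[i], L2 - tail_len + 1, L2))
        else s1[i]
      } else {
        tail_len <- max(0L, (o + L2) - L1)
        paste0(substr(s2rc[i], 1, -o), s1[i],
               if (tail_len > 0)
                 substr(s2rc[i], L2 - tail_len + 1, L2) else "")
      }
    }, character(1))
  }
  list(merged = merged, ok = ok, tie = tie)
}

#' Demultiplex merged reads and count barcodes
#'
#' Assigns each merged read to a construct by its sequence architecture:
#' the upstream anchor must match the read start with at most
#' `max_anchor_mismatch` substitutions, and the 6-nt sub-library tag plus
#' 2-nt dinucleotide barcode that follow must match a construct exactly
#' (the barcode is only two bases, so no mismatch there can be tolerated
#' without changing identity). Anything else — short reads, anchor
#' failures, unknown tag/barcode combinations — lands in the unassigned
#' tally, so assigned + unassigned always equals the number of reads.
#'
#' @param reads Character vector of merged reads.
#' @param constructs Construct table from [build_constructs()].
#' @param max_anchor_mismatch Substitutions tolerated in the upstream
#'   anchor.
#' @return A list with `counts` (named integer vector over construct IDs),
#'   `unassigned`, and `total`.
#' @export
demultiplex_count <- function(reads, constructs, max_anchor_mismatch = 2) {
  if (nrow(constructs) == 0) .stopf("empty construct table")
  up <- .UPSTREAM_ANCHOR
  ulen <- nchar(up)
  key <- paste0(constructs$sublib_tag, constructs$barcode)
  if (anyDuplicated(key))
    .stopf("construct table has duplicated (sublib_tag, barcode) pairs")
  counts <- stats::setNames(integer(nrow(constructs)),
                            constructs$construct_id)
  n <- length(reads)
  if (n == 0) return(list(counts = counts, unassigned = 0L, total = 0L))
  long <- nchar(reads) >= ulen + 8
  idx <- which(long)
  assigned_id <- rep(NA_character_, n)
  if (length(idx) > 0) {
    head_seq <- substr(reads[idx], 1, ulen)
    anchor_chars <- strsplit(up, "")[[1]]
    hm <- .seq_matrix(head_seq)
    mmu <- rowSums(hm != matrix(anchor_chars, nrow = length(idx),
                                ncol = ulen, byrow = TRUE))
    tagbc <- substr(reads[idx], ulen + 1, ulen + 8)
    hit <- match(tagbc, key)
    good <- mmu <= max_anchor_mismatch & !is.na(hit)
    assigned_id[idx[good]] <- constructs$construct_id[hit[good]]
  }
  tab <- table(factor(assigned_id, levels = constructs$construct_id))
  counts[] <- as.integer(tab)
  list(counts = counts, unassigned = as.integer(sum(is.na(assigned_id))),
       total = n)
}

#' Quantify one sample from paired FASTQ
#'
#' Convenience wrapper: [merge_pairs()] then [demultiplex_count()].
#'
#' @inheritParams merge_pairs
#' @inheritParams demultiplex_count
#' @return A list with `counts`, `unassigned`, `total_pairs`, and the merge
#'   `report`.
#' @export
quantify_sample <- function(r1, r2, constructs, min_overlap = 20,
                            max_mismatch = 2, max_anchor_mismatch = 2) {
  m <- merge_pairs(r1, r2, min_overlap, max_mismatch)
  d <- demultiplex_count(m$merged, constructs, max_anchor_mismatch)
  list(counts = d$counts, unassigned = d$unassigned,
       total_pairs = m$report$total, merge_report = m$report)
}

#' Plasmid-normalized reporter activity
#'
#' Converts barcode counts into reporter activities: each column is
#' depth-normalized to counts per million (cpm), each cDNA cpm is divided
#' by the construct's plasmid-input cpm, and each column is then scaled by
#' the same ratio for the negative-control construct — so the control's
#' activity is exactly 1 in every sample by construction. Constructs whose
#' plasmid count falls below `min_input_count` are flagged `low_input` and
#' carry `NA` activities (their cDNA/plasmid ratio would be dominated by
#' input sampling noise).
#'
#' @param counts A `dirseq_counts` table (see [count_table()]).
#' @param control_id Construct ID of the negative control.
#' @param pseudocount Added to every count before cpm; default 0 (a filter,
#'   not smoothing, is the default guard against sparse input).
#' @param min_input_count Minimum plasmid count for a construct to be
#'   quantified.
#' @return An object of class `dirseq_activity`: list with `activity`
#'   (constructs x cDNA samples matrix), `samples` (cDNA sample metadata),
#'   `flags` (per-construct `ok`/`low_input`), `control_id`.
#' @export
#' @examples
#' cts <- matrix(c(20, 20, 20, 10, 20, 40), ncol = 2,
#'               dimnames = list(c("ctrl", "a", "b"), c("plasmid", "s1")))
#' samples <- data.frame(sample = c("plasmid", "s1"),
#'                       cell_line = c(NA, "MCF7"), replicate = c(NA, 1),
#'                       material = c("plasmid", "cdna"))
#' act <- normalize_activity(count_table(cts, samples), control_id = "ctrl",
#'                           min_input_count = 1)
#' act$activity[, "s1"]   # 1, 2, 4
normalize_activity <- function(counts, control_id = .NEG_CONTROL_ID,
                               pseudocount = 0, min_input_count = 10) {
  stopifnot(inherits(counts, "dirseq_counts"))
  cts <- counts$counts + pseudocount
  plasmid_col <- counts$samples$sample[counts$samples$material == "plasmid"]
  cdna_cols <- counts$samples$sample[counts$samples$material == "cdna"]
  if (!(control_id %in% rownames(cts)))
    .stopf("control construct %s absent from count table", control_id)
  cpm <- sweep(cts, 2, colSums(cts), "/") * 1e6
  plasmid_cpm <- cpm[, plasmid_col]
  if (plasmid_cpm[control_id] <= 0)
    .stopf("control construct %s has zero plasmid input", control_id)
  low <- counts$counts[, plasmid_col] < min_input_count
  low[control_id] <- FALSE
  raw <- cpm[, cdna_cols, drop = FALSE] / plasmid_cpm
  act <- sweep(raw, 2, raw[control_id, ], "/")
  act[low, ] <- NA_real_
  flags <- ifelse(low, "low_input", "ok")
  names(flags) <- rownames(cts)
  structure(list(activity = act,
                 samples = counts$samples[counts$samples$material == "cdna", ,
                                          drop = FALSE],
                 flags = flags,
                 control_id = control_id,
                 params = list(pseudocount = pseudocount,
                               min_input_count = min_input_count,
                               depth_normalization = "cpm")),
            class = "dirseq_activity")
}

#' @export
print.dirseq_activity <- function(x, ...) {
  cat(sprintf("dirseq_activity: %d constructs x %d cDNA samples (%d low_input); control %s == 1\n",
              nrow(x$activity), ncol(x$activity),
              sum(x$flags == "low_input"), x$control_id))
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' The matrix and the sample metadata are written side by side as two
#' tab-separated files.
#'
#' @param x A `dirseq_counts` table.
#' @param counts_path,samples_path Output TSV paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(x, counts_path, samples_path) {
  df <- data.frame(construct_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$construct_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  count_table(m, samples)
}
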