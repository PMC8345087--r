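#' Load a SNP design manifest
#'
#' Reads the tab-separated manifest describing the risk SNPs to assay. The
#' file must carry the columns `rsid`, `risk_allele`, `protective_allele`,
#' `context`, `snp_offset` and `source`. `snp_offset` is the 0-based index
#' of the SNP within `context` on disk (the convention of the manifest
#' format); the returned data frame adds `snp_pos`, its 1-based equivalent
#' used by every function in this package.
#'
#' Each record is validated: alleles are upper-cased and must be distinct
#' single nucleotides in A/C/G/T, the context must cover the offset with at
#' least 27 nt of flank on each side (enough for a 55-bp SNP-centered
#' oligo), and rsIDs must be unique.
#'
#' @param path Path to the tab-separated manifest.
#' @return A data frame with one row per SNP and columns `rsid`,
#'   `risk_allele`, `protective_allele`, `context`, `snp_offset`,
#'   `snp_pos`, `source`.
#' @seealso [design_oligo()], [build_constructs()]
#' @export
#' @examples
#' manifest <- system.file("extdata", "snp_manifest_synthetic.tsv", package = "dirseq")
#' snps <- load_snp_manifest(manifest)
#' nrow(snps)
load_snp_manifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("rsid", "risk_allele", "protective_allele", "context",
                "snp_offset", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    .stopf("manifest is missing required column(s): %s",
           paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    .warnf("manifest %s has a header but no data rows", path)
    df$snp_offset <- integer(0)
    df$snp_pos <- integer(0)
    return(df[, c(required[1:5], "snp_pos", "source")])
  }
  df$risk_allele <- toupper(trimws(df$risk_allele))
  df$protective_allele <- toupper(trimws(df$protective_allele))
  df$context <- toupper(trimws(df$context))
  df$snp_offset <- suppressWarnings(as.integer(df$snp_offset))
  validate_snp_records(df)
  df$snp_pos <- df$snp_offset + 1L
  rownames(df) <- NULL
  df[, c("rsid", "risk_allele", "protective_allele", "context",
         "snp_offset", "snp_pos", "source")]
}

#' Validate SNP design records
#'
#' Checks the invariants of a SNP design table: single-nucleotide distinct
#' alleles, in-range SNP offset, at least 27 nt of flank on each side, a
#' context base equal to one of the two alleles, and unique rsIDs. Called by
#' [load_snp_manifest()]; exported so programmatically built tables can be
#' checked too.
#'
#' @param df Data frame with manifest columns (`snp_offset` 0-based).
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_snp_records <- function(df) {
  nt <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    tag <- sprintf("manifest row %d (%s)", i, r$rsid)
    if (is.na(r$rsid) || !nzchar(r$rsid)) .stopf("%s: empty rsid", tag)
    if (!(r$risk_allele %in% nt))
      .stopf("%s: risk_allele %s is not a single A/C/G/T base",
             tag, r$risk_allele)
    if (!(r$protective_allele %in% nt))
      .stopf("%s: protective_allele %s is not a single A/C/G/T base",
             tag, r$protective_allele)
    if (r$risk_allele == r$protective_allele)
      .stopf("%s: risk and protective alleles are identical (%s)",
             tag, r$risk_allele)
    if (is.na(r$snp_offset) || r$snp_offset < 0 ||
        r$snp_offset >= nchar(r$context))
      .stopf("%s: snp_offset out of range for context of length %d",
             tag, nchar(r$context))
    if (r$snp_offset < 27 || nchar(r$context) - r$snp_offset - 1 < 27)
      .stopf("%s: context needs >= 27 nt flanking the SNP on each side", tag)
    ctx_base <- substr(r$context, r$snp_offset + 1, r$snp_offset + 1)
    if (!(ctx_base %in% c(r$risk_allele, r$protective_allele)))
      .stopf("%s: context base %s at the SNP matches neither allele",
             tag, ctx_base)
  }
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup) > 0)
    .stopf("duplicate rsID(s) in manifest: %s",
           paste(unique(dup), collapse = ", "))
  invisible(df)
}

#' Design the 55-bp SNP-centered allele oligo
#'
#' Builds the reporter insert for one allele of one SNP: 27 nt of upstream
#' flank, the allele, and 27 nt of downstream flank, copied verbatim from
#' the manifest context. The allele sits at position 28 of the 55-mer
#' (1-based), i.e. the exact center.
#'
#' @param record A one-row data frame as returned by [load_snp_manifest()].
#' @param allele The allele to place at the center; must be one of the
#'   record's two alleles.
#' @return A 55-character nucleotide string.
#' @export
#' @examples
#' manifest <- system.file("extdata", "snp_manifest_synthetic.tsv", package = "dirseq")
#' snps <- load_snp_manifest(manifest)
#' oligo <- design_oligo(snps[1, ], snps$risk_allele[1])
#' nchar(oligo)
#' substr(oligo, 28, 28)
design_oligo <- function(record, allele) {
  allele <- toupper(allele)
  if (!(allele %in% c(record$risk_allele, record$protective_allele)))
    .stopf("allele %s is neither allele of %s", allele, record$rsid)
  pos <- record$snp_pos
  if (pos - 27 < 1 || pos + 27 > nchar(record$context))
    .stopf("%s: context provides fewer than 27 nt of flank", record$rsid)
  up <- substr(record$context, pos - 27, pos - 1)
  down <- substr(record$context, pos + 1, pos + 27)
  paste0(up, allele, down)
}

#' Build the barcoded construct library
#'
#' Expands validated SNP records into the reporter construct table: one
#' construct per allele (2 per SNP) plus one promoter-only negative control
#' with no insert. Each construct gets a (sub-library tag, dinucleotide
#' barcode) identity assigned deterministically: records are ordered by
#' rsID then allele role (both lexicographic, C locale), the control comes
#' last, and the 16 dinucleotide barcodes (AA, AC, ..., TT) of each
#' sub-library are exhausted before the next sub-library tag is opened.
#' The same manifest therefore always yields byte-identical construct
#' tables.
#'
#' @param records Data frame from [load_snp_manifest()] (may have 0 rows,
#'   in which case only the control construct is returned, with a warning).
#' @return A data frame with columns `construct_id`, `rsid_or_control`,
#'   `allele_role` (`risk`, `protective` or `control`), `allele`,
#'   `insert_seq` (55 nt; empty for the control), `sublib_tag`, `barcode`.
#' @export
#' @examples
#' manifest <- system.file("extdata", "snp_manifest_synthetic.tsv", package = "dirseq")
#' constructs <- build_constructs(load_snp_manifest(manifest))
#' nrow(constructs)            # 2 * 22 + 1
#' length(unique(constructs$sublib_tag))
build_constructs <- function(records) {
  validate_snp_records(records)
  if (nrow(records) == 0)
    .warnf("no SNP records: building a control-only library")
  ord <- order(records$rsid, method = "radix")
  records <- records[ord, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    # allele roles in lexicographic order: protective before risk
    for (role in c("protective", "risk")) {
      allele <- if (role == "risk") r$risk_allele else r$protective_allele
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = paste(r$rsid, role, sep = "_"),
        rsid_or_control = r$rsid,
        allele_role = role,
        allele = allele,
        insert_seq = design_oligo(r, allele),
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    construct_id = .NEG_CONTROL_ID,
    rsid_or_control = .NEG_CONTROL_ID,
    allele_role = "control",
    allele = "",
    insert_seq = "",
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  n <- nrow(out)
  n_sublib <- ceiling(n / 16)
  if (n_sublib > length(.SUBLIB_TAGS))
    .stopf("library needs %d sub-libraries but only %d tags are defined",
           n_sublib, length(.SUBLIB_TAGS))
  idx <- seq_len(n) - 1L
  out$sublib_tag <- .SUBLIB_TAGS[idx %/% 16L + 1L]
  out$barcode <- .DINUCLEOTIDES[idx %% 16L + 1L]
  rownames(out) <- NULL
  out
}

#' Write the construct table and insert FASTA
#'
#' @param constructs Construct table from [build_constructs()].
#' @param tsv_path Where to write the tab-separated construct table.
#' @param fasta_path Optional path for a FASTA of the non-control insert
#'   sequences (names are construct IDs).
#' @return `tsv_path`, invisibly.
#' @export
write_constructs <- function(constructs, tsv_path, fasta_path = NULL) {
  utils::write.table(constructs, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    ins <- constructs[constructs$allele_role != "control", ]
    seqs <- Biostrings::DNAStringSet(ins$insert_seq)
    names(seqs) <- ins$construct_id
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(tsv_path)
}

#' Read a construct table written by [write_constructs()]
#'
#' @param path Tab-separated construct table.
#' @return Construct data frame; errors if the (sub-library tag, barcode)
#'   pairs are not unique.
#' @export
read_constructs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  key <- paste(df$sublib_tag, df$barcode)
  if (anyDuplicated(key))
    .stopf("construct table %s has duplicated (sublib_tag, barcode) pairs",
           path)
  df
}
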