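#' Construct a four-channel chromatogram object
#'
#' Container for a Sanger trace: per-sample fluorescence intensities of
#' the four base channels, the trace-sample index of each called base, and
#' the called base string.
#'
#' @param channels Numeric matrix, one row per trace sample, columns named
#'   `A`, `C`, `G`, `T`.
#' @param called_positions Strictly increasing integer vector of trace-
#'   sample indices (1-based), one per called base.
#' @param called_sequence Base string; one character per called position.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(channels, called_positions, called_sequence) {
  channels <- as.matrix(channels)
  if (!identical(colnames(channels), c("A", "C", "G", "T")))
    .stopf("channels must have columns A, C, G, T")
  called_positions <- as.integer(called_positions)
  if (any(diff(called_positions) <= 0))
    .stopf("called_positions must be strictly increasing")
  if (any(called_positions < 1) || any(called_positions > nrow(channels)))
    .stopf("called_positions outside the trace")
  if (nchar(called_sequence) != length(called_positions))
    .stopf("called_sequence length (%d) != number of called positions (%d)",
           nchar(called_sequence), length(called_positions))
  structure(list(channels = channels, called_positions = called_positions,
                 called_sequence = toupper(called_sequence)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d trace samples, %d called bases (%s%s)\n",
              nrow(x$channels), length(x$called_positions),
              substr(x$called_sequence, 1, 20),
              if (nchar(x$called_sequence) > 20) "..." else ""))
  invisible(x)
}

#' Write / read a chromatogram in the columnar text format
#'
#' The trace is stored as a TSV of `position`, `A`, `C`, `G`, `T`
#' intensities plus a JSON sidecar (`<path>.calls.json`) holding the
#' called positions (1-based) and called sequence.
#'
#' @param x A [chromatogram()].
#' @param path TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  df <- data.frame(position = seq_len(nrow(x$channels)), x$channels,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(called_positions = x$called_positions,
                            called_sequence = x$called_sequence),
                       paste0(path, ".calls.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".calls.json"),
                              simplifyVector = TRUE)
  chromatogram(as.matrix(df[, c("A", "C", "G", "T")]),
               side$called_positions, side$called_sequence)
}

# integration window around a called base: half-width = window_frac x the
# local inter-peak spacing (mean of the distances to the flanking calls)
.peak_window <- function(trace, call_index, window_frac) {
  pos <- trace$called_positions
  n <- length(pos)
  if (call_index < 1 || call_index > n)
    .stopf("call_index %d outside the %d called bases", call_index, n)
  if (n < 2) .stopf("need at least two called bases to estimate spacing")
  gaps <- c(if (call_index > 1) pos[call_index] - pos[call_index - 1],
            if (call_index < n) pos[call_index + 1] - pos[call_index])
  w <- round(window_frac * mean(gaps))
  center <- pos[call_index]
  lo <- center - w
  hi <- center + w
  if (lo < 1 || hi > nrow(trace$channels))
    .stopf("integration window [%d, %d] exceeds the trace edge", lo, hi)
  list(lo = lo, hi = hi, w = w, center = center)
}

#' Under-peak area of one channel at a called base
#'
#' Integrates (trapezoid rule) the channel's intensity over a window of
#' half-width `window_frac` x the local inter-peak spacing, centered on the
#' called position, after subtracting a baseline estimated as the channel's
#' 10th-percentile intensity over a neighborhood five times the window.
#' Negative areas are clipped to zero. `mode = "height"` returns the
#' baseline-subtracted peak maximum instead, as a sensitivity alternative.
#'
#' @param trace A [chromatogram()].
#' @param call_index 1-based index of the called base.
#' @param channel One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param window_frac Window half-width as a fraction of the local
#'   inter-peak spacing, in (0, 1].
#' @param mode `"area"` (default) or `"height"`.
#' @return Nonnegative area (intensity x trace samples) or height.
#' @export
peak_area <- function(trace, call_index, channel, window_frac = 0.5,
                      mode = c("area", "height")) {
  stopifnot(inherits(trace, "chromatogram"))
  mode <- match.arg(mode)
  if (!(channel %in% c("A", "C", "G", "T")))
    .stopf("unknown channel %s", channel)
  if (window_frac <= 0 || window_frac > 1)
    .stopf("window_frac must lie in (0, 1]")
  win <- .peak_window(trace, call_index, window_frac)
  y <- trace$channels[, channel]
  nlo <- max(1, win$center - 5 * win$w)
  nhi <- min(length(y), win$center + 5 * win$w)
  baseline <- stats::quantile(y[nlo:nhi], 0.10, names = FALSE)
  seg <- y[win$lo:win$hi] - baseline
  val <- if (mode == "area") pracma::trapz(win$lo:win$hi, seg) else max(seg)
  max(val, 0)
}

#' Allele ratio from under-peak areas
#'
#' Quantifies both alleles' channels at a heterozygous called position and
#' reports each allele's share of the summed area. The two ratios sum to 1
#' whenever at least one area is positive.
#'
#' @param trace A [chromatogram()].
#' @param call_index 1-based called-base index of the heterozygous site.
#' @param alleles Character vector of the two allele bases.
#' @inheritParams peak_area
#' @return Object of class `allele_quant`: list with `position`,
#'   `allele_areas` (named), `ratios` (named, summing to 1).
#' @export
#' @examples
#' tr <- simulate_trace(trace_truth(0.7, noise_sd = 0), "ACGTGACGT", 5,
#'                      c("G", "A"))
#' allele_ratio(tr, 5, c("G", "A"))$ratios
allele_ratio <- function(trace, call_index, alleles, window_frac = 0.5,
                         mode = c("area", "height")) {
  mode <- match.arg(mode)
  alleles <- toupper(alleles)
  if (length(alleles) != 2 || alleles[1] == alleles[2])
    .stopf("alleles must be two distinct bases")
  if (!all(alleles %in% c("A", "C", "G", "T")))
    .stopf("unknown nucleotide among alleles: %s",
           paste(alleles, collapse = ", "))
  areas <- vapply(alleles, function(b)
    peak_area(trace, call_index, b, window_frac, mode), numeric(1))
  if (sum(areas) <= 0)
    .stopf("both allele areas are zero: allele ratio undefined")
  structure(list(position = call_index,
                 allele_areas = areas,
                 ratios = areas / sum(areas)),
            class = "allele_quant")
}

#' @export
print.allele_quant <- function(x, ...) {
  cat(sprintf("allele_quant at call %d: %s\n", x$position,
              paste(sprintf("%s=%.3f", names(x$ratios), x$ratios),
                    collapse = ", ")))
  invisible(x)
}

#' Allele-specific expression fold from gDNA/cDNA trace pairs
#'
#' Compares one allele's ratio in cDNA against genomic DNA on the odds
#' scale: fold = odds(cDNA) / odds(gDNA) with odds = ratio / (1 - ratio).
#' The gDNA quantification normalizes away assay bias (primer or peak-
#' height asymmetry), so fold = 1 means both alleles are expressed in
#' proportion to their genomic dosage.
#'
#' @param gdna,cdna `allele_quant` objects from [allele_ratio()] at the
#'   same site with the same allele pair.
#' @param allele Which allele's expression bias to report.
#' @return Positive fold (> 1: the allele is over-expressed relative to
#'   its genomic share).
#' @export
#' @examples
#' g <- simulate_trace(trace_truth(0.5, noise_sd = 0), "ACGTGACGT", 5,
#'                     c("G", "A"))
#' c <- simulate_trace(trace_truth(0.8, noise_sd = 0), "ACGTGACGT", 5,
#'                     c("G", "A"))
#' ase_imbalance(allele_ratio(g, 5, c("G", "A")),
#'               allele_ratio(c, 5, c("G", "A")), "G")   # 4
ase_imbalance <- function(gdna, cdna, allele) {
  stopifnot(inherits(gdna, "allele_quant"), inherits(cdna, "allele_quant"))
  allele <- toupper(allele)
  if (!identical(sort(names(gdna$ratios)), sort(names(cdna$ratios))))
    .stopf("gDNA and cDNA quantifications cover different allele pairs")
  if (!(allele %in% names(gdna$ratios)))
    .stopf("allele %s not among the quantified pair", allele)
  rg <- gdna$ratios[[allele]]
  rc <- cdna$ratios[[allele]]
  if (rg <= 0 || rg >= 1)
    .stopf("gDNA ratio for %s is %g: odds undefined, cannot normalize",
           allele, rg)
  odds <- function(r) r / (1 - r)
  unname(odds(rc) / odds(rg))
}
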