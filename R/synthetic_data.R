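# Cell-line panel emulated by the count generator: nine breast cancer lines
# plus two prostate cancer comparator lines.
.DEFAULT_CELL_LINES <- c("MDA-MB-231", "MDA-MB-468", "MDA-MB-453", "BT-549",
                         "BT-20", "T47D", "ZR75-1", "MCF7", "BT-474",
                         "22Rv1", "LNCaP")

# run `code` under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Declare the ground truth for a simulated DiR-seq experiment
#'
#' Bundles and validates the parameters of the count/read generator. The
#' defaults describe the emulated study design: an equimolar 45-construct
#' plasmid pool, triplicate transfections, 1e5 read pairs per sample,
#' mildly overdispersed cDNA counts, and a low per-base substitution error.
#'
#' @param activity_multiplier Named numeric vector of per-construct true
#'   activities (names are construct IDs). Constructs absent from the vector
#'   default to 1; the negative control is always 1.
#' @param replicates cDNA replicates per cell line (biological triplicates
#'   by default).
#' @param depth Expected read (pair) count per sample.
#' @param dispersion Negative-binomial overdispersion of cDNA counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson sampling.
#' @param read_error_rate Per-base substitution probability in simulated
#'   reads; must lie in [0, 0.1).
#' @param plasmid_jitter_sd Standard deviation of the lognormal jitter
#'   applied to the nominally equimolar plasmid proportions.
#' @param seed Integer seed; every artifact generated from this truth is a
#'   deterministic function of it.
#' @return An object of class `simulation_truth`.
#' @export
#' @examples
#' truth <- simulation_truth(c(rs0001_risk = 0.5), depth = 1e4, seed = 7)
#' truth$replicates
simulation_truth <- function(activity_multiplier = numeric(0),
                             replicates = 3,
                             depth = 1e5,
                             dispersion = 0.002,
                             read_error_rate = 0.001,
                             plasmid_jitter_sd = 0.05,
                             seed = 1) {
  if (length(activity_multiplier) > 0 &&
      is.null(names(activity_multiplier)))
    .stopf("activity_multiplier must be named by construct ID")
  if (any(activity_multiplier <= 0))
    .stopf("all activity multipliers must be > 0")
  if (replicates < 2) .stopf("at least 2 replicates are required")
  if (depth < 0) .stopf("depth must be nonnegative")
  if (depth < 1) .warnf("depth < 1: cDNA columns will be all zero")
  if (dispersion < 0) .stopf("dispersion must be >= 0")
  if (read_error_rate < 0 || read_error_rate >= 0.1)
    .stopf("read_error_rate must lie in [0, 0.1)")
  structure(list(activity_multiplier = activity_multiplier,
                 replicates = as.integer(replicates),
                 depth = depth,
                 dispersion = dispersion,
                 read_error_rate = read_error_rate,
                 plasmid_jitter_sd = plasmid_jitter_sd,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Construct a barcode count table
#'
#' A count table couples a constructs x samples integer matrix with its
#' sample metadata: one plasmid-input column and cell-line x replicate cDNA
#' columns.
#'
#' @param counts Integer matrix, rows named by construct ID, columns by
#'   sample name.
#' @param samples Data frame with columns `sample`, `cell_line`,
#'   `replicate`, `material` (`plasmid` or `cdna`), one row per column of
#'   `counts`, in column order.
#' @return An object of class `dirseq_counts`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) .stopf("counts must be nonnegative")
  if (!identical(colnames(counts), samples$sample))
    .stopf("column names of counts must equal samples$sample, in order")
  if (sum(samples$material == "plasmid") != 1)
    .stopf("exactly one plasmid column is required")
  structure(list(counts = counts, samples = samples),
            class = "dirseq_counts")
}

#' @export
print.dirseq_counts <- function(x, ...) {
  cat(sprintf("dirseq_counts: %d constructs x %d samples (%d cDNA, %d plasmid)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$material == "cdna"),
              sum(x$samples$material == "plasmid")))
  invisible(x)
}

#' Simulate plasmid and cDNA barcode counts
#'
#' Draws one plasmid-input column and `replicates` cDNA columns per cell
#' line from the declared truth. The plasmid pool is nominally equimolar
#' with mild lognormal jitter; plasmid counts are multinomial at the
#' requested depth. Each cDNA column is negative-binomial with mean
#' proportional to plasmid proportion x activity multiplier, scaled to the
#' requested depth. A fixed seed gives identical output on every run.
#'
#' @param constructs Construct table from [build_constructs()].
#' @param truth A [simulation_truth()] object.
#' @param cell_lines Character vector of cell-line names; defaults to the
#'   emulated 11-line panel (nine breast, two prostate).
#' @return A [count_table()] (`dirseq_counts`) with attribute
#'   `true_multiplier` (the per-construct truth, control = 1).
#' @export
#' @examples
#' snps <- load_snp_manifest(system.file("extdata", "snp_manifest_synthetic.tsv",
#'                                       package = "dirseq"))
#' constructs <- build_constructs(snps)
#' tab <- simulate_counts(constructs, simulation_truth(depth = 1e4, seed = 1),
#'                        cell_lines = "MCF7")
#' tab
simulate_counts <- function(constructs, truth,
                            cell_lines = .DEFAULT_CELL_LINES) {
  stopifnot(inherits(truth, "simulation_truth"))
  ids <- constructs$construct_id
  n <- length(ids)
  m <- rep(1, n)
  names(m) <- ids
  known <- intersect(names(truth$activity_multiplier), ids)
  m[known] <- truth$activity_multiplier[known]
  m[constructs$allele_role == "control"] <- 1
  .with_seed(truth$seed, {
    p <- exp(stats::rnorm(n, 0, truth$plasmid_jitter_sd))
    p <- p / sum(p)
    plasmid <- as.integer(stats::rmultinom(1, size = round(truth$depth), p))
    w <- p * m
    mu <- truth$depth * w / sum(w)
    cols <- list(plasmid = plasmid)
    meta <- data.frame(sample = "plasmid", cell_line = NA_character_,
                       replicate = NA_integer_, material = "plasmid",
                       stringsAsFactors = FALSE)
    for (cl in cell_lines) {
      for (r in seq_len(truth$replicates)) {
        y <- if (truth$dispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / truth$dispersion)
        } else {
          stats::rpois(n, lambda = mu)
        }
        nm <- sprintf("%s_rep%d", cl, r)
        cols[[nm]] <- as.integer(y)
        meta <- rbind(meta, data.frame(sample = nm, cell_line = cl,
                                       replicate = r, material = "cdna",
                                       stringsAsFactors = FALSE))
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    if (truth$depth < 1) .warnf("depth < 1 produced all-zero cDNA columns")
    out <- count_table(counts, meta)
    attr(out, "true_multiplier") <- m
    out
  })
}

# substitute bases at random positions of a character matrix of single bases
.inject_errors <- function(mat, rate) {
  if (rate <= 0) return(mat)
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit) > 0) {
    pick <- sample.int(3, length(hit), replace = TRUE)
    mat[hit] <- alt[cbind(match(mat[hit], rownames(alt)), pick)]
  }
  mat
}

#' Render a count column as paired-end FASTQ
#'
#' Emits `count`-many read pairs per construct for one sample of a count
#' table. Each fragment is upstream anchor + sub-library tag + dinucleotide
#' barcode + downstream anchor (the reverse complement of the BarP6 RT
#' primer); mate 1 is the fragment, mate 2 its reverse complement, so the
#' pair overlaps fully. Substitution errors are applied independently to
#' each mate at the truth's `read_error_rate`. Qualities are constant
#' Phred+33 'I'.
#'
#' @param counts A `dirseq_counts` table.
#' @param constructs Construct table matching the count rows.
#' @param sample Sample (column) name to render.
#' @param r1_path,r2_path Output FASTQ paths.
#' @param truth A [simulation_truth()]; supplies `read_error_rate`.
#' @param seed Seed for read order and errors; defaults to
#'   `truth$seed + 1L` so reads can be regenerated independently of counts.
#' @return Invisibly, the number of read pairs written.
#' @export
render_fastq <- function(counts, constructs, sample, r1_path, r2_path,
                         truth, seed = truth$seed + 1L) {
  stopifnot(inherits(counts, "dirseq_counts"))
  if (!(sample %in% colnames(counts$counts)))
    .stopf("sample %s not found in count table", sample)
  cnt <- counts$counts[, sample]
  ord <- match(rownames(counts$counts), constructs$construct_id)
  if (anyNA(ord))
    .stopf("count rows missing from construct table")
  frag <- paste0(.UPSTREAM_ANCHOR, constructs$sublib_tag[ord],
                 constructs$barcode[ord], .DOWNSTREAM_ANCHOR)
  reads <- rep(frag, cnt)
  n <- length(reads)
  .with_seed(seed, {
    if (n > 0) reads <- reads[sample.int(n)]
    len <- nchar(.UPSTREAM_ANCHOR) + 8L + nchar(.DOWNSTREAM_ANCHOR)
    m0 <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                 ncol = len, byrow = TRUE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # each mate reads the same template; errors are independent per mate
    m1 <- .inject_errors(m0, truth$read_error_rate)
    m2 <- .inject_errors(matrix(comp[m0[, rev(seq_len(len)), drop = FALSE]],
                                nrow = n), truth$read_error_rate)
    r1 <- apply(m1, 1, paste0, collapse = "")
    r2 <- apply(m2, 1, paste0, collapse = "")
    if (n == 0) r1 <- r2 <- character(0)
    ids <- sprintf("read%07d", seq_len(n))
    qual <- Biostrings::BStringSet(rep(strrep("I", len), n))
    s1 <- Biostrings::DNAStringSet(r1)
    s2 <- Biostrings::DNAStringSet(r2)
    names(s1) <- names(s2) <- ids
    names(qual) <- ids
    Biostrings::writeXStringSet(s1, r1_path, format = "fastq",
                                qualities = qual)
    Biostrings::writeXStringSet(s2, r2_path, format = "fastq",
                                qualities = qual)
  })
  invisible(n)
}

#' Simulate a qPCR Ct table
#'
#' Generates technical-replicate Ct values from true template quantities
#' under the exponential amplification model: Ct = baseline -
#' log_e(quantity) + N(0, noise_sd), with e the amplification efficiency
#' (2 = perfect doubling). A quantity of 1 sits at the baseline Ct; halving
#' the quantity raises Ct by one cycle at e = 2.
#'
#' @param design Data frame with columns `sample`, `amplicon`, `role` and
#'   `quantity` (true relative template amount, > 0).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param replicates Technical replicates per well group.
#' @param baseline_ct Ct corresponding to quantity 1.
#' @param efficiency Amplification efficiency (fold per cycle).
#' @param seed Integer seed.
#' @return A Ct record data frame with columns `sample`, `amplicon`,
#'   `role`, `ct`, `replicate`.
#' @export
#' @examples
#' design <- data.frame(sample = c("ctrl", "kd"), amplicon = "GENE",
#'                      role = "target", quantity = c(1, 0.4))
#' simulate_ct_table(design, noise_sd = 0, seed = 1)
simulate_ct_table <- function(design, noise_sd = 0.2, replicates = 3,
                              baseline_ct = 25, efficiency = 2, seed = 1) {
  req <- c("sample", "amplicon", "role", "quantity")
  if (!all(req %in% names(design)))
    .stopf("design needs columns: %s", paste(req, collapse = ", "))
  if (any(design$quantity <= 0)) .stopf("all quantities must be > 0")
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      mu <- baseline_ct - log(design$quantity[i], base = efficiency)
      data.frame(sample = design$sample[i], amplicon = design$amplicon[i],
                 role = design$role[i],
                 ct = mu + stats::rnorm(replicates, 0, noise_sd),
                 replicate = seq_len(replicates), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Declare the ground truth of a simulated Sanger trace
#'
#' @param allele_fraction Fraction of allele 1 at the heterozygous
#'   position, in [0, 1] (allele 2 gets the complement).
#' @param peak_spacing Trace samples per called base.
#' @param peak_width Gaussian peak standard deviation, in trace samples.
#' @param noise_sd Standard deviation of additive intensity noise, on the
#'   scale of a unit-height peak.
#' @param seed Integer seed.
#' @return An object of class `trace_truth`.
#' @export
trace_truth <- function(allele_fraction = 0.5, peak_spacing = 10,
                        peak_width = 1.5, noise_sd = 0.02, seed = 1) {
  if (allele_fraction < 0 || allele_fraction > 1)
    .stopf("allele_fraction must lie in [0, 1]")
  if (peak_spacing < 4 * peak_width)
    .warnf("peak spacing < 4 x peak width: neighboring peaks will overlap")
  structure(list(allele_fraction = allele_fraction,
                 peak_spacing = peak_spacing,
                 peak_width = peak_width,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trace_truth")
}

#' Simulate a four-channel Sanger chromatogram
#'
#' Renders Gaussian peaks of unit height at regular spacing, one per called
#' base in `sequence`, in the channel of that base. At `het_position` the
#' two `alleles` share the position, with peak heights (hence areas)
#' proportional to the truth's allele fractions. Gaussian noise is added to
#' all channels and intensities are clipped at zero.
#'
#' @param truth A [trace_truth()] object.
#' @param sequence Called base string surrounding the site of interest.
#' @param het_position 1-based index of the heterozygous base within
#'   `sequence`.
#' @param alleles Character vector of the two alleles at `het_position`;
#'   `truth$allele_fraction` applies to the first.
#' @return A [chromatogram()] object.
#' @export
#' @examples
#' tr <- simulate_trace(trace_truth(0.7, noise_sd = 0), "ACGTGACGT", 5,
#'                      c("G", "A"))
#' allele_ratio(tr, 5, c("G", "A"))$ratios
simulate_trace <- function(truth, sequence, het_position,
                           alleles = c("A", "C")) {
  stopifnot(inherits(truth, "trace_truth"))
  bases <- strsplit(toupper(sequence), "")[[1]]
  nb <- length(bases)
  if (het_position < 1 || het_position > nb)
    .stopf("het_position outside the called sequence")
  alleles <- toupper(alleles)
  if (length(alleles) != 2 || alleles[1] == alleles[2])
    .stopf("alleles must be two distinct bases")
  sp <- truth$peak_spacing
  centers <- round(sp * (seq_len(nb) + 0.5))
  len <- round(sp * (nb + 2))
  x <- seq_len(len)
  chan <- matrix(0, nrow = len, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  gauss <- function(center) exp(-(x - center)^2 / (2 * truth$peak_width^2))
  for (i in seq_len(nb)) {
    if (i == het_position) {
      chan[, alleles[1]] <- chan[, alleles[1]] +
        truth$allele_fraction * gauss(centers[i])
      chan[, alleles[2]] <- chan[, alleles[2]] +
        (1 - truth$allele_fraction) * gauss(centers[i])
    } else {
      chan[, bases[i]] <- chan[, bases[i]] + gauss(centers[i])
    }
  }
  # the base caller reports the majority allele at the het site
  called <- bases
  called[het_position] <- if (truth$allele_fraction >= 0.5) alleles[1] else
    alleles[2]
  .with_seed(truth$seed, {
    if (truth$noise_sd > 0)
      chan <- chan + matrix(stats::rnorm(length(chan), 0, truth$noise_sd),
                            nrow = len)
    chan[chan < 0] <- 0
    chromatogram(chan, centers, paste(called, collapse = ""))
  })
}
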