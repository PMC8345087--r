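#' Configuration of the regulatory-SNP call rule
#'
#' A SNP is called regulatory in a cell line when the risk/protective
#' activity fold change leaves the (fc_low, fc_high) band and the
#' two-sample t-test on replicate activities is significant at `alpha`.
#' The defaults are the published rule: fold change < 0.8 or > 1.2 with
#' p < 0.05 from a pooled-variance (Student) t-test on linear activities;
#' a Welch test can be selected for robustness studies.
#'
#' @param fc_low,fc_high Fold-change band limits (0 < fc_low < 1 < fc_high).
#' @param alpha Significance level.
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @return An object of class `call_config`.
#' @export
call_config <- function(fc_low = 0.8, fc_high = 1.2, alpha = 0.05,
                        test = c("student", "welch")) {
  test <- match.arg(test)
  if (!(fc_low > 0 && fc_low < 1 && fc_high > 1))
    .stopf("need 0 < fc_low < 1 < fc_high")
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  structure(list(fc_low = fc_low, fc_high = fc_high, alpha = alpha,
                 test = test), class = "call_config")
}

# two-sample t robust to zero-variance degenerate inputs
.two_sample_t <- function(x, y, var_equal) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf, df = length(x) + length(y) - 2, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Call a regulatory SNP from replicate allele activities
#'
#' Computes the risk/protective fold change from replicate means, tests
#' the difference with a two-tailed two-sample t-test on the linear
#' activities, and applies the call rule of [call_config()]: `down` when
#' fc < fc_low with p < alpha, `up` when fc > fc_high with p < alpha,
#' otherwise `none`.
#'
#' @param risk_acts,prot_acts Numeric vectors of replicate activities
#'   (>= 2 each, all positive).
#' @param cfg A [call_config()].
#' @return A one-row data frame with `fc`, `log2fc`, `t`, `p_value`,
#'   `call`, `n_risk`, `n_prot`.
#' @export
#' @examples
#' call_regulatory(c(0.5, 0.52, 0.48), c(1.0, 1.02, 0.98))$call
call_regulatory <- function(risk_acts, prot_acts, cfg = call_config()) {
  if (length(risk_acts) < 2 || length(prot_acts) < 2)
    .stopf("at least 2 replicates per allele are required")
  if (any(!is.finite(risk_acts)) || any(!is.finite(prot_acts)) ||
      any(risk_acts <= 0) || any(prot_acts <= 0))
    .stopf("activities must be finite and > 0")
  fc <- mean(risk_acts) / mean(prot_acts)
  tt <- .two_sample_t(risk_acts, prot_acts,
                      var_equal = cfg$test == "student")
  call <- if (fc < cfg$fc_low && tt$p < cfg$alpha) "down"
          else if (fc > cfg$fc_high && tt$p < cfg$alpha) "up"
          else "none"
  data.frame(fc = fc, log2fc = log2(fc), t = tt$t, p_value = tt$p,
             call = call, n_risk = length(risk_acts),
             n_prot = length(prot_acts), stringsAsFactors = FALSE)
}

#' Call every SNP in every cell line of an activity table
#'
#' Pairs each SNP's risk and protective constructs, collects their
#' replicate activities per cell line, and applies [call_regulatory()].
#' SNP/cell-line combinations with missing (low-input) activities yield a
#' masked row (`NA` statistics, `NA` call) rather than an error. No
#' multiple-testing correction is applied; `attr(, "n_tests")` reports the
#' number of tests performed so callers can adjust if they wish.
#'
#' @param activity A `dirseq_activity` object from [normalize_activity()].
#' @param constructs Construct table from [build_constructs()].
#' @param cfg A [call_config()].
#' @return Data frame with columns `rsid`, `cell_line`, `fc`, `log2fc`,
#'   `t`, `p_value`, `call`, `n_risk`, `n_prot`.
#' @export
call_regulatory_all <- function(activity, constructs, cfg = call_config()) {
  stopifnot(inherits(activity, "dirseq_activity"))
  alleles <- constructs[constructs$allele_role != "control", ]
  rsids <- sort(unique(alleles$rsid_or_control), method = "radix")
  lines <- unique(activity$samples$cell_line)
  rows <- list()
  for (rs in rsids) {
    risk_id <- alleles$construct_id[alleles$rsid_or_control == rs &
                                      alleles$allele_role == "risk"]
    prot_id <- alleles$construct_id[alleles$rsid_or_control == rs &
                                      alleles$allele_role == "protective"]
    for (cl in lines) {
      cols <- activity$samples$sample[activity$samples$cell_line == cl]
      ra <- activity$activity[risk_id, cols]
      pa <- activity$activity[prot_id, cols]
      if (length(risk_id) != 1 || length(prot_id) != 1 ||
          anyNA(ra) || anyNA(pa) || any(ra <= 0) || any(pa <= 0)) {
        res <- data.frame(fc = NA_real_, log2fc = NA_real_, t = NA_real_,
                          p_value = NA_real_, call = NA_character_,
                          n_risk = NA_integer_, n_prot = NA_integer_,
                          stringsAsFactors = FALSE)
      } else {
        res <- call_regulatory(ra, pa, cfg)
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(rsid = rs, cell_line = cl, stringsAsFactors = FALSE), res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}

#' log2 fold-change matrix across SNPs and cell lines
#'
#' Reshapes a call table into the SNP x cell-line matrix of
#' log2(risk/protective) values, with a logical significance mask (calls
#' other than `none`) attached as `attr(, "significant")`. Missing
#' combinations stay `NA` (masked).
#'
#' @param calls Call table from [call_regulatory_all()].
#' @return Numeric matrix, rows = rsIDs, columns = cell lines.
#' @seealso [plot_fc_matrix()]
#' @export
fc_matrix <- function(calls) {
  keys <- paste(calls$rsid, calls$cell_line)
  if (anyDuplicated(keys))
    .stopf("duplicate (rsid, cell_line) rows in call table")
  rsids <- sort(unique(calls$rsid), method = "radix")
  lines <- unique(calls$cell_line)
  m <- matrix(NA_real_, length(rsids), length(lines),
              dimnames = list(rsids, lines))
  sig <- matrix(FALSE, length(rsids), length(lines),
                dimnames = list(rsids, lines))
  for (i in seq_len(nrow(calls))) {
    m[calls$rsid[i], calls$cell_line[i]] <- calls$log2fc[i]
    sig[calls$rsid[i], calls$cell_line[i]] <-
      !is.na(calls$call[i]) && calls$call[i] != "none"
  }
  attr(m, "significant") <- sig
  m
}

#' Heatmap of the log2 fold-change matrix
#'
#' Renders the [fc_matrix()] as a heatmap with the log2(risk/protective)
#' values annotated, in the style of an MPRA activity summary. Requires
#' the pheatmap package.
#'
#' @param m Matrix from [fc_matrix()].
#' @param filename Optional path to write a PNG.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_fc_matrix <- function(m, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    .stopf("plot_fc_matrix needs the pheatmap package")
  m2 <- m
  m2[is.na(m2)] <- 0
  ph <- pheatmap::pheatmap(m2, cluster_rows = FALSE, cluster_cols = FALSE,
                           display_numbers = round(m2, 2),
                           filename = filename, ...)
  invisible(ph)
}

#' Welch two-sample tests across genotype groups
#'
#' The eQTL-style association test: expression values grouped by genotype
#' are compared with two-tailed two-sample t-tests with Welch's
#' unequal-variance correction. With three genotype groups all three
#' pairwise tests are reported.
#'
#' @param groups Named list of 2 or 3 numeric vectors (expression per
#'   genotype group), each with n >= 2.
#' @return Data frame with `group1`, `group2`, `t`, `df`, `p_value`, one
#'   row per pairwise comparison.
#' @export
#' @examples
#' welch_association(list(TT = c(1, 2, 3), CC = c(4, 5, 6)))
welch_association <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || length(groups) > 3)
    .stopf("groups must be a list of 2 or 3 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    .stopf("every genotype group needs n >= 2 (got %s)",
           paste(ns, collapse = ", "))
  pairs <- utils::combn(names(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- .two_sample_t(groups[[g1]], groups[[g2]], var_equal = FALSE)
    data.frame(group1 = g1, group2 = g2, t = tt$t, df = tt$df,
               p_value = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
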