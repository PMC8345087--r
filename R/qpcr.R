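# All Ct arithmetic assumes exponential amplification with per-cycle fold
# `efficiency` (2 = perfect doubling). Technical replicates are averaged on
# the Ct scale before any delta is taken.

.mean_ct <- function(ct_table, sample, amplicon) {
  v <- ct_table$ct[ct_table$sample == sample & ct_table$amplicon == amplicon]
  if (length(v) == 0) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' Averages technical replicates per (sample, amplicon), forms
#' dCt = Ct_target - Ct_reference per sample, subtracts the calibrator
#' sample's dCt, and reports rq = efficiency^(-ddCt). The calibrator's rq
#' is 1 by construction. The replicate spread is propagated as
#' dct_sd = sqrt(sd_target^2 + sd_reference^2).
#'
#' @param ct_table Ct record data frame with columns `sample`, `amplicon`,
#'   `ct` (and optionally `role`, `replicate`); see [simulate_ct_table()].
#' @param target,reference Amplicon names of the gene of interest and the
#'   reference gene (e.g. beta-actin).
#' @param calibrator Sample name whose expression defines rq = 1.
#' @param efficiency Amplification efficiency.
#' @return Data frame with `sample`, `target`, `dct`, `ddct`, `rq`,
#'   `dct_sd`.
#' @export
#' @examples
#' design <- data.frame(sample = rep(c("ctrl", "kd"), each = 2),
#'                      amplicon = rep(c("GENE", "ACTB"), 2),
#'                      role = rep(c("target", "reference"), 2),
#'                      quantity = c(1, 1, 0.4, 1))
#' cts <- simulate_ct_table(design, noise_sd = 0, seed = 1)
#' ddct(cts, "GENE", "ACTB", calibrator = "ctrl")$rq   # 1, 0.4
ddct <- function(ct_table, target, reference, calibrator, efficiency = 2) {
  samples <- unique(ct_table$sample)
  if (!(calibrator %in% samples))
    .stopf("calibrator sample %s not in Ct table", calibrator)
  stats_per <- lapply(samples, function(s) {
    tg <- .mean_ct(ct_table, s, target)
    rf <- .mean_ct(ct_table, s, reference)
    if (is.na(tg["mean"]))
      .stopf("sample %s has no Ct for target amplicon %s", s, target)
    if (is.na(rf["mean"]))
      .stopf("sample %s has no Ct for reference amplicon %s", s, reference)
    c(dct = unname(tg["mean"] - rf["mean"]),
      dct_sd = unname(sqrt(tg["sd"]^2 + rf["sd"]^2)))
  })
  dct <- vapply(stats_per, `[[`, numeric(1), "dct")
  dct_sd <- vapply(stats_per, `[[`, numeric(1), "dct_sd")
  ddct_v <- dct - dct[samples == calibrator]
  data.frame(sample = samples, target = target, dct = dct, ddct = ddct_v,
             rq = efficiency^(-ddct_v), dct_sd = dct_sd,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percent-of-input enrichment (FAIRE / ChIP)
#'
#' The input aliquot is a known fraction of the chromatin used for the
#' enriched sample (e.g. 1/10 volume), so its Ct is first adjusted down by
#' log_e(1/input_fraction) cycles to represent 100% of the material;
#' percent input is then 100 * efficiency^(adjusted_input_ct - sample_ct).
#'
#' @param sample_ct Ct of the enriched (FAIRE or ChIP) DNA.
#' @param input_ct Ct of the input aliquot.
#' @param input_fraction Fraction of material in the input aliquot, in
#'   (0, 1].
#' @param efficiency Amplification efficiency.
#' @return Percent of input (vectorized over the Ct arguments).
#' @export
#' @examples
#' percent_input(sample_ct = 20, input_ct = 20, input_fraction = 0.1)  # ~10
percent_input <- function(sample_ct, input_ct, input_fraction,
                          efficiency = 2) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    .stopf("input_fraction must lie in (0, 1]")
  adjusted <- input_ct - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adjusted - sample_ct)
}

#' ChIP enrichment over the IgG control
#'
#' Reports percent-of-input for the specific antibody and the IgG mock
#' pulldown, plus their ratio, which reduces to
#' efficiency^(igg_ct - flag_ct) since the input correction cancels.
#'
#' @param flag_ct Ct of the specific-antibody ChIP DNA.
#' @param igg_ct Ct of the IgG control ChIP DNA.
#' @param input_ct Ct of the input aliquot.
#' @param input_fraction Input aliquot fraction.
#' @param efficiency Amplification efficiency.
#' @return List with `percent_input_flag`, `percent_input_igg`, `fold`.
#' @export
chip_fold_over_igg <- function(flag_ct, igg_ct, input_ct,
                               input_fraction = 0.1, efficiency = 2) {
  if (anyNA(c(flag_ct, igg_ct, input_ct)))
    .stopf("all Ct values must be present")
  pf <- percent_input(flag_ct, input_ct, input_fraction, efficiency)
  pi_igg <- percent_input(igg_ct, input_ct, input_fraction, efficiency)
  list(percent_input_flag = pf, percent_input_igg = pi_igg,
       fold = pf / pi_igg)
}

#' getPCR allele-remaining fraction after genome editing
#'
#' Allele-specific qPCR readout of editing: the allele-specific amplicon's
#' Ct is referenced against a non-allelic amplicon in both the edited and
#' the unedited pool, and the double delta gives the fraction of the
#' targeted allele remaining. Editing efficiency is 1 minus this fraction.
#'
#' @param allele_ct_edited,allele_ct_control Allele-specific amplicon Cts
#'   in the edited and unedited pools.
#' @param ref_ct_edited,ref_ct_control Non-allelic reference amplicon Cts
#'   in the same pools.
#' @param efficiency Amplification efficiency.
#' @return Remaining fraction of the targeted allele (about 0 to 1).
#' @export
#' @examples
#' # one extra cycle on the allele-specific arm only: half the allele left
#' getpcr_remaining_fraction(21, 20, 18, 18)
getpcr_remaining_fraction <- function(allele_ct_edited, allele_ct_control,
                                      ref_ct_edited, ref_ct_control,
                                      efficiency = 2) {
  if (anyNA(c(allele_ct_edited, allele_ct_control, ref_ct_edited,
              ref_ct_control)))
    .stopf("all four Ct arms must be present")
  ddct_v <- (allele_ct_edited - ref_ct_edited) -
    (allele_ct_control - ref_ct_control)
  efficiency^(-ddct_v)
}
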