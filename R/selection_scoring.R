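# Per-SNP composite selection evidence, per-RE aggregation, and
# SNP-in-region enrichment statistics.

#' Fisher's combination of selection-score p-values
#'
#' Combines the per-statistic p-values (Fst, iHS, XP-EHH, PBS by
#' default) into one composite p-value: the statistic is
#' `-2 * sum(log p)` and the combined p-value is the upper tail of a
#' chi-square with `2 * Q` degrees of freedom. This is the simplified
#' composite-of-multiple-signals score used per SNP.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @param floor Values of exactly 0 (or below the floor) are clamped to
#'   this with a warning so the log stays finite.
#' @return A list with `stat` and `p`.
#' @export
fisher_combine <- function(pvalues, floor = 1e-300) {
  if (length(pvalues) == 0) stop("no p-values to combine")
  if (any(is.na(pvalues))) stop("NA p-value")
  if (any(pvalues > 1)) stop("p-value > 1")
  if (any(pvalues < floor)) {
    warning("p-value(s) below floor clamped to ", floor)
    pvalues <- pmax(pvalues, floor)
  }
  stat <- -2 * sum(log(pvalues))
  list(stat = stat,
       p = stats::pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues Vector of p-values in \[0, 1\].
#' @param level FDR level; rejections are `q <= level`.
#' @return A tibble with `p`, `q` and `reject`, in the input order.
#' @export
bh_fdr <- function(pvalues, level = 0.05) {
  if (length(pvalues) == 0) {
    return(tibble::tibble(p = numeric(), q = numeric(), reject = logical()))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  tibble::tibble(p = pvalues, q = q, reject = q <= level)
}

#' Difference in derived-allele frequency between populations
#'
#' `delta_daf = f_adaptive - f_wildtype`, each frequency a derived-allele
#' count over the total allele count in that population panel.
#'
#' @param adaptive,wildtype Length-2 vectors `c(count, total)`.
#' @return A number in \[-1, 1\].
#' @export
delta_daf <- function(adaptive, wildtype) {
  for (x in list(adaptive, wildtype)) {
    if (length(x) != 2) stop("expected c(count, total)")
    if (x[2] <= 0) stop("total allele count must be > 0")
    if (x[1] < 0 || x[1] > x[2]) stop("count must be in [0, total]")
  }
  adaptive[1] / adaptive[2] - wildtype[1] / wildtype[2]
}

#' LD-score weights
#'
#' A SNP's weight is the reciprocal of its LD score, down-weighting
#' SNPs that are redundant with many linked neighbours.
#'
#' @param ld_scores Positive LD scores.
#' @return `1 / ld_scores`.
#' @export
ld_weights <- function(ld_scores) {
  bad <- which(!(ld_scores > 0))
  if (length(bad) > 0) {
    stop("non-positive LD score at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  1 / ld_scores
}

#' Build the per-SNP selection table
#'
#' Attaches LD weights, the Fisher-combined composite p-value across the
#' four selection statistics, BH q-values and the selected flag at the
#' given FDR level. Missing individual scores (e.g. iHS undefined at
#' fixed sites) are imputed as p = 1 before combination and the SNP is
#' flagged.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`,
#'   `fst_mlogp`, `ihs_mlogp`, `xpehh_mlogp`, `pbs_mlogp` (each a
#'   -log10 p), `ddaf` and `ld_score`.
#' @param fdr FDR level for the selected flag.
#' @param floor p-value floor before the log.
#' @return The input with added columns `w`, `c_p` (composite p-value),
#'   `q`, `selected`, `imputed`.
#' @export
build_snp_table <- function(snps, fdr = 0.05, floor = 1e-300) {
  score_cols <- c("fst_mlogp", "ihs_mlogp", "xpehh_mlogp", "pbs_mlogp")
  needed <- c("snp_id", "chrom", "pos", score_cols, "ddaf", "ld_score")
  missing <- setdiff(needed, names(snps))
  if (length(missing) > 0) {
    stop("SNP table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(abs(snps$ddaf) > 1, na.rm = TRUE)) stop("ddaf outside [-1, 1]")
  X <- as.matrix(snps[, score_cols])
  if (any(X < 0, na.rm = TRUE)) stop("negative -log10 p selection score")
  imputed <- rowSums(is.na(X)) > 0
  X[is.na(X)] <- 0  # p = 1
  pmat <- pmax(10^(-X), floor)
  stat <- -2 * rowSums(log(pmat))
  c_p <- stats::pchisq(stat, df = 2 * ncol(pmat), lower.tail = FALSE)
  adj <- bh_fdr(c_p, level = fdr)
  snps |>
    dplyr::mutate(
      w = ld_weights(.data$ld_score),
      c_p = c_p,
      q = adj$q,
      selected = adj$reject,
      imputed = imputed
    )
}

#' Aggregate per-SNP selection evidence to regulatory elements
#'
#' For each RE, `J_k` is the set of SNPs whose position falls in the
#' half-open RE interval. Aggregates are LD-weighted means over `J_k`:
#' `agg_X[q] = mean(w * X[, q])`, `agg_Y = mean(w * Y)`, and the
#' selection-probability initialisation `p0 = 1 - mean(c_p)`. REs with
#' no SNPs get all aggregates 0 and `p0 = 0` (no evidence, no signal);
#' they are retained in the catalog but excluded from the logistic
#' regression.
#'
#' @param snps Output of [build_snp_table()].
#' @param res Tibble of REs (`re_id`, `chrom`, `start`, `end`).
#' @return A tibble with one row per RE: `n_snps`, `agg_fst`, `agg_ihs`,
#'   `agg_xpehh`, `agg_pbs`, `agg_ddaf`, `p0`.
#' @export
aggregate_re_features <- function(snps, res) {
  hits <- purrr::map(seq_len(nrow(res)), function(k) {
    which(snps$chrom == res$chrom[k] &
            snps$pos >= res$start[k] & snps$pos < res$end[k])
  })
  agg_one <- function(idx) {
    if (length(idx) == 0) {
      return(c(n = 0, fst = 0, ihs = 0, xpehh = 0, pbs = 0, ddaf = 0, p0 = 0))
    }
    w <- snps$w[idx]
    c(n = length(idx),
      fst = mean(w * snps$fst_mlogp[idx]),
      ihs = mean(w * snps$ihs_mlogp[idx]),
      xpehh = mean(w * snps$xpehh_mlogp[idx]),
      pbs = mean(w * snps$pbs_mlogp[idx]),
      ddaf = mean(w * snps$ddaf[idx]),
      p0 = 1 - mean(snps$c_p[idx]))
  }
  m <- t(vapply(hits, agg_one, numeric(7)))
  tibble::tibble(
    re_id = res$re_id,
    n_snps = as.integer(m[, "n"]),
    agg_fst = m[, "fst"], agg_ihs = m[, "ihs"],
    agg_xpehh = m[, "xpehh"], agg_pbs = m[, "pbs"],
    agg_ddaf = m[, "ddaf"], p0 = m[, "p0"]
  )
}

#' Fold-enrichment of selected SNPs in open chromatin
#'
#' `FE = (selected-in-peaks / all-in-peaks) / (selected-total / all-total)`.
#'
#' @param n_sel_in_peaks,n_all_in_peaks,n_sel_total,n_all_total Counts.
#' @return The FE score; `NA` with a warning when a denominator is zero.
#' @export
fe_score <- function(n_sel_in_peaks, n_all_in_peaks, n_sel_total, n_all_total) {
  if (n_all_total <= 0) stop("n_all_total must be > 0")
  if (n_sel_in_peaks > n_all_in_peaks || n_sel_total > n_all_total) {
    stop("numerator exceeds its denominator")
  }
  if (n_all_in_peaks == 0 || n_sel_total == 0) {
    warning("FE score undefined (zero denominator)")
    return(NA_real_)
  }
  (n_sel_in_peaks / n_all_in_peaks) / (n_sel_total / n_all_total)
}

#' Fold ratio and binomial p-value of selected SNPs in a region set
#'
#' The fold ratio compares the per-bp density of selected SNPs in the
#' region set with the genome-wide density of all SNPs. The p-value is
#' the upper tail of `Binomial(n_selected_total, region_len/genome_len)`
#' at the observed count.
#'
#' @param n_sel_in_region Selected SNPs falling in the region set.
#' @param region_len,genome_len Lengths in bp.
#' @param n_total Total SNPs genome-wide.
#' @param n_selected_total Total selected SNPs (the binomial `n`); a
#'   study parameter, not recomputed.
#' @return A list with `fold` and `p`.
#' @export
fold_ratio_enrichment <- function(n_sel_in_region, region_len, n_total,
                                  genome_len, n_selected_total) {
  if (region_len <= 0 || genome_len <= 0) stop("lengths must be > 0")
  if (region_len > genome_len) stop("region_len exceeds genome_len")
  fold <- (n_sel_in_region / region_len) / (n_total / genome_len)
  p <- stats::pbinom(n_sel_in_region - 1, size = n_selected_total,
                     prob = region_len / genome_len, lower.tail = FALSE)
  list(fold = fold, p = p)
}
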