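#' Alternative-allele support fractions at SNP positions
#'
#' One `n/N` value per SNP site with depth at least `min_depth`: the
#' foreign-allele read count over the total. A transcript transported
#' into tissue with low endogenous expression would show values near 1;
#' pure sequencing noise keeps them near the error rate.
#'
#' @param sites site-count `data.frame` (see [graft_sample()]).
#' @param min_depth minimum `N` for a site to contribute.
#' @param total_definition see [site_totals()].
#' @return Numeric vector of values in `[0, 1]` (possibly empty).
#' @export
snp_fractions <- function(sites, min_depth = 1L,
                          total_definition = "local_plus_foreign") {
  stopifnot(min_depth >= 1)
  st <- site_totals(sites, total_definition)
  keep <- st$n_total >= min_depth
  st$n_foreign[keep] / st$n_total[keep]
}

#' Second-nucleotide noise fractions at neighbouring positions
#'
#' One `m/M` value per non-SNP position with top-two depth at least
#' `min_depth`: the second most frequent nucleotide's count over the
#' summed counts of the two most frequent nucleotides. This is the
#' noise statistic the SNP `n/N` distribution is compared against.
#'
#' @param neighbours neighbour-count `data.frame` (see
#'   [neighbour_totals()]).
#' @param min_depth minimum `M` for a position to contribute.
#' @return Numeric vector of values in `[0, 0.5]` (possibly empty).
#' @export
neighbour_fractions <- function(neighbours, min_depth = 1L) {
  stopifnot(min_depth >= 1)
  nt <- neighbour_totals(neighbours)
  keep <- nt$M_top2 >= min_depth
  nt$m_second[keep] / nt$M_top2[keep]
}

#' Compare the SNP and neighbour-position fraction distributions
#'
#' Runs the distribution comparison on the raw value collections: an
#' exact two-sample Kolmogorov–Smirnov test (asymptotic, with a log
#' message, when the combined sample is too large for the exact
#' computation), a one-sided KS test of the alternative that the SNP
#' values are stochastically larger (the direction a real foreign allele
#' would push `n/N` above `m/M`), and Welch's t and Wilcoxon rank-sum
#' tests as secondary checks. Tests run on raw values, not binned
#' histograms: binning a KS test discards information, so the 100-bin
#' view is reproduced only in plotting.
#'
#' @param snp_vals `n/N` values from [snp_fractions()]; at least 3.
#' @param neigh_vals `m/M` values from [neighbour_fractions()]; at
#'   least 3.
#' @param alpha significance level used for the verdict field only.
#' @param exact_max largest combined sample size for which the exact KS
#'   p-value is computed.
#' @return An object of class `distribution_report`: a list of
#'   `ks_exact`, `ks_one_sided`, `welch_t`, `wilcoxon` (each with
#'   `statistic` and `p_value`), plus `alpha` and `no_support` — `TRUE`
#'   when no test rejects, i.e. the data offer no support for SNP
#'   positions being different from ordinary noise.
#' @export
compare_distributions <- function(snp_vals, neigh_vals, alpha = 0.05,
                                  exact_max = 10000L) {
  if (length(snp_vals) < 3 || length(neigh_vals) < 3) {
    stop("need at least 3 values in each collection")
  }
  use_exact <- length(snp_vals) * length(neigh_vals) <= exact_max^2 &&
    (length(snp_vals) + length(neigh_vals)) <= exact_max
  if (!use_exact) {
    message("combined sample too large for the exact KS computation; ",
            "using the asymptotic distribution")
  }
  ks2 <- suppressWarnings(
    ks.test(snp_vals, neigh_vals, exact = use_exact)
  )
  # alternative = "less": the CDF of x lies below that of y, i.e. x is
  # stochastically larger — the n/N > m/M direction
  ks1 <- suppressWarnings(
    ks.test(snp_vals, neigh_vals, alternative = "less")
  )
  wt <- t.test(snp_vals, neigh_vals)
  wx <- suppressWarnings(wilcox.test(snp_vals, neigh_vals))
  res <- list(
    ks_exact = list(statistic = unname(ks2$statistic),
                    p_value = ks2$p.value, exact = use_exact),
    ks_one_sided = list(statistic = unname(ks1$statistic),
                        p_value = ks1$p.value),
    welch_t = list(statistic = unname(wt$statistic), p_value = wt$p.value),
    wilcoxon = list(statistic = unname(wx$statistic), p_value = wx$p.value),
    alpha = alpha,
    n_snp = length(snp_vals), n_neighbour = length(neigh_vals)
  )
  res$no_support <- all(vapply(
    res[c("ks_exact", "ks_one_sided", "welch_t", "wilcoxon")],
    function(t) t$p_value > alpha, logical(1)
  ))
  structure(res, class = "distribution_report")
}

#' @exportS3Method base::print
print.distribution_report <- function(x, ...) {
  cat("SNP n/N versus neighbour m/M distributions\n")
  cat(sprintf("  %d SNP values, %d neighbour values\n", x$n_snp,
              x$n_neighbour))
  cat(sprintf("  two-sided KS (%s): D = %.6g, P = %.4g\n",
              if (x$ks_exact$exact) "exact" else "asymptotic",
              x$ks_exact$statistic, x$ks_exact$p_value))
  cat(sprintf("  one-sided KS (SNP larger): D = %.6g, P = %.4g\n",
              x$ks_one_sided$statistic, x$ks_one_sided$p_value))
  cat(sprintf("  Welch t: t = %.4g, P = %.4g\n",
              x$welch_t$statistic, x$welch_t$p_value))
  cat(sprintf("  Wilcoxon: W = %.4g, P = %.4g\n",
              x$wilcoxon$statistic, x$wilcoxon$p_value))
  cat(if (x$no_support) {
    sprintf("  no support for SNP positions being different (all P > %g)\n",
            x$alpha)
  } else {
    "  at least one test rejects equality\n"
  })
  invisible(x)
}

#' Histogram of fraction values in the style used for SNP/noise panels
#'
#' 100 equal-width bins over the data range, drawn with base graphics.
#' Provided for visual inspection only; the statistical comparison in
#' [compare_distributions()] always uses the raw values.
#'
#' @param vals fraction values.
#' @param main plot title.
#' @param ... passed to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot_fraction_histogram <- function(vals, main = "", ...) {
  h <- graphics::hist(vals, breaks = 100, main = main,
                      xlab = "fraction", ...)
  invisible(h)
}
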