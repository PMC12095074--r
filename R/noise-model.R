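#' Upper tail of the binomial distribution
#'
#' Probability of seeing at least `m_thr` successes out of `N` trials with
#' per-trial probability `q`: `P(k >= m_thr | N, q)`. This is the chance
#' that sequencing error alone produces `m_thr` or more foreign-allele
#' reads at total depth `N`, the quantity behind every absolute-read-count
#' mobility criterion.
#'
#' @param m_thr required number of successes, `0 <= m_thr <= N + 1`
#'   (vectorised).
#' @param N number of trials (reads).
#' @param q per-trial success (foreign-allele error) probability.
#' @return `P(k >= m_thr)`, computed through the numerically stable
#'   regularised-beta tail used by [stats::pbinom()]; exact to at least 12
#'   significant digits for `N` up to `1e6`.
#' @examples
#' binomial_tail(2, 100, 0.001)
#' @export
binomial_tail <- function(m_thr, N, q) {
  n <- max(length(m_thr), length(N), length(q))
  m_thr <- rep_len(m_thr, n); N <- rep_len(N, n); q <- rep_len(q, n)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (any(N < 0)) stop("N must be non-negative")
  if (any(m_thr < 0 | m_thr > N + 1)) {
    stop("m_thr must lie in [0, N + 1]")
  }
  out <- numeric(n)
  out[m_thr == 0] <- 1
  out[m_thr == N + 1] <- 0
  mid <- m_thr >= 1 & m_thr <= N
  out[mid] <- pbinom(m_thr[mid] - 1, N[mid], q[mid], lower.tail = FALSE)
  out
}

#' Define a published mobility criterion
#'
#' Published SNP-based definitions of a mobile transcript require a fixed
#' number of foreign-allele reads: at least 1 read covering two SNPs, at
#' least 2, at least 3, or more than 3 reads covering a single SNP. A
#' strict `>` threshold is normalised to the equivalent inclusive `>=`
#' threshold at construction, removing the ambiguity at the API boundary.
#'
#' @param name display name.
#' @param min_reads read-count threshold.
#' @param min_snps_per_read 1 (single-SNP criterion) or 2 (each
#'   qualifying read must cover two SNPs, so an erroneous call needs two
#'   independent errors on one read).
#' @param strict if `TRUE` the threshold is `> min_reads`, i.e.
#'   `>= min_reads + 1`.
#' @return An object of class `mobility_criterion`.
#' @export
mobility_criterion <- function(name, min_reads, min_snps_per_read = 1L,
                               strict = FALSE) {
  stopifnot(min_reads >= 1, min_snps_per_read %in% c(1L, 2L))
  m_eff <- as.integer(min_reads) + if (strict) 1L else 0L
  structure(
    list(name = name, m_thr = m_eff,
         min_snps_per_read = as.integer(min_snps_per_read)),
    class = "mobility_criterion"
  )
}

#' The four published mobility criteria
#'
#' Convenience list: `>=1` read covering two SNPs, `>=2` reads, `>=3`
#' reads and `>3` reads covering a single SNP.
#'
#' @return Named list of [mobility_criterion()] objects.
#' @export
published_criteria <- function() {
  list(
    ge1_two_snps = mobility_criterion(">=1 read covering two SNPs", 1L,
                                      min_snps_per_read = 2L),
    ge2 = mobility_criterion(">=2 reads", 2L),
    ge3 = mobility_criterion(">=3 reads", 3L),
    gt3 = mobility_criterion(">3 reads", 3L, strict = TRUE)
  )
}

#' False-positive probability of a mobility criterion at a given depth
#'
#' For a single-SNP criterion this is the binomial tail at the read
#' threshold. For a two-SNP criterion both SNPs on a read must err, so the
#' per-read probability is `q^2` (probabilities multiply under
#' independence) and `N` counts multi-SNP reads.
#'
#' @param criterion a [mobility_criterion()].
#' @param N read depth (single-SNP reads, or multi-SNP reads for
#'   two-SNP criteria); vectorised.
#' @param q foreign-allele error probability per sequenced base.
#' @return Probability that noise alone satisfies the criterion.
#' @export
criterion_fp_probability <- function(criterion, N, q) {
  stopifnot(inherits(criterion, "mobility_criterion"))
  q_eff <- if (criterion$min_snps_per_read == 2L) q^2 else q
  m <- pmin(criterion$m_thr, N + 1)
  binomial_tail(m, N, q_eff)
}

#' Expected number of false mobile calls over a set of transcripts
#'
#' Sums the criterion's false-positive probability over per-transcript
#' SNP-covering read depths, and tabulates the depth dependency over a
#' grid — absolute-read-count criteria call more transcripts mobile purely
#' because deeper transcripts accumulate more errors.
#'
#' @param depths non-negative per-transcript total SNP-read depths.
#' @param criterion a [mobility_criterion()].
#' @param q foreign-allele error probability.
#' @param grid_points number of depth-grid points for the curve.
#' @return A list: `expected` (expected false-positive count),
#'   `per_transcript` (each transcript's probability), and `curve`
#'   (`data.frame` of `depth`, `fp_probability`, non-decreasing in depth).
#' @export
expected_false_positives <- function(depths, criterion, q,
                                     grid_points = 50L) {
  if (!length(depths)) {
    warning("empty depth list: expected false positives is 0")
    return(list(expected = 0, per_transcript = numeric(0),
                curve = data.frame(depth = integer(0),
                                   fp_probability = numeric(0))))
  }
  if (any(depths < 0)) stop("depths must be non-negative")
  p <- criterion_fp_probability(criterion, depths, q)
  grid <- unique(round(seq(0, max(depths, 1), length.out = grid_points)))
  list(
    expected = sum(p),
    per_transcript = p,
    curve = data.frame(
      depth = grid,
      fp_probability = criterion_fp_probability(criterion, grid, q)
    )
  )
}

#' Estimate the background foreign-allele rate from a homograft
#'
#' In a homograft no foreign genotype is present, so every read matching
#' the would-be foreign allele is noise (sequencing or RT error,
#' mismapping, pseudo-heterozygosity). Counts are pooled over all sites
#' and summarised both as a point rate and as a conjugate
#' `Beta(prior_a + n, prior_b + N - n)` posterior that carries the
#' depth-dependent uncertainty forward.
#'
#' @param homograft a [graft_sample()] with `graft_type = "homograft"`.
#' @param prior_a,prior_b Beta prior pseudo-counts.
#' @param total_definition what the site total counts; see
#'   [site_totals()].
#' @param by_gene if `TRUE`, additionally return a per-gene stratified
#'   table (pseudo-heterozygous loci can inflate the pooled rate, so the
#'   stratified view localises them).
#' @return An object of class `noise_estimate`: `sample_id`,
#'   `n_foreign_total`, `n_total`, `rate_point`, `posterior_a`,
#'   `posterior_b`, and optionally `per_gene`.
#' @export
estimate_background <- function(homograft, prior_a = 1, prior_b = 1,
                                total_definition = "local_plus_foreign",
                                by_gene = FALSE) {
  stopifnot(inherits(homograft, "graft_sample"))
  if (homograft$graft_type != "homograft") {
    stop("background noise must be estimated from a homograft ",
         "(no foreign genotype present)")
  }
  st <- site_totals(homograft$sites, total_definition)
  n <- sum(st$n_foreign)
  N <- sum(st$n_total)
  if (N == 0) stop("homograft has zero total depth at every site")
  out <- structure(
    list(sample_id = homograft$sample_id,
         n_foreign_total = n, n_total = N,
         rate_point = n / N,
         posterior_a = prior_a + n, posterior_b = prior_b + N - n),
    class = "noise_estimate"
  )
  if (by_gene) {
    agg <- aggregate(cbind(n_foreign, n_total) ~ gene_id, data = st, FUN = sum)
    agg$rate_point <- ifelse(agg$n_total > 0, agg$n_foreign / agg$n_total, NA)
    out$per_gene <- agg
  }
  out
}

#' @exportS3Method base::print
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> %s: %d foreign-matching of %d reads (%s)\n",
    x$sample_id, x$n_foreign_total, x$n_total,
    format_percent(x$rate_point)
  ))
  cat(sprintf("  posterior Beta(%g, %g)\n", x$posterior_a, x$posterior_b))
  invisible(x)
}

#' Foreign-read fraction of a sample
#'
#' The ratio of reads assigned to an alternative (foreign) allele over all
#' SNP-covering reads — a simple accuracy metric to compute for homografts
#' and compare against heterografts: a heterograft fraction no higher than
#' the homograft's offers no evidence of transport.
#'
#' @param sample a [graft_sample()].
#' @param total_definition see [site_totals()].
#' @return A list: `fraction`, `percent` (two significant figures by
#'   default style; see [format_percent()]), `n_foreign`, `n_total`.
#' @export
foreign_read_fraction <- function(sample,
                                  total_definition = "local_plus_foreign") {
  stopifnot(inherits(sample, "graft_sample"))
  st <- site_totals(sample$sites, total_definition)
  n <- sum(st$n_foreign)
  N <- sum(st$n_total)
  if (N == 0) stop("sample has zero total depth: fraction undefined")
  list(fraction = n / N, percent = format_percent(n / N),
       n_foreign = n, n_total = N)
}

#' Compare heterograft and homograft foreign-read fractions
#'
#' @param het,hom [graft_sample()] objects.
#' @param total_definition see [site_totals()].
#' @return A list with both fractions and `no_excess` — `TRUE` when the
#'   heterograft fraction does not exceed the homograft's, i.e. the
#'   dataset-level metric offers no support for transport.
#' @export
compare_foreign_fractions <- function(het, hom,
                                      total_definition = "local_plus_foreign") {
  f_het <- foreign_read_fraction(het, total_definition)
  f_hom <- foreign_read_fraction(hom, total_definition)
  list(heterograft = f_het, homograft = f_hom,
       no_excess = f_het$fraction <= f_hom$fraction)
}

#' Format a fraction as a percentage
#'
#' @param x fraction in `[0, 1]`.
#' @param style `"signif2"` (two significant figures, the default used in
#'   running text) or `"decimals2"` (two decimal places).
#' @return Character, e.g. `"0.084%"` or `"0.10%"`.
#' @export
format_percent <- function(x, style = c("signif2", "decimals2")) {
  style <- match.arg(style)
  pct <- 100 * x
  if (style == "decimals2") {
    sprintf("%.2f%%", pct)
  } else {
    paste0(formatC(signif(pct, 2), format = "fg"), "%")
  }
}
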