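# Shared fixture builders and independent oracles used across the suite.

# Build a site-count table from foreign/local read counts (other
# nucleotides zero unless given).
make_sites <- function(n_foreign, n_local, gene_id = "g1",
                       sample_id = "s1", local = "A", foreign = "G",
                       other = 0L, chrom = "Chr1", pos = NULL) {
  k <- max(length(n_foreign), length(n_local))
  n_foreign <- rep_len(n_foreign, k)
  n_local <- rep_len(n_local, k)
  gene_id <- rep_len(gene_id, k)
  local <- rep_len(local, k)
  foreign <- rep_len(foreign, k)
  other <- rep_len(other, k)
  if (is.null(pos)) pos <- seq_len(k) * 100L
  cnt <- matrix(0L, k, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  cnt[cbind(seq_len(k), match(local, colnames(cnt)))] <- as.integer(n_local)
  cnt[cbind(seq_len(k), match(foreign, colnames(cnt)))] <-
    as.integer(n_foreign)
  # park any "other" reads on a nucleotide that is neither allele
  if (any(other > 0)) {
    for (i in which(other > 0)) {
      third <- setdiff(colnames(cnt), c(local[i], foreign[i]))[1]
      cnt[i, third] <- as.integer(other[i])
    }
  }
  out <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                    gene_id = gene_id, local_allele = local,
                    foreign_allele = foreign, stringsAsFactors = FALSE)
  out[paste0("count_", colnames(cnt))] <- as.data.frame(cnt)
  out
}

make_hom <- function(sites, sample_id = "hom1") {
  graft_sample(sample_id, "homograft", "root", "gtA", "gtA", sites = sites)
}

make_het <- function(sites, sample_id = "het1") {
  graft_sample(sample_id, "heterograft", "root", "gtA", "gtB", sites = sites)
}

# Independent binomial upper-tail oracle: exhaustive term-by-term
# summation (log-space to survive large N), no pbinom anywhere.
enum_binomial_tail <- function(m, N, q) {
  if (m == 0) return(1)
  if (m > N) return(0)
  if (q == 0) return(0)
  if (q == 1) return(1)
  k <- m:N
  sum(exp(lchoose(N, k) + k * log(q) + (N - k) * log1p(-q)))
}

# Independent beta-binomial marginal oracle: adaptive quadrature of
# binomial x prior in q-space. The integrand is proportional to the
# Beta(n + a, N - n + b) posterior density, so integrating between that
# posterior's 1e-13 and 1 - 1e-13 quantiles keeps the spike interior,
# avoids the prior's endpoint singularities, and truncates only ~2e-13
# of the mass — far below the 8-digit tolerance this oracle serves.
quad_log_marginal <- function(n, N, a, b) {
  # mirror counts above N/2 (exact identity under q -> 1 - q), so the
  # posterior's upper quantile never rounds to 1.0 where a < 1 priors
  # are singular
  if (n > N - n) return(quad_log_marginal(N - n, N, b, a))
  lo <- stats::qbeta(1e-13, n + a, N - n + b)
  hi <- stats::qbeta(1e-13, n + a, N - n + b, lower.tail = FALSE)
  logf <- function(q) {
    dbinom(n, N, q, log = TRUE) + stats::dbeta(q, a, b, log = TRUE)
  }
  # centre the log-scale shift on the posterior median: it always sits
  # inside the integrand's mass, unlike a grid maximum, which can land
  # on an integrable prior singularity of huge density but no mass
  shift <- logf(stats::qbeta(0.5, n + a, N - n + b))
  val <- stats::integrate(function(q) exp(logf(q) - shift),
                          lo, hi, rel.tol = 1e-11, abs.tol = 0,
                          subdivisions = 2000L)$value
  log(val) + shift
}

# Significant-digit agreement helper.
expect_signif_equal <- function(x, y, digits) {
  denom <- pmax(abs(x), abs(y))
  rel <- ifelse(denom == 0, 0, abs(x - y) / denom)
  expect_true(all(rel < 10^(-digits)),
              label = sprintf("max rel err %.3g vs 1e-%d", max(rel), digits))
}
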