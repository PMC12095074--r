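#' Log marginal likelihood of counts under a beta-binomial model
#'
#' Integrates the binomial likelihood of `n` foreign-allele reads out of
#' `N` over a `Beta(a, b)` prior on the unknown rate:
#' `log[ C(N, n) * B(n + a, N - n + b) / B(a, b) ]`, evaluated through
#' log-gamma so it stays finite for `N` up to `1e7`.
#'
#' @param n foreign-allele read count (vectorised).
#' @param N total read count.
#' @param a,b Beta prior pseudo-counts, both `> 0`.
#' @return Log marginal likelihood (natural log).
#' @examples
#' log_betabinom_marginal(1, 1, 1, 1)  # log(1/2)
#' @export
log_betabinom_marginal <- function(n, N, a, b) {
  k <- max(length(n), length(N))
  n <- rep_len(n, k); N <- rep_len(N, k)
  if (any(a <= 0) || any(b <= 0)) stop("prior pseudo-counts must be > 0")
  if (any(n < 0) || any(n > N)) stop("n must lie in [0, N]")
  lchoose(N, n) + lbeta(n + a, N - n + b) - lbeta(a, b)
}

#' Bayes factor for a foreign component beyond homograft noise
#'
#' Compares two hypotheses for the pooled foreign/total counts of one
#' transcript in a heterograft and a matched homograft:
#'
#' * noise: one shared foreign-allele rate generated both samples —
#'   marginal `m1 = Int Bin(n_hom | N_hom, q) Bin(n_het | N_het, q)
#'   Beta(q | a, b) dq`, available in closed form;
#' * foreign component present: each sample has its own rate —
#'   `m2` is the product of the two beta-binomial marginals.
#'
#' The returned value is `log10(m2 / m1)`; values above the configured
#' threshold (default 1, "strong" on Jeffreys' scale) mark mobile
#' candidates. The second rate is unconstrained rather than truncated
#' above the homograft rate, which keeps the closed form, is symmetric
#' under label exchange and is conservative for the transport direction.
#'
#' @param n_het,N_het pooled heterograft foreign and total counts.
#' @param n_hom,N_hom pooled homograft counts.
#' @param prior_a,prior_b Beta prior pseudo-counts (default flat).
#' @return `log10` Bayes factor (vectorised); exactly 0, with attribute
#'   `zero_evidence`, when both samples have zero depth.
#' @export
bayes_factor <- function(n_het, N_het, n_hom, N_hom,
                         prior_a = 1, prior_b = 1) {
  k <- max(length(n_het), length(N_het), length(n_hom), length(N_hom))
  n_het <- rep_len(n_het, k); N_het <- rep_len(N_het, k)
  n_hom <- rep_len(n_hom, k); N_hom <- rep_len(N_hom, k)
  log_m2 <- log_betabinom_marginal(n_het, N_het, prior_a, prior_b) +
    log_betabinom_marginal(n_hom, N_hom, prior_a, prior_b)
  # shared-rate marginal: the binomial coefficients factor out of the
  # integral over the common rate
  log_m1 <- lchoose(N_het, n_het) + lchoose(N_hom, n_hom) +
    lbeta(n_het + n_hom + prior_a, N_het + N_hom - n_het - n_hom + prior_b) -
    lbeta(prior_a, prior_b)
  out <- (log_m2 - log_m1) / log(10)
  zero <- N_het == 0 & N_hom == 0
  out[zero] <- 0
  attr(out, "zero_evidence") <- zero
  out
}

#' Classify transcripts as noise-consistent or mobile candidates
#'
#' Pools each gene's foreign/total counts over its SNP sites in the
#' heterograft and the homograft, computes the [bayes_factor()], and
#' classifies against the configured `log10` threshold. Genes present in
#' the heterograft but absent from the homograft are emitted with a
#' `missing_hom` flag and excluded from downstream summaries.
#'
#' @param het heterograft [graft_sample()].
#' @param hom homograft [graft_sample()].
#' @param config an [analysis_config()]; uses `prior_a`, `prior_b`,
#'   `log_bf_threshold` and `total_definition`.
#' @param per_snp if `TRUE`, compute one Bayes factor per SNP and keep
#'   the gene-level call as the maximum (pseudo-SNPs can dominate pooled
#'   counts; the per-SNP mode localises them).
#' @return A `data.frame` of mobility calls: `gene_id, n_het, N_het,
#'   n_hom, N_hom, log10_bf, classification, zero_evidence, missing_hom`.
#' @export
classify_transcripts <- function(het, hom, config = analysis_config(),
                                 per_snp = FALSE) {
  stopifnot(inherits(het, "graft_sample"), inherits(hom, "graft_sample"))
  if (hom$graft_type != "homograft") {
    stop("the reference sample must be a homograft")
  }
  st_het <- site_totals(het$sites, config$total_definition)
  st_hom <- site_totals(hom$sites, config$total_definition)

  if (per_snp) {
    key_hom <- paste(st_hom$chrom, st_hom$pos)
    idx <- match(paste(st_het$chrom, st_het$pos), key_hom)
    lb <- bayes_factor(st_het$n_foreign, st_het$n_total,
                       ifelse(is.na(idx), 0L, st_hom$n_foreign[idx]),
                       ifelse(is.na(idx), 0L, st_hom$n_total[idx]),
                       config$prior_a, config$prior_b)
    per_site <- data.frame(gene_id = st_het$gene_id, log10_bf = lb)
    gene_bf <- aggregate(log10_bf ~ gene_id, per_site, max)
  }

  agg_het <- aggregate(cbind(n_foreign, n_total) ~ gene_id, st_het, sum)
  agg_hom <- aggregate(cbind(n_foreign, n_total) ~ gene_id, st_hom, sum)
  m <- merge(agg_het, agg_hom, by = "gene_id", all.x = TRUE,
             suffixes = c("_het", "_hom"))
  missing_hom <- is.na(m$n_total_hom)
  m$n_foreign_hom[missing_hom] <- 0L
  m$n_total_hom[missing_hom] <- 0L

  lb <- bayes_factor(m$n_foreign_het, m$n_total_het,
                     m$n_foreign_hom, m$n_total_hom,
                     config$prior_a, config$prior_b)
  zero <- attr(lb, "zero_evidence")
  if (per_snp) {
    lb <- gene_bf$log10_bf[match(m$gene_id, gene_bf$gene_id)]
  }
  calls <- data.frame(
    gene_id = m$gene_id,
    n_het = m$n_foreign_het, N_het = m$n_total_het,
    n_hom = m$n_foreign_hom, N_hom = m$n_total_hom,
    log10_bf = as.numeric(lb),
    stringsAsFactors = FALSE
  )
  calls$classification <- ifelse(calls$log10_bf > config$log_bf_threshold,
                                 "mobile_candidate", "noise_consistent")
  calls$zero_evidence <- zero | calls$N_het == 0
  calls$classification[calls$zero_evidence & calls$n_het == 0] <-
    "noise_consistent"
  calls$missing_hom <- missing_hom
  calls
}

#' Summarise how many listed mobile mRNAs are explained by noise
#'
#' Given mobility calls and a previously annotated list of mobile gene
#' ids, reports how many of the listed genes the evidence classifies as
#' noise-consistent, and the percentage (nearest integer).
#'
#' @param calls output of [classify_transcripts()]; calls flagged
#'   `missing_hom` are excluded.
#' @param reference_list character vector of gene ids annotated mobile.
#' @return A list: `n_noise_consistent`, `n_listed`, `percent_explained`.
#' @examples
#' calls <- data.frame(gene_id = c("g1", "g2"),
#'                     classification = c("noise_consistent",
#'                                        "mobile_candidate"),
#'                     missing_hom = FALSE)
#' summarize_noise_explained(calls, c("g1", "g2"))
#' @export
summarize_noise_explained <- function(calls, reference_list) {
  if (!length(reference_list)) stop("reference list of mobile genes is empty")
  calls <- calls[!calls$missing_hom, , drop = FALSE]
  listed <- calls[calls$gene_id %in% reference_list, , drop = FALSE]
  n_noise <- sum(listed$classification == "noise_consistent")
  n_listed <- length(unique(reference_list))
  list(
    n_noise_consistent = n_noise,
    n_listed = n_listed,
    percent_explained = round(100 * n_noise / n_listed)
  )
}
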