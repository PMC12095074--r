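NUCLEOTIDES <- c("A", "C", "G", "T")
COUNT_COLS <- paste0("count_", NUCLEOTIDES)

#' Construct and validate a SNP site table
#'
#' A SNP site is a bi-allelic genomic position at which the two graft
#' partners carry different nucleotides: the `local_allele` belongs to the
#' genotype of the sampled tissue, the `foreign_allele` to the graft
#' partner. Reads matching the foreign allele are the raw evidence for
#' transport (or for noise).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param gene_id character vector of gene/transcript identifiers.
#' @param local_allele,foreign_allele nucleotides in `A/C/G/T`; must differ
#'   position-wise.
#' @return A `data.frame` with one row per site and an `is_biallelic`
#'   column (always `TRUE` for sites built through this constructor).
#' @examples
#' snp_sites("Chr1", 1042L, "AT1G01010", "A", "G")
#' @export
snp_sites <- function(chrom, pos, gene_id, local_allele, foreign_allele) {
  s <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    gene_id = as.character(gene_id),
    local_allele = toupper(as.character(local_allele)),
    foreign_allele = toupper(as.character(foreign_allele)),
    is_biallelic = TRUE,
    stringsAsFactors = FALSE
  )
  validate_snp_sites(s)
  s
}

validate_snp_sites <- function(s) {
  stopifnot(is.data.frame(s))
  if (any(s$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  bad <- !(s$local_allele %in% NUCLEOTIDES) | !(s$foreign_allele %in% NUCLEOTIDES)
  if (any(bad)) stop("alleles must be one of A, C, G, T")
  if (any(s$local_allele == s$foreign_allele)) {
    stop("local_allele and foreign_allele must differ at every site")
  }
  key <- paste(s$chrom, s$pos)
  if (anyDuplicated(key)) stop("duplicated (chrom, pos) in site set")
  invisible(s)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters shared by the audit stages.
#'
#' @param alt_error_prob probability `q` that a sequenced base at a SNP
#'   position reports the foreign allele purely by error. With uniform
#'   misincorporation this is one third of the per-base error rate.
#' @param prior_a,prior_b pseudo-counts of the Beta prior on the unknown
#'   foreign-allele rate (default the flat `Beta(1, 1)`).
#' @param log_bf_threshold base-10 log Bayes-factor cutoff above which a
#'   transcript is a mobile candidate; 1 is "strong" on Jeffreys' scale.
#' @param neighbour_window half-width (in bp) of the window of non-SNP
#'   positions used as the noise comparison set around each SNP.
#' @param total_definition what the site total `N` counts:
#'   `"local_plus_foreign"` (reads matching either graft allele; the
#'   default) or `"all_nucleotides"` (all four counts).
#' @param alpha significance level reported by the distribution tests.
#' @param rng_seed integer seed for any stochastic stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alt_error_prob = 1e-4,
                            prior_a = 1, prior_b = 1,
                            log_bf_threshold = 1,
                            neighbour_window = 5L,
                            total_definition = c("local_plus_foreign",
                                                 "all_nucleotides"),
                            alpha = 0.05,
                            rng_seed = 1L) {
  total_definition <- match.arg(total_definition)
  stopifnot(
    alt_error_prob > 0, alt_error_prob < 1,
    prior_a > 0, prior_b > 0,
    neighbour_window >= 1
  )
  structure(
    list(
      alt_error_prob = alt_error_prob,
      prior_a = prior_a, prior_b = prior_b,
      log_bf_threshold = log_bf_threshold,
      neighbour_window = as.integer(neighbour_window),
      total_definition = total_definition,
      alpha = alpha,
      rng_seed = as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Fields in the file override the defaults of [analysis_config()]; fields
#' supplied through `...` (e.g. from command-line flags) override the file.
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @param ... overrides applied after the file is read.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Construct a graft sample
#'
#' A graft sample holds the per-site nucleotide counts (and optionally
#' neighbour-position counts and multi-SNP read observations) for one
#' sequenced tissue of one graft. Homografts join two plants of the same
#' genotype and therefore measure the noise-only null.
#'
#' @param sample_id sample identifier.
#' @param graft_type `"homograft"` or `"heterograft"`.
#' @param tissue `"root"`, `"shoot"` or `"other"`.
#' @param genotype_sampled,genotype_partner genotype labels; for a
#'   homograft they must be equal.
#' @param sites `data.frame` of per-site counts as produced by
#'   [read_allele_table()] (columns `sample_id, chrom, pos, gene_id,
#'   local_allele, foreign_allele, count_A..count_T`).
#' @param neighbours optional `data.frame` of neighbour-position counts
#'   (columns `sample_id, chrom, pos, count_A..count_T`).
#' @param reads optional long-format `data.frame` of multi-SNP read
#'   observations (columns `read_id, sample_id, chrom, pos,
#'   observed_base`).
#' @return An object of class `graft_sample`.
#' @export
graft_sample <- function(sample_id, graft_type = c("homograft", "heterograft"),
                         tissue = c("root", "shoot", "other"),
                         genotype_sampled, genotype_partner,
                         sites, neighbours = NULL, reads = NULL) {
  graft_type <- match.arg(graft_type)
  tissue <- match.arg(tissue)
  if (graft_type == "homograft" && genotype_sampled != genotype_partner) {
    stop("a homograft joins two plants of the same genotype: ",
         "genotype_sampled must equal genotype_partner")
  }
  validate_site_counts(sites)
  structure(
    list(
      sample_id = as.character(sample_id),
      graft_type = graft_type, tissue = tissue,
      genotype_sampled = as.character(genotype_sampled),
      genotype_partner = as.character(genotype_partner),
      sites = sites, neighbours = neighbours, reads = reads
    ),
    class = "graft_sample"
  )
}

#' @exportS3Method base::print
print.graft_sample <- function(x, ...) {
  cat(sprintf("<graft_sample> %s: %s %s (%s sampled, partner %s)\n",
              x$sample_id, x$graft_type, x$tissue,
              x$genotype_sampled, x$genotype_partner))
  cat(sprintf("  %d SNP sites, %d genes", nrow(x$sites),
              length(unique(x$sites$gene_id))))
  if (!is.null(x$neighbours)) {
    cat(sprintf(", %d neighbour positions", nrow(x$neighbours)))
  }
  if (!is.null(x$reads)) {
    cat(sprintf(", %d multi-SNP reads", length(unique(x$reads$read_id))))
  }
  cat("\n")
  invisible(x)
}

validate_site_counts <- function(sites) {
  needed <- c("sample_id", "chrom", "pos", "gene_id",
              "local_allele", "foreign_allele", COUNT_COLS)
  missing <- setdiff(needed, names(sites))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  }
  cnt <- as.matrix(sites[COUNT_COLS])
  if (any(cnt < 0)) stop("nucleotide counts must be non-negative")
  invisible(sites)
}

#' Per-site foreign and total counts
#'
#' Derives, for each site row, `n_foreign` (reads matching the foreign
#' allele) and `n_total` (`N`). What `N` counts is configurable because the
#' published statistic divides by "local and foreign reads" while a raw
#' pileup reports all four nucleotides; the default follows the former.
#'
#' @param sites a site-count `data.frame` (see [graft_sample()]).
#' @param total_definition `"local_plus_foreign"` or `"all_nucleotides"`.
#' @return The input with `n_foreign`, `n_total` and `zero_depth` columns
#'   appended.
#' @export
site_totals <- function(sites,
                        total_definition = c("local_plus_foreign",
                                             "all_nucleotides")) {
  total_definition <- match.arg(total_definition)
  validate_site_counts(sites)
  cnt <- as.matrix(sites[COUNT_COLS])
  colnames(cnt) <- NUCLEOTIDES
  idx_f <- match(sites$foreign_allele, NUCLEOTIDES)
  idx_l <- match(sites$local_allele, NUCLEOTIDES)
  sites$n_foreign <- cnt[cbind(seq_len(nrow(cnt)), idx_f)]
  if (total_definition == "all_nucleotides") {
    sites$n_total <- rowSums(cnt)
  } else {
    sites$n_total <- sites$n_foreign + cnt[cbind(seq_len(nrow(cnt)), idx_l)]
  }
  sites$zero_depth <- sites$n_total == 0L
  sites
}

#' Second-most-frequent nucleotide statistics for neighbour positions
#'
#' At a non-SNP position any minor nucleotide is unambiguous noise. The
#' noise statistic is `m/M`: the count of the second most frequent
#' nucleotide `m` over the summed counts of the two most frequent
#' nucleotides `M`. Count ties are value-identical, so the fixed A<C<G<T
#' order used to rank tied nucleotides does not affect `m` or `M`.
#'
#' @param neighbours `data.frame` with columns `chrom, pos, sample_id,
#'   count_A..count_T`.
#' @return The input with `m_second`, `M_top2` and `zero_depth` appended.
#' @export
neighbour_totals <- function(neighbours) {
  missing <- setdiff(c("chrom", "pos", COUNT_COLS), names(neighbours))
  if (length(missing)) {
    stop("neighbour table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  cnt <- as.matrix(neighbours[COUNT_COLS])
  if (any(cnt < 0)) stop("nucleotide counts must be non-negative")
  ord <- t(apply(cnt, 1L, sort, decreasing = TRUE))
  neighbours$m_second <- ord[, 2L]
  neighbours$M_top2 <- ord[, 1L] + ord[, 2L]
  neighbours$zero_depth <- neighbours$M_top2 == 0L
  neighbours
}
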