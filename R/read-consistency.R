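#' Classify a multi-SNP read by allele consistency
#'
#' A read genuinely transcribed from one genotype must carry that
#' genotype's allele at every SNP it covers; mixed observations are the
#' signature of sequencing error. Reads with any observation matching
#' neither allele are kept apart (`contains_other`, taking precedence)
#' because a third nucleotide is unambiguous error and would dilute the
#' local-versus-foreign contrast.
#'
#' @param observed_class character vector of per-SNP observations for one
#'   read, each `"local"`, `"foreign"` or `"other"`; at least 2.
#' @return One of `"all_local"`, `"all_foreign"`, `"inconsistent"`,
#'   `"contains_other"`.
#' @examples
#' classify_read(c("foreign", "foreign"))
#' classify_read(c("foreign", "local"))
#' @export
classify_read <- function(observed_class) {
  if (length(observed_class) < 2) {
    stop("a multi-SNP read needs at least 2 observations")
  }
  if (!all(observed_class %in% c("local", "foreign", "other"))) {
    stop("observations must be 'local', 'foreign' or 'other'")
  }
  if (any(observed_class == "other")) return("contains_other")
  if (all(observed_class == "foreign")) return("all_foreign")
  if (all(observed_class == "local")) return("all_local")
  "inconsistent"
}

#' Summarise allele consistency over all multi-SNP reads of a sample
#'
#' Tallies reads covering two or more SNPs into the four consistency
#' categories. Under pure sequencing noise the all-foreign fraction of
#' k-SNP reads scales as `(e/3)^k`, so genuinely transported transcripts
#' stand out as an excess of all-foreign reads, while inconsistent reads
#' directly measure the error process.
#'
#' @param reads long-format observation `data.frame` (columns `read_id`
#'   and either `observed_class`, or `chrom, pos, observed_base` plus
#'   `sites` to classify against).
#' @param sites optional SNP site table used to derive `observed_class`
#'   when absent.
#' @return An object of class `consistency_summary`: a `data.frame` of
#'   `category, count, fraction, percent`, with attribute `n_reads`.
#'   Categories partition the reads, so counts sum to the total.
#' @export
consistency_summary <- function(reads, sites = NULL) {
  if (is.null(reads) || !nrow(reads)) {
    warning("no multi-SNP reads supplied")
    reads <- data.frame(read_id = character(0),
                        observed_class = character(0))
  }
  if (!"observed_class" %in% names(reads)) {
    if (is.null(sites)) {
      stop("reads lack observed_class: supply the SNP site table")
    }
    reads <- classify_observations(reads, sites)
  }
  # single-SNP reads are outside this audit's domain
  tab <- table(reads$read_id)
  multi <- names(tab)[tab >= 2L]
  reads <- reads[reads$read_id %in% multi, , drop = FALSE]
  per_read <- vapply(split(reads$observed_class, reads$read_id),
                     classify_read, character(1))
  categories <- c("all_local", "all_foreign", "inconsistent",
                  "contains_other")
  counts <- table(factor(per_read, levels = categories))
  total <- length(per_read)
  out <- data.frame(
    category = categories,
    count = as.integer(counts),
    fraction = if (total > 0) as.integer(counts) / total else rep(0, 4),
    stringsAsFactors = FALSE
  )
  out$percent <- vapply(out$fraction, format_percent, character(1),
                        style = "decimals2")
  structure(out, n_reads = total, class = c("consistency_summary",
                                            "data.frame"))
}

#' @exportS3Method base::print
print.consistency_summary <- function(x, ...) {
  cat(sprintf("Multi-SNP read consistency over %d reads:\n",
              attr(x, "n_reads")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
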