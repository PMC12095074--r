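#' Read a per-site allele-depth table (TSV or VCF)
#'
#' The TSV dialect is tab-separated UTF-8 with a mandatory header row and
#' `#`-prefixed comment lines, one row per (sample, site), with raw counts
#' of all four nucleotides as produced by a pileup (e.g. `bcftools mpileup`
#' with per-sample allelic-depth annotations). VCF input (v4.2) must carry
#' an `AD` FORMAT field; only bi-allelic SNP records are used and the
#' number of skipped multi-allelic records is reported via a message and
#' the `"n_skipped"` attribute, because the audit restricts itself to
#' bi-allelic SNPs.
#'
#' Coordinates are 1-based inclusive in both formats. Sites with all-zero
#' counts are retained (flagged later by [site_totals()]), so that
#' zero-coverage SNPs stay visible to depth summaries.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample_id for VCF input without a `sample_id` column: use this id
#'   (default: the VCF sample name). For VCF, `gene_id` / allele roles are
#'   taken as REF = local, ALT = foreign; a `gene_id` may be supplied via
#'   the `GENE` INFO tag, else `NA`.
#' @return A `data.frame` of site counts (columns `sample_id, chrom, pos,
#'   gene_id, local_allele, foreign_allele, count_A..count_T`), with
#'   attribute `n_skipped` giving the number of non-bi-allelic records
#'   dropped.
#' @export
read_allele_table <- function(path, format = c("tsv", "vcf"),
                              sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_allele_tsv(path) else read_allele_vcf(path, sample_id)
}

read_allele_tsv <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  needed <- c("sample_id", "chrom", "pos", "gene_id",
              "local_allele", "foreign_allele", COUNT_COLS)
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("allele table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  cnt <- as.matrix(x[COUNT_COLS])
  if (any(cnt < 0)) {
    bad <- which(rowSums(cnt < 0) > 0)[1L]
    stop("negative nucleotide count at data line ", bad, " of ", path)
  }
  x$pos <- as.integer(x$pos)
  out <- x[needed]
  attr(out, "n_skipped") <- 0L
  out
}

read_allele_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- nchar(ref) == 1L & !grepl(",", alt, fixed = TRUE) &
    nchar(alt) == 1L & ref %in% NUCLEOTIDES & alt %in% NUCLEOTIDES
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-bi-allelic or non-SNP VCF record(s) skipped")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD (allelic depth) FORMAT field")
  vcf_sample <- colnames(ad)[1L]
  if (is.null(sample_id)) sample_id <- vcf_sample
  ad <- ad[, 1L]
  gene <- vcfR::extract.info(v, element = "GENE")
  if (is.null(gene)) gene <- rep(NA_character_, nrow(fix))

  keep <- which(snp)
  parts <- strsplit(ad[keep], ",", fixed = TRUE)
  ad_ref <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
  ad_alt <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  cnt <- matrix(0L, length(keep), 4L, dimnames = list(NULL, NUCLEOTIDES))
  cnt[cbind(seq_along(keep), match(ref[keep], NUCLEOTIDES))] <- ad_ref
  cnt[cbind(seq_along(keep), match(alt[keep], NUCLEOTIDES))] <- ad_alt
  out <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    gene_id = gene[keep],
    local_allele = ref[keep], foreign_allele = alt[keep],
    stringsAsFactors = FALSE
  )
  out[COUNT_COLS] <- as.data.frame(cnt)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a multi-SNP read observation table
#'
#' Long format, one row per (read, SNP position) observation:
#' `read_id, sample_id, chrom, pos, observed_base`. Observations are
#' classified against a site table into `local`, `foreign` or `other`.
#'
#' @param path TSV file (same dialect as [read_allele_table()]).
#' @param sites SNP site table used to classify each observed base.
#' @return A `data.frame` with an `observed_class` column appended.
#' @export
read_read_table <- function(path, sites) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("read_id", "sample_id", "chrom", "pos", "observed_base")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("read table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  classify_observations(x, sites)
}

#' Classify per-read base observations against a SNP site table
#'
#' Maps each observed base at a SNP position to `"local"`, `"foreign"`
#' or `"other"` according to the site's two alleles.
#'
#' @param obs `data.frame` with columns `chrom`, `pos`, `observed_base`
#'   (plus any read/sample identifiers, passed through).
#' @param sites SNP site table carrying `local_allele` /
#'   `foreign_allele` per position.
#' @return `obs` with an `observed_class` column appended.
#' @export
classify_observations <- function(obs, sites) {
  key <- paste(obs$chrom, obs$pos)
  skey <- paste(sites$chrom, sites$pos)
  idx <- match(key, skey)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " read observation(s) at positions absent from ",
         "the site table")
  }
  base <- toupper(obs$observed_base)
  obs$observed_class <- ifelse(
    base == sites$local_allele[idx], "local",
    ifelse(base == sites$foreign_allele[idx], "foreign", "other")
  )
  obs
}

#' Write a result table as delimited text
#'
#' Round-trip safe: integers survive bit-for-bit and reals to at least 15
#' significant digits, so a read-back reproduces every value to the 6
#' significant digits the package guarantees.
#'
#' @param records a `data.frame` of results (any stage's output table).
#' @param path output path (tab-separated, header row, no quoting).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  num <- vapply(records, is.double, logical(1))
  out <- records
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a list of candidate mobile gene ids
#'
#' One id per line; `#` comments and blank lines ignored. A header line
#' `gene_id` is tolerated.
#'
#' @param path text file of gene identifiers.
#' @return Character vector of unique ids in file order.
#' @export
read_mobile_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  x <- x[x != "gene_id"]
  unique(x)
}
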