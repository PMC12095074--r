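test_that("snp site validation enforces bi-allelic distinct alleles", {
  s <- snp_sites("Chr1", c(10L, 20L), "g1", c("A", "C"), c("G", "T"))
  expect_equal(nrow(s), 2L)
  expect_true(all(s$is_biallelic))
  expect_error(snp_sites("Chr1", 10L, "g1", "A", "A"), "must differ")
  expect_error(snp_sites("Chr1", 10L, "g1", "A", "N"), "A, C, G, T")
  expect_error(snp_sites("Chr1", 0L, "g1", "A", "G"), "1-based")
  expect_error(snp_sites("Chr1", c(5L, 5L), "g1", c("A", "A"), c("G", "T")),
               "duplicated")
})

test_that("site totals derive n and N under both total definitions", {
  # counts A=99, G=1, plus 2 reads on a third nucleotide
  sites <- make_sites(n_foreign = 1L, n_local = 99L, other = 2L)
  lpf <- site_totals(sites, "local_plus_foreign")
  expect_equal(lpf$n_foreign, 1L)
  expect_equal(lpf$n_total, 100L)
  all4 <- site_totals(sites, "all_nucleotides")
  expect_equal(all4$n_total, 102L)
  expect_false(lpf$zero_depth)
  # all-zero site retained but flagged
  z <- site_totals(make_sites(0L, 0L))
  expect_true(z$zero_depth)
})

test_that("neighbour totals rank the second most frequent nucleotide", {
  nb <- data.frame(sample_id = "s1", chrom = "Chr1", pos = c(5L, 6L, 7L),
                   count_A = c(98L, 50L, 0L), count_C = c(0L, 50L, 0L),
                   count_G = c(2L, 0L, 0L), count_T = c(0L, 0L, 0L))
  nt <- neighbour_totals(nb)
  expect_equal(nt$m_second, c(2L, 50L, 0L))
  expect_equal(nt$M_top2, c(100L, 100L, 0L))
  expect_equal(neighbour_fractions(nb), c(0.02, 0.5))
  expect_true(all(nt$m_second / pmax(nt$M_top2, 1) <= 0.5))
})

test_that("TSV reader maps counts and rejects malformed input", {
  sites <- make_sites(n_foreign = 1L, n_local = 99L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(sites, path)
  back <- read_allele_table(path, "tsv")
  expect_equal(site_totals(back)$n_foreign, 1L)
  expect_equal(site_totals(back)$n_total, 100L)

  # missing column named in the error
  bad <- sites[setdiff(names(sites), "local_allele")]
  write_results(bad, path)
  expect_error(read_allele_table(path, "tsv"), "local_allele")

  # negative count carries a line number
  neg <- sites
  neg$count_A <- -1L
  write_results(neg, path)
  expect_error(read_allele_table(path, "tsv"), "line 1")

  expect_error(read_allele_table("no/such/file.tsv", "tsv"), "not found")
})

test_that("VCF reader matches the TSV reader and skips multi-allelic records", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "Chr1\t100\t.\tA\tG\t.\tPASS\tGENE=g1\tAD:DP\t99,1:100",
    "Chr1\t200\t.\tC\tT\t.\tPASS\tGENE=g1\tAD:DP\t120,0:120",
    "Chr1\t300\t.\tG\tA,T\t.\tPASS\tGENE=g2\tAD:DP\t50,5,5:60"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  got <- read_allele_table(path, "vcf")
  expect_equal(attr(got, "n_skipped"), 1L)  # the tri-allelic record
  expect_equal(nrow(got), 2L)
  st <- site_totals(got)
  expect_equal(st$n_foreign, c(1L, 0L))
  expect_equal(st$n_total, c(100L, 120L))

  # equivalent TSV content produces identical SiteCounts
  tsv_equiv <- make_sites(n_foreign = c(1L, 0L), n_local = c(99L, 120L),
                          gene_id = "g1", sample_id = "s1",
                          local = c("A", "C"), foreign = c("G", "T"),
                          pos = c(100L, 200L))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_results(tsv_equiv, tpath)
  via_tsv <- read_allele_table(tpath, "tsv")
  cols <- c("chrom", "pos", "local_allele", "foreign_allele",
            paste0("count_", c("A", "C", "G", "T")))
  expect_equal(site_totals(via_tsv)[cols], site_totals(got)[cols],
               ignore_attr = TRUE)
})

test_that("write_results round-trips integers exactly and reals to 6 digits", {
  set.seed(11)
  df <- data.frame(
    id = sprintf("r%03d", 1:100),
    n = sample.int(1e6, 100),
    rate = runif(100) * 10^sample(-8:3, 100, replace = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(df, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back$n, df$n)
  expect_identical(back$id, df$id)
  expect_true(all(abs(back$rate - df$rate) <= 1e-6 * abs(df$rate)))
  # empty collection: header-only file
  write_results(df[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("homograft sample construction requires matching genotypes", {
  sites <- make_sites(1L, 99L)
  expect_error(
    graft_sample("h", "homograft", "root", "gtA", "gtB", sites = sites),
    "same genotype"
  )
  s <- make_hom(sites)
  expect_s3_class(s, "graft_sample")
  expect_output(print(s), "homograft")
})

test_that("analysis config validates and reads YAML with overrides", {
  cfg <- analysis_config()
  expect_equal(cfg$log_bf_threshold, 1)
  expect_equal(cfg$total_definition, "local_plus_foreign")
  expect_error(analysis_config(alt_error_prob = 0), "not TRUE")
  expect_error(analysis_config(prior_a = -1))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alt_error_prob: 0.001", "log_bf_threshold: 2"), path)
  got <- read_analysis_config(path)
  expect_equal(got$alt_error_prob, 0.001)
  expect_equal(got$log_bf_threshold, 2)
  # explicit overrides beat the file
  got2 <- read_analysis_config(path, log_bf_threshold = 3)
  expect_equal(got2$log_bf_threshold, 3)
  writeLines("no_such_field: 1", path)
  expect_error(read_analysis_config(path), "no_such_field")
})
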