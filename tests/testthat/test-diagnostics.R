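test_that("noiseless proportionality is recovered exactly", {
  x <- seq(100, 10000, length.out = 100)
  rep <- suppressWarnings(
    contamination_regression(data.frame(x = x, y = 0.01 * x))
  )
  expect_equal(rep$slope, 0.01, tolerance = 1e-10)
  expect_equal(rep$correlation, 1, tolerance = 1e-10)
  expect_equal(rep$intercept, 0, tolerance = 1e-8)
  expect_true(rep$contamination_suspected)
  expect_error(contamination_regression(data.frame(x = 1:5, y = 1:5)),
               "at least 10")
  expect_error(contamination_regression(data.frame(x = rep(1, 20),
                                                   y = rnorm(20))),
               "zero variance")
})

test_that("simulated contamination proportion is recovered within 20%", {
  c_true <- 0.005
  # moderate expression spread and site-level dispersion: the OLS slope
  # is attenuated by measurement noise in the source-count regressor
  # (errors in variables), so recovery is assessed where the estimator
  # is close to consistent
  ds <- simulate_experiment(simulation_config(
    n_genes = 700, snps_per_gene_mean = 3, contamination_c = c_true,
    expression_log_mean = log(1000), expression_log_sd = 0.75,
    depth_dispersion = 0.02, base_error_rate = 0.003, rng_seed = 404
  ))
  pairs <- contamination_pairs(ds$samples$het_root, ds$samples$het_shoot)
  expect_gte(nrow(pairs), 2000)
  rep <- contamination_regression(pairs)
  expect_lt(abs(rep$slope - c_true) / c_true, 0.2)
  expect_lt(rep$p_value, 1e-15)
  expect_true(rep$contamination_suspected)
})

test_that("independent noise rarely triggers the contamination flag", {
  flags <- vapply(1:60, function(seed) {
    set.seed(8000 + seed)
    pairs <- data.frame(x = rpois(200, 500), y = rpois(200, 2))
    contamination_regression(pairs)$contamination_suspected
  }, logical(1))
  expect_lte(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("regression attenuation on Poisson-noised counts vanishes with depth", {
  set.seed(12)
  c_true <- 0.1
  slope_at <- function(depth) {
    mu <- runif(4000, 0, depth)       # latent per-site expression
    x <- rpois(4000, mu)              # noisily measured regressor
    y <- rpois(4000, c_true * mu)     # foreign counts track the latent level
    contamination_regression(data.frame(x, y))$slope
  }
  # errors-in-variables attenuation factor is roughly depth/(depth + 6)
  # for uniform(0, depth) expression, so bias shrinks as depth grows
  err_lo <- abs(slope_at(30) - c_true)
  err_hi <- abs(slope_at(5000) - c_true)
  expect_lt(err_hi, c_true * 0.03)
  expect_lt(err_hi, err_lo)
  expect_gt(err_lo, c_true * 0.08)  # the bias is real at shallow depth
})

test_that("pseudo-heterozygosity flags intermediate fractions only", {
  bg <- estimate_background(make_hom(make_sites(10L, 9990L)))
  hom <- make_hom(make_sites(n_foreign = c(40L, 1L), n_local = c(60L, 999L),
                             gene_id = c("gA", "gB")))
  fl <- flag_pseudohet(hom, bg, min_depth = 50)
  expect_true(fl$sites$flagged[fl$sites$gene_id == "gA"])   # n=40/100
  expect_false(fl$sites$flagged[fl$sites$gene_id == "gB"])  # noise scale
  expect_equal(fl$genes, "gA")
  expect_error(flag_pseudohet(make_het(make_sites(1L, 9L)), bg),
               "homograft")
})

test_that("simulated pseudo-het loci are recovered with few false flags", {
  ds <- simulate_experiment(simulation_config(
    n_genes = 300, pseudo_het_fraction = 0.1, pseudo_het_level = 0.4,
    expression_log_mean = log(500), expression_log_sd = 0.5,
    base_error_rate = 0.003, rng_seed = 500
  ))
  hom <- ds$samples$hom_root
  bg <- estimate_background(hom)
  fl <- flag_pseudohet(hom, bg, min_depth = 200)
  truth_ph <- ds$truth$gene_id[ds$truth$label == "pseudo_het"]
  deep <- fl$sites
  ph_sites <- deep[deep$gene_id %in% truth_ph, ]
  expect_gte(mean(ph_sites$flagged), 0.9)
  expect_lte(mean(deep$flagged[!deep$gene_id %in% truth_ph]), 0.01)
})

test_that("a clean homograft is never flagged pseudo-heterozygous", {
  false_flags <- vapply(1:40, function(seed) {
    ds <- simulate_experiment(simulation_config(
      n_genes = 40, base_error_rate = 0.003,
      expression_log_mean = log(300), rng_seed = 9000 + seed
    ))
    hom <- ds$samples$hom_root
    sum(flag_pseudohet(hom, estimate_background(hom),
                       min_depth = 50)$sites$flagged)
  }, numeric(1))
  expect_lte(sum(false_flags), 1)
})

test_that("mobile-list intersection is a plain symmetric set operation", {
  expect_equal(nrow(intersect_mobile_list(c("g1", "g2"), c("g3", "g4"))), 0)
  got <- intersect_mobile_list(c("g1", "g2"), c("g2", "g3"))
  expect_equal(got$gene_id, "g2")
  expect_equal(attr(got, "n_flagged"), 2L)
  # symmetry at the gene-id level
  expect_equal(intersect_mobile_list(c("g2", "g3"), c("g1", "g2"))$gene_id,
               got$gene_id)
})

test_that("injected pseudo-het genes are recovered from a mobile list", {
  ds <- simulate_experiment(simulation_config(
    n_genes = 100, pseudo_het_fraction = 0.1, pseudo_het_level = 0.4,
    expression_log_mean = log(600), expression_log_sd = 0.3,
    base_error_rate = 0.003, rng_seed = 501
  ))
  hom <- ds$samples$hom_root
  fl <- flag_pseudohet(hom, estimate_background(hom), min_depth = 100)
  truth_ph <- sort(ds$truth$gene_id[ds$truth$label == "pseudo_het"])
  # a "published mobile list" containing the pseudo-het genes plus others
  mobile_list <- c(truth_ph, setdiff(ds$truth$gene_id, truth_ph)[1:90])
  got <- intersect_mobile_list(fl, mobile_list)
  expect_equal(got$gene_id, truth_ph)
})
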