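# Transition partner used by the concentrated error mode (the classic
# reverse-transcription-style bias: every miscall lands on one nucleotide).
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulation configuration for a synthetic graft experiment
#'
#' The generator produces a homograft pair and a heterograft pair
#' (root + shoot each) with truth labels, reproducing the statistical
#' structure the audit assumes: per-site read depth overdispersed around a
#' log-normal per-gene expression level, foreign-allele counts binomial in
#' the per-base error rate and the true foreign-molecule fraction, pure
#' error at neighbouring positions, and per-read molecule origins for
#' multi-SNP reads.
#'
#' @param n_genes number of simulated genes.
#' @param snps_per_gene_mean mean SNPs per gene; each gene gets
#'   `1 + Poisson(snps_per_gene_mean - 1)` sites.
#' @param expression_log_mean,expression_log_sd log-normal parameters of
#'   the per-gene, per-tissue expected site depth (reads).
#' @param depth_dispersion negative-binomial overdispersion of per-site
#'   depth around the gene mean (`size = 1/depth_dispersion`; 0 gives
#'   Poisson).
#' @param base_error_rate per-base substitution probability `e`; with
#'   uniform misincorporation a specific wrong nucleotide is seen with
#'   probability `e/3`.
#' @param mobile_fraction_genes proportion of genes truly mobile.
#' @param mobile_phi foreign-molecule fraction at sites of mobile genes in
#'   heterograft samples.
#' @param contamination_c proportionality constant linking source-tissue
#'   expression to contaminating foreign molecules; when positive, every
#'   gene that is neither mobile nor pseudo-heterozygous receives a foreign
#'   fraction `c*src/(loc + c*src)` in the heterograft (contamination is a
#'   whole-transcriptome mechanism) and the label `contaminated`.
#' @param pseudo_het_fraction proportion of genes whose loci are
#'   pseudo-heterozygous (copy-number-style mismapping); their sites show
#'   `pseudo_het_level` in homografts and heterografts alike.
#' @param pseudo_het_level expected alternative-allele fraction at
#'   pseudo-heterozygous loci.
#' @param multi_snp_read_rate expected multi-SNP reads per unit of site
#'   depth for genes with at least two SNPs (0 disables read emission).
#' @param neighbour_window half-width of the emitted neighbour-position
#'   window around each SNP.
#' @param read_length nominal read length (bp); controls SNP placement
#'   within a gene so that two SNPs can share a read.
#' @param error_mode `"uniform"` (miscalls uniform over the three other
#'   nucleotides) or `"concentrated"` (all miscalls land on the transition
#'   partner and SNP alleles are transitions, so the SNP and neighbour
#'   error mechanisms coincide exactly — the mode used for null
#'   calibration of the distribution tests).
#' @param rng_seed integer master seed; per-stage substreams are derived
#'   from it by fixed offsets, so equal seeds give identical datasets.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L,
                              snps_per_gene_mean = 3,
                              expression_log_mean = log(100),
                              expression_log_sd = 1,
                              depth_dispersion = 0.1,
                              base_error_rate = 0.003,
                              mobile_fraction_genes = 0,
                              mobile_phi = 0.05,
                              contamination_c = 0,
                              pseudo_het_fraction = 0,
                              pseudo_het_level = 0.4,
                              multi_snp_read_rate = 0,
                              neighbour_window = 5L,
                              read_length = 150L,
                              error_mode = c("uniform", "concentrated"),
                              rng_seed = 1L) {
  error_mode <- match.arg(error_mode)
  if (n_genes < 1) stop("n_genes must be at least 1")
  probs <- c(mobile_fraction_genes, pseudo_het_fraction, pseudo_het_level,
             mobile_phi, base_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (base_error_rate > 0.05) {
    stop("base_error_rate above 0.05 is outside the regime this generator ",
         "emulates")
  }
  if (mobile_fraction_genes > 0 && mobile_phi <= base_error_rate / 3) {
    warning("mobile_phi <= base_error_rate/3: mobile genes are ",
            "indistinguishable from noise (power ~ 0)")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      snps_per_gene_mean = snps_per_gene_mean,
      expression_log_mean = expression_log_mean,
      expression_log_sd = expression_log_sd,
      depth_dispersion = depth_dispersion,
      base_error_rate = base_error_rate,
      mobile_fraction_genes = mobile_fraction_genes,
      mobile_phi = mobile_phi,
      contamination_c = contamination_c,
      pseudo_het_fraction = pseudo_het_fraction,
      pseudo_het_level = pseudo_het_level,
      multi_snp_read_rate = multi_snp_read_rate,
      neighbour_window = as.integer(neighbour_window),
      read_length = as.integer(read_length),
      error_mode = error_mode,
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_config"
  )
}

# Derived substream seed for stage k; keeps every derived seed a valid
# 32-bit integer.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 10007) %% (2^31 - 1))
}

# Per-nucleotide observation probabilities for one site: a fraction phi of
# molecules carries the foreign allele, each sequenced base keeps its
# template with probability 1-e and otherwise miscalls per error_mode.
site_base_probs <- function(local, foreign, phi, e, error_mode) {
  err_row <- function(template) {
    p <- setNames(numeric(4), NUCLEOTIDES)
    if (error_mode == "uniform") {
      p[] <- e / 3
      p[template] <- 1 - e
    } else {
      p[template] <- 1 - e
      p[TRANSITION[[template]]] <- p[TRANSITION[[template]]] + e
    }
    p
  }
  (1 - phi) * err_row(local) + phi * err_row(foreign)
}

# Vectorised multinomial count draws: one row of counts per site.
draw_counts <- function(depth, prob_matrix) {
  n <- length(depth)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, NUCLEOTIDES))
  pos <- depth > 0
  if (any(pos)) {
    out[pos, ] <- t(vapply(
      which(pos),
      function(i) rmultinom(1L, depth[i], prob_matrix[i, ])[, 1L],
      integer(4)
    ))
  }
  out
}

#' Simulate a synthetic graft experiment
#'
#' Generates four samples — homograft root/shoot and heterograft
#' root/shoot — over a shared SNP map, with per-gene truth labels
#' (`noise_only`, `mobile`, `contaminated` or `pseudo_het`) and the true
#' foreign fractions, so false-positive rates and power of every audit
#' stage can be measured against known ground truth.
#'
#' For each site and sample the depth `N` is negative-binomial around the
#' gene's tissue expression and the foreign-allele count is binomial with
#' success probability `e/3 + (1 - e/3 - e) * phi`, where `phi` is the true
#' foreign-molecule fraction of that gene in that sample (0 for noise-only
#' genes and for all genes in homografts, except pseudo-heterozygous loci,
#' which show their level in both graft types). Miscalls landing on the
#' remaining nucleotides populate the "other" counts. Neighbour positions
#' receive pure sequencing error at the same depth distribution. Multi-SNP
#' reads draw the molecule origin once per read, then per-base errors
#' independently.
#'
#' @param config a [simulation_config()].
#' @return An object of class `synthetic_dataset`: a list with `samples`
#'   (named list of [graft_sample()]: `hom_root`, `hom_shoot`, `het_root`,
#'   `het_shoot`), `truth` (`data.frame` of `gene_id, label, phi, c`),
#'   `site_map`, and the `config`.
#' @examples
#' ds <- simulate_experiment(simulation_config(n_genes = 20, rng_seed = 7))
#' ds$samples$het_root
#' table(ds$truth$label)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  e <- cfg$base_error_rate

  ## stage 1: genome structure, labels, expression
  set.seed(stage_seed(cfg$rng_seed, 1L))
  gene_id <- sprintf("G%05d", seq_len(cfg$n_genes))
  k_snps <- 1L + rpois(cfg$n_genes, max(cfg$snps_per_gene_mean - 1, 0))

  label <- rep("noise_only", cfg$n_genes)
  n_ph <- round(cfg$pseudo_het_fraction * cfg$n_genes)
  n_mob <- round(cfg$mobile_fraction_genes * cfg$n_genes)
  shuffled <- sample(cfg$n_genes)
  if (n_ph > 0) label[shuffled[seq_len(n_ph)]] <- "pseudo_het"
  if (n_mob > 0) label[shuffled[n_ph + seq_len(n_mob)]] <- "mobile"
  if (cfg$contamination_c > 0) {
    label[label == "noise_only"] <- "contaminated"
  }

  # per-gene, per-tissue expected site depth
  expr <- matrix(
    rlnorm(2L * cfg$n_genes, cfg$expression_log_mean, cfg$expression_log_sd),
    ncol = 2L, dimnames = list(gene_id, c("root", "shoot"))
  )

  # SNP placement: each gene occupies its own coordinate block; SNPs are
  # spaced below read_length so two can share a read
  site_gene <- rep(seq_len(cfg$n_genes), k_snps)
  offset <- unlist(lapply(k_snps, function(k) {
    cumsum(sample(seq(10L, max(11L, cfg$read_length %/% 2)), k, replace = TRUE))
  }))
  site_map <- data.frame(
    chrom = "Chr1",
    pos = (site_gene - 1L) * 100000L + offset,
    gene_id = gene_id[site_gene],
    stringsAsFactors = FALSE
  )
  site_map$local_allele <- sample(NUCLEOTIDES, nrow(site_map), replace = TRUE)
  if (cfg$error_mode == "concentrated") {
    site_map$foreign_allele <- TRANSITION[site_map$local_allele]
  } else {
    shift <- sample(1:3, nrow(site_map), replace = TRUE)
    site_map$foreign_allele <- NUCLEOTIDES[
      (match(site_map$local_allele, NUCLEOTIDES) - 1L + shift) %% 4L + 1L
    ]
  }
  rownames(site_map) <- NULL
  validate_snp_sites(cbind(site_map, is_biallelic = TRUE))

  truth <- data.frame(
    gene_id = gene_id, label = label,
    phi = ifelse(label == "mobile", cfg$mobile_phi,
                 ifelse(label == "pseudo_het", cfg$pseudo_het_level, 0)),
    c = ifelse(label == "contaminated", cfg$contamination_c, 0),
    stringsAsFactors = FALSE
  )

  # true foreign fraction of gene g in (graft_type, tissue)
  phi_eff <- function(g, graft_type, tissue) {
    lab <- label[g]
    out <- numeric(length(g))
    out[lab == "pseudo_het"] <- cfg$pseudo_het_level
    if (graft_type == "heterograft") {
      out[lab == "mobile"] <- cfg$mobile_phi
      if (cfg$contamination_c > 0) {
        src <- expr[cbind(g, match(setdiff(c("root", "shoot"), tissue),
                                   c("root", "shoot")))]
        loc <- expr[cbind(g, match(tissue, c("root", "shoot")))]
        ctm <- lab == "contaminated"
        out[ctm] <- (cfg$contamination_c * src / (loc + cfg$contamination_c * src))[ctm]
      }
    }
    out
  }

  samples <- list(
    hom_root = list(graft_type = "homograft", tissue = "root", k = 2L),
    hom_shoot = list(graft_type = "homograft", tissue = "shoot", k = 3L),
    het_root = list(graft_type = "heterograft", tissue = "root", k = 4L),
    het_shoot = list(graft_type = "heterograft", tissue = "shoot", k = 5L)
  )

  out_samples <- lapply(names(samples), function(nm) {
    sm <- samples[[nm]]
    set.seed(stage_seed(cfg$rng_seed, sm$k))
    mu <- expr[cbind(site_gene, match(sm$tissue, c("root", "shoot")))]
    depth <- draw_depth(mu, cfg$depth_dispersion)
    phi <- phi_eff(site_gene, sm$graft_type, sm$tissue)
    pm <- t(mapply(site_base_probs,
                   site_map$local_allele, site_map$foreign_allele,
                   phi, MoreArgs = list(e = e, error_mode = cfg$error_mode)))
    cnt <- draw_counts(depth, pm)
    sites <- data.frame(
      sample_id = nm,
      site_map[c("chrom", "pos", "gene_id", "local_allele",
                 "foreign_allele")],
      stringsAsFactors = FALSE
    )
    sites[COUNT_COLS] <- as.data.frame(cnt)
    rownames(sites) <- NULL

    neighbours <- simulate_neighbours(nm, site_map, mu, cfg)
    reads <- simulate_reads(nm, site_map, site_gene, mu, phi, cfg)

    graft_sample(
      sample_id = nm, graft_type = sm$graft_type, tissue = sm$tissue,
      genotype_sampled = "genotypeA",
      genotype_partner = if (sm$graft_type == "homograft") "genotypeA"
                         else "genotypeB",
      sites = sites, neighbours = neighbours, reads = reads
    )
  })
  names(out_samples) <- names(samples)

  structure(
    list(samples = out_samples, truth = truth, site_map = site_map,
         config = cfg),
    class = "synthetic_dataset"
  )
}

draw_depth <- function(mu, dispersion) {
  if (dispersion > 0) {
    rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  } else {
    rpois(length(mu), mu)
  }
}

# Neighbour positions carry the reference base of a single genotype at
# non-SNP coordinates, so regardless of molecule origin the counts are
# template + pure sequencing error.
simulate_neighbours <- function(sample_id, site_map, mu, cfg) {
  w <- cfg$neighbour_window
  offs <- setdiff(seq(-w, w), 0L)
  n_sites <- nrow(site_map)
  pos <- rep(site_map$pos, each = length(offs)) + offs
  chrom <- rep(site_map$chrom, each = length(offs))
  mu_n <- rep(mu, each = length(offs))
  keep <- !(paste(chrom, pos) %in% paste(site_map$chrom, site_map$pos)) &
    !duplicated(paste(chrom, pos))
  pos <- pos[keep]; chrom <- chrom[keep]; mu_n <- mu_n[keep]

  template <- sample(NUCLEOTIDES, length(pos), replace = TRUE)
  depth <- draw_depth(mu_n, cfg$depth_dispersion)
  pm <- t(vapply(template, function(tm) {
    site_base_probs(tm, TRANSITION[[tm]], 0, cfg$base_error_rate,
                    cfg$error_mode)
  }, numeric(4)))
  cnt <- draw_counts(depth, pm)
  out <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  out[COUNT_COLS] <- as.data.frame(cnt)
  rownames(out) <- NULL
  out
}

# Multi-SNP reads: molecule origin drawn once per read, per-base errors
# independent given the origin.
simulate_reads <- function(sample_id, site_map, site_gene, mu, phi, cfg) {
  if (cfg$multi_snp_read_rate <= 0) return(NULL)
  genes <- unique(site_gene[duplicated(site_gene)])
  if (!length(genes)) return(NULL)
  gene_mu <- vapply(genes, function(g) mean(mu[site_gene == g]), numeric(1))
  n_reads <- rpois(length(genes), cfg$multi_snp_read_rate * gene_mu)
  total <- sum(n_reads)
  if (total == 0) return(NULL)

  read_gene <- rep(genes, n_reads)
  gene_phi <- vapply(genes, function(g) phi[match(g, site_gene)], numeric(1))
  foreign_origin <- rbinom(total, 1L, rep(gene_phi, n_reads)) == 1L

  # choose two distinct sites of the read's gene
  first_idx <- match(read_gene, site_gene)
  k_of <- tabulate(site_gene)[read_gene]
  i1 <- floor(runif(total) * k_of)
  i2 <- floor(runif(total) * (k_of - 1))
  i2 <- i2 + (i2 >= i1)
  rows <- c(first_idx + i1, first_idx + i2)

  origin2 <- rep(foreign_origin, 2L)
  template <- ifelse(origin2, site_map$foreign_allele[rows],
                     site_map$local_allele[rows])
  observed <- apply_base_errors(template, cfg$base_error_rate, cfg$error_mode)

  data.frame(
    read_id = rep(sprintf("%s_r%07d", sample_id, seq_len(total)), 2L),
    sample_id = sample_id,
    chrom = site_map$chrom[rows],
    pos = site_map$pos[rows],
    observed_base = observed,
    stringsAsFactors = FALSE
  )
}

apply_base_errors <- function(template, e, error_mode) {
  n <- length(template)
  err <- runif(n) < e
  out <- template
  if (any(err)) {
    if (error_mode == "uniform") {
      shift <- sample(1:3, sum(err), replace = TRUE)
      out[err] <- NUCLEOTIDES[
        (match(template[err], NUCLEOTIDES) - 1L + shift) %% 4L + 1L
      ]
    } else {
      out[err] <- TRANSITION[template[err]]
    }
  }
  out
}

#' @exportS3Method base::print
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes, %d SNP sites, seed %d\n",
              nrow(x$truth), nrow(x$site_map), x$config$rng_seed))
  print(table(x$truth$label))
  invisible(x)
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Emits `samples.tsv` (sample metadata), `sites.tsv` (stacked per-sample
#' allele tables), `truth.tsv`, and — when present — `neighbours.tsv` and
#' `reads.tsv`. The files parse back through [read_fixture()] into an
#' equal dataset, and equal seeds produce byte-identical files.
#'
#' @param dataset a [simulate_experiment()] result.
#' @param dir output directory.
#' @param overwrite refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("directory ", dir, " is not empty; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(dataset$samples, function(s) {
    data.frame(sample_id = s$sample_id, graft_type = s$graft_type,
               tissue = s$tissue, genotype_sampled = s$genotype_sampled,
               genotype_partner = s$genotype_partner,
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  write_results(meta, file.path(dir, "samples.tsv"))
  write_results(do.call(rbind, lapply(dataset$samples, `[[`, "sites")),
                file.path(dir, "sites.tsv"))
  write_results(dataset$truth, file.path(dir, "truth.tsv"))
  neigh <- do.call(rbind, lapply(dataset$samples, `[[`, "neighbours"))
  if (!is.null(neigh) && nrow(neigh)) {
    write_results(neigh, file.path(dir, "neighbours.tsv"))
  }
  reads <- do.call(rbind, lapply(dataset$samples, `[[`, "reads"))
  if (!is.null(reads) && nrow(reads)) {
    write_results(reads, file.path(dir, "reads.tsv"))
  }
  invisible(dir)
}

#' Read back a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing `samples.tsv`, `sites.tsv`,
#'   `truth.tsv` and optionally `neighbours.tsv` / `reads.tsv`.
#' @return A list with `samples` (named list of [graft_sample()]) and
#'   `truth`.
#' @export
read_fixture <- function(dir) {
  meta <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  sites <- read_allele_table(file.path(dir, "sites.tsv"), "tsv")
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  neigh_path <- file.path(dir, "neighbours.tsv")
  neigh <- if (file.exists(neigh_path)) {
    read.delim(neigh_path, stringsAsFactors = FALSE)
  }
  reads_path <- file.path(dir, "reads.tsv")
  reads <- if (file.exists(reads_path)) {
    read.delim(reads_path, stringsAsFactors = FALSE)
  }
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$sample_id[i]
    graft_sample(
      sample_id = id, graft_type = meta$graft_type[i],
      tissue = meta$tissue[i],
      genotype_sampled = meta$genotype_sampled[i],
      genotype_partner = meta$genotype_partner[i],
      sites = sites[sites$sample_id == id, , drop = FALSE],
      neighbours = if (!is.null(neigh)) {
        n <- neigh[neigh$sample_id == id, , drop = FALSE]
        if (nrow(n)) n else NULL
      },
      reads = if (!is.null(reads)) {
        r <- reads[reads$sample_id == id, , drop = FALSE]
        if (nrow(r)) r else NULL
      }
    )
  })
  names(samples) <- meta$sample_id
  list(samples = samples, truth = truth)
}
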