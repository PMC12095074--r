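#' Build (source expression, sampled foreign count) pairs per SNP
#'
#' For contamination analysis: at each shared SNP, pairs the total read
#' count in the source tissue's own sample (`x`, endogenous expression)
#' with the foreign-allele read count observed in the sampled tissue
#' (`y`). Contamination — or non-selective transport of the whole
#' transcriptome — makes `y` a constant proportion of `x`.
#'
#' @param sampled [graft_sample()] of the sampled tissue (heterograft).
#' @param source [graft_sample()] of the graft partner tissue.
#' @param total_definition see [site_totals()].
#' @return `data.frame` of `chrom, pos, gene_id, x, y` over shared sites.
#' @export
contamination_pairs <- function(sampled, source,
                                total_definition = "local_plus_foreign") {
  st_s <- site_totals(sampled$sites, total_definition)
  st_o <- site_totals(source$sites, total_definition)
  idx <- match(paste(st_s$chrom, st_s$pos), paste(st_o$chrom, st_o$pos))
  keep <- !is.na(idx)
  data.frame(
    chrom = st_s$chrom[keep], pos = st_s$pos[keep],
    gene_id = st_s$gene_id[keep],
    x = st_o$n_total[idx[keep]],
    y = st_s$n_foreign[keep],
    stringsAsFactors = FALSE
  )
}

#' Regress sampled-tissue foreign counts on source-tissue expression
#'
#' Ordinary least squares of `y` (foreign-allele reads at a SNP in the
#' sampled tissue) on `x` (read depth at the same SNP in the source
#' tissue). A strong positive linear relationship means a constant
#' proportion of the source transcriptome appears as foreign reads —
#' indicative of contamination, though transport of the whole
#' transcriptome is observationally equivalent; the report therefore
#' flags contamination as *suspected*, never as established. The
#' through-origin slope is reported alongside, as the estimate of the
#' transcriptome proportion under the proportional model.
#'
#' @param pairs `data.frame` with columns `x` and `y` (see
#'   [contamination_pairs()]).
#' @param min_depth sites with `x < min_depth` are dropped before the
#'   fit.
#' @param alpha significance level of the slope test used for the flag.
#' @return An object of class `contamination_report`: `n_sites`,
#'   `slope`, `intercept`, `slope_origin`, `correlation`, `p_value`,
#'   `estimated_proportion` (the through-origin slope) and
#'   `contamination_suspected`.
#' @export
contamination_regression <- function(pairs, min_depth = 1L, alpha = 0.05) {
  stopifnot(all(c("x", "y") %in% names(pairs)))
  pairs <- pairs[pairs$x >= min_depth & complete.cases(pairs[c("x", "y")]), ,
                 drop = FALSE]
  if (nrow(pairs) < 10) {
    stop("need at least 10 (source expression, foreign count) pairs ",
         "after depth filtering")
  }
  if (var(pairs$x) == 0) stop("source expression has zero variance")
  fit <- lm(y ~ x, data = pairs)
  fit0 <- lm(y ~ x + 0, data = pairs)
  sm <- summary(fit)
  slope <- unname(coef(fit)["x"])
  p_slope <- sm$coefficients["x", "Pr(>|t|)"]
  structure(
    list(
      n_sites = nrow(pairs),
      slope = slope,
      intercept = unname(coef(fit)["(Intercept)"]),
      slope_origin = unname(coef(fit0)["x"]),
      correlation = unname(cor(pairs$x, pairs$y)),
      p_value = p_slope,
      estimated_proportion = unname(coef(fit0)["x"]),
      contamination_suspected = p_slope < alpha && slope > 0,
      alpha = alpha
    ),
    class = "contamination_report"
  )
}

#' @exportS3Method base::print
print.contamination_report <- function(x, ...) {
  cat(sprintf("Contamination regression over %d SNP sites\n", x$n_sites))
  cat(sprintf("  slope %.4g (intercept %.4g), through-origin slope %.4g\n",
              x$slope, x$intercept, x$slope_origin))
  cat(sprintf("  r = %.4f, slope P = %.3g\n", x$correlation, x$p_value))
  cat(if (x$contamination_suspected) {
    paste0("  constant transcriptome proportion detected: contamination\n",
           "  suspected (whole-transcriptome transport is observationally\n",
           "  equivalent and cannot be excluded)\n")
  } else {
    "  no constant-proportion relationship detected\n"
  })
  invisible(x)
}

#' Flag pseudo-heterozygous loci in a homograft
#'
#' Copy-number variation and read mismapping create loci where a single
#' genotype shows a stable intermediate alternative-allele fraction —
#' pseudo-heterozygosity — which mimics a second genotype. A site is
#' flagged when its depth reaches `min_depth`, its alternative-allele
#' fraction lies inside `fraction_band`, and the binomial tail of its
#' count under the homograft background rate falls below `tail_p`
#' (i.e. noise cannot plausibly explain it). A gene is pseudo-het if any
#' of its sites is flagged.
#'
#' @param hom a homograft [graft_sample()].
#' @param background [estimate_background()] result for the same
#'   genotype.
#' @param fraction_band numeric length-2 interval of alt fractions
#'   regarded as heterozygosity-like (default `c(0.15, 0.85)`, wide
#'   enough for copy-number ratios while excluding pure noise and fixed
#'   differences).
#' @param min_depth minimum site depth.
#' @param tail_p binomial-tail cutoff under the background rate.
#' @param total_definition see [site_totals()].
#' @return A list: `sites` (`data.frame` with `alt_fraction`, `tail_p`
#'   and `flagged` per qualifying site) and `genes` (character vector of
#'   pseudo-het gene ids).
#' @export
flag_pseudohet <- function(hom, background,
                           fraction_band = c(0.15, 0.85),
                           min_depth = 50L, tail_p = 1e-6,
                           total_definition = "local_plus_foreign") {
  stopifnot(inherits(hom, "graft_sample"),
            inherits(background, "noise_estimate"),
            length(fraction_band) == 2, fraction_band[1] < fraction_band[2])
  if (hom$graft_type != "homograft") {
    stop("pseudo-heterozygosity is screened in homografts")
  }
  st <- site_totals(hom$sites, total_definition)
  st <- st[st$n_total >= min_depth, , drop = FALSE]
  st$alt_fraction <- st$n_foreign / st$n_total
  st$tail_p <- binomial_tail(st$n_foreign, st$n_total,
                             background$rate_point)
  st$flagged <- st$alt_fraction >= fraction_band[1] &
    st$alt_fraction <= fraction_band[2] &
    st$tail_p < tail_p
  keep <- c("sample_id", "chrom", "pos", "gene_id", "n_foreign", "n_total",
            "alt_fraction", "tail_p", "flagged")
  list(
    sites = st[keep],
    genes = sort(unique(st$gene_id[st$flagged]))
  )
}

#' Intersect pseudo-heterozygosity flags with a mobile-gene list
#'
#' Genes that are both flagged pseudo-heterozygous and annotated mobile
#' are the likely mismapping-driven false positives among published
#' mobile transcripts.
#'
#' @param flags result of [flag_pseudohet()] (or a character vector of
#'   flagged gene ids).
#' @param mobile_list character vector of mobile gene ids.
#' @return A `data.frame` of the intersection (sorted, order-stable) with
#'   attribute counts `n_flagged`, `n_mobile`.
#' @export
intersect_mobile_list <- function(flags, mobile_list) {
  flagged <- if (is.list(flags)) flags$genes else as.character(flags)
  if (!length(flagged) || !length(mobile_list)) {
    both <- character(0)
  } else {
    both <- sort(intersect(flagged, unique(mobile_list)))
  }
  out <- data.frame(gene_id = both, stringsAsFactors = FALSE)
  attr(out, "n_flagged") <- length(unique(flagged))
  attr(out, "n_mobile") <- length(unique(mobile_list))
  out
}
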