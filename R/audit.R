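#' Run the full mobility-evidence audit
#'
#' Executes the recommended checks in order against one heterograft /
#' homograft pair: homograft background estimation and the foreign-read
#' fraction comparison; SNP-versus-neighbour distribution comparison;
#' multi-SNP read consistency; Bayes-factor mobility classification with
#' the noise-explained summary; replicate overlap when several
#' heterografts are supplied; contamination regression (when a source
#' sample is given); and pseudo-heterozygosity flagging. Stage failures
#' are caught and recorded — the report is always produced, with failing
#' stages marked.
#'
#' @param het a heterograft [graft_sample()] or list of replicates.
#' @param hom a homograft [graft_sample()] or list (first is used for
#'   background and classification).
#' @param config an [analysis_config()].
#' @param source_sample optional [graft_sample()] of the graft partner
#'   tissue for the contamination regression.
#' @param mobile_list optional gene-id vector for the noise-explained
#'   summary and pseudo-het intersection (default: all genes called
#'   mobile candidates).
#' @param pseudohet_min_depth minimum depth for pseudo-het screening.
#' @return An object of class `audit_report`: per-stage results under
#'   `stages`, a `status` vector (`"ok"`, `"warn"` or `"error"` per
#'   stage), and the `config` (including seed) embedded so the run can be
#'   reproduced exactly.
#' @export
run_audit <- function(het, hom, config = analysis_config(),
                      source_sample = NULL, mobile_list = NULL,
                      pseudohet_min_depth = 50L) {
  hets <- if (inherits(het, "graft_sample")) list(het) else het
  homs <- if (inherits(hom, "graft_sample")) list(hom) else hom
  if (!length(hets)) stop("at least one heterograft sample is required")
  if (!length(homs)) {
    stop("a homograft sample is required: the background noise rate ",
         "(foreign-read fraction under the null) cannot be estimated ",
         "without one")
  }
  het1 <- hets[[1L]]; hom1 <- homs[[1L]]
  stages <- list(); status <- character(0)
  run_stage <- function(name, expr) {
    warn_msgs <- character(0)
    res <- tryCatch(
      withCallingHandlers(
        list(value = expr, status = "ok"),
        warning = function(w) {
          warn_msgs <<- c(warn_msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) list(value = NULL, status = "error",
                               message = conditionMessage(e))
    )
    if (res$status == "ok" && length(warn_msgs)) {
      res$status <- "warn"
      res$message <- paste(warn_msgs, collapse = "; ")
    }
    stages[[name]] <<- res
    status[name] <<- res$status
    invisible(res)
  }

  run_stage("background", estimate_background(
    hom1, config$prior_a, config$prior_b, config$total_definition
  ))
  run_stage("foreign_fraction", compare_foreign_fractions(
    het1, hom1, config$total_definition
  ))
  run_stage("distribution", {
    if (is.null(het1$neighbours)) {
      stop("heterograft has no neighbour-position counts")
    }
    compare_distributions(
      snp_fractions(het1$sites, 1L, config$total_definition),
      neighbour_fractions(het1$neighbours, 1L),
      alpha = config$alpha
    )
  })
  run_stage("read_consistency", {
    if (is.null(het1$reads)) stop("heterograft has no multi-SNP reads")
    consistency_summary(classify_observations(het1$reads, het1$sites))
  })
  run_stage("classification", classify_transcripts(het1, hom1, config))
  run_stage("noise_explained", {
    calls <- stages$classification$value
    if (is.null(calls)) stop("classification stage failed")
    ref <- mobile_list
    if (is.null(ref)) {
      ref <- calls$gene_id[calls$classification == "mobile_candidate"]
    }
    if (!length(ref)) {
      list(n_noise_consistent = 0L, n_listed = 0L,
           percent_explained = NA_real_)
    } else {
      summarize_noise_explained(calls, ref)
    }
  })
  if (length(hets) >= 2) {
    run_stage("replicate_overlap", replicate_overlap(
      lapply(hets, classify_transcripts, hom = hom1, config = config)
    ))
  }
  run_stage("pseudo_het", {
    bg <- stages$background$value
    if (is.null(bg)) stop("background stage failed")
    flags <- flag_pseudohet(hom1, bg, min_depth = pseudohet_min_depth,
                            total_definition = config$total_definition)
    flags$mobile_intersection <- if (!is.null(mobile_list)) {
      intersect_mobile_list(flags, mobile_list)
    }
    flags
  })
  if (!is.null(source_sample)) {
    run_stage("contamination", {
      pairs <- contamination_pairs(het1, source_sample,
                                   config$total_definition)
      # pseudo-heterozygous loci carry large foreign counts unrelated to
      # source expression; screening them out first keeps the regression
      # a test of the contamination/whole-transcriptome hypothesis
      ph_genes <- stages$pseudo_het$value$genes
      if (length(ph_genes)) {
        pairs <- pairs[!pairs$gene_id %in% ph_genes, , drop = FALSE]
      }
      contamination_regression(pairs, alpha = config$alpha)
    })
  }

  structure(
    list(stages = stages, status = status, config = config),
    class = "audit_report"
  )
}

#' @exportS3Method base::print
print.audit_report <- function(x, ...) {
  cat("Graft mobility evidence audit\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  [%s] %s\n", x$status[[nm]], nm))
    if (x$status[[nm]] == "error") {
      cat("      ", x$stages[[nm]]$message, "\n")
    }
  }
  invisible(x)
}

#' Write an audit report to disk
#'
#' TSV tables for the tabular stages plus one JSON summary embedding the
#' configuration (including the seed), so the run is reproducible from
#' the report alone.
#'
#' @param report an [run_audit()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  if (!is.null(st$classification$value)) {
    write_results(st$classification$value, file.path(dir, "mobility_calls.tsv"))
  }
  if (!is.null(st$read_consistency$value)) {
    write_results(as.data.frame(st$read_consistency$value),
                  file.path(dir, "read_consistency.tsv"))
  }
  if (!is.null(st$pseudo_het$value$sites)) {
    write_results(st$pseudo_het$value$sites, file.path(dir, "pseudo_het.tsv"))
  }
  summary <- list(
    status = as.list(report$status),
    config = unclass(report$config),
    background = if (!is.null(st$background$value)) {
      v <- st$background$value
      list(rate_point = v$rate_point, n_foreign = v$n_foreign_total,
           n_total = v$n_total)
    },
    foreign_fraction = if (!is.null(st$foreign_fraction$value)) {
      v <- st$foreign_fraction$value
      list(heterograft = v$heterograft$fraction,
           homograft = v$homograft$fraction, no_excess = v$no_excess)
    },
    distribution = if (!is.null(st$distribution$value)) {
      v <- st$distribution$value
      list(ks_D = v$ks_exact$statistic, ks_p = v$ks_exact$p_value,
           no_support = v$no_support)
    },
    noise_explained = st$noise_explained$value,
    contamination = if (!is.null(st$contamination$value)) {
      v <- st$contamination$value
      list(slope = v$slope, p_value = v$p_value,
           suspected = v$contamination_suspected)
    }
  )
  jsonlite::write_json(summary, file.path(dir, "audit_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Replicate overlap of mobility calls
#'
#' Poor overlap of candidate mobile transcripts between biological
#' replicates is itself evidence of noise. Given per-replicate call
#' tables, reports how many replicates support each gene and the
#' pairwise Jaccard overlap of the candidate sets.
#'
#' @param calls_list list (length >= 2) of [classify_transcripts()]
#'   outputs, one per replicate.
#' @return A list: `support` (`data.frame` of `gene_id, n_replicates`,
#'   over genes called mobile in at least one replicate) and `jaccard`
#'   (pairwise overlap matrix of the candidate sets).
#' @export
replicate_overlap <- function(calls_list) {
  if (length(calls_list) < 2) {
    stop("replicate overlap needs at least 2 replicates")
  }
  sets <- lapply(calls_list, function(cl) {
    unique(cl$gene_id[cl$classification == "mobile_candidate"])
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("rep", seq_along(sets))
  }
  all_genes <- sort(unique(unlist(sets)))
  support <- data.frame(
    gene_id = all_genes,
    n_replicates = vapply(all_genes, function(g) {
      sum(vapply(sets, function(s) g %in% s, logical(1)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(support) <- NULL
  k <- length(sets)
  jac <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      u <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- if (u == 0) 1 else {
        length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  list(support = support, jaccard = jac)
}
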