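#' Build a pipeline run configuration
#'
#' Collects every setting of the end-to-end analysis in one validated list.
#' Defaults mirror the package-wide defaults: filters (10% per-group
#' missingness, 1% MAF, HWE P >= 1e-3), 10,000 Monte-Carlo iterations, the
#' nominal threshold set \{1e-4, 1e-3, 7.5e-3, 1e-2\}, and a 100 x 100
#' surface lattice.
#'
#' @param genotypes path to a VCF or matrix file (see [load_genotypes()]),
#'   or a `genotype_matrix` object.
#' @param group_map group map file or data frame (ignored when `genotypes`
#'   is already a `genotype_matrix`).
#' @param phenotypes phenotype table (path to TSV with columns `id`,
#'   `length_mm`, `weight_g`, `habitat`, `date`, or a data frame), or
#'   `NULL` to skip phenotype stages.
#' @param baseline,group_a,group_b group labels (defaults `"larvae"`,
#'   `"brackish"`, `"marine"`).
#' @param max_missing_frac,maf_min,hwe_alpha filter thresholds.
#' @param balance_alpha allele-balance filter level (used when depths are
#'   attached; `NULL` disables).
#' @param n_iter Monte-Carlo iterations per locus.
#' @param thresholds nominal threshold sweep set.
#' @param outlier_threshold threshold defining the outlier set for surfaces.
#' @param grid_n surface lattice size.
#' @param seed master seed.
#' @param out_dir output directory (`NULL` for no file output).
#' @return A list of class `run_config`.
#' @export
run_config <- function(genotypes, group_map = NULL, phenotypes = NULL,
                       baseline = "larvae", group_a = "brackish",
                       group_b = "marine",
                       max_missing_frac = 0.10, maf_min = 0.01,
                       hwe_alpha = 1e-3, balance_alpha = 0.05,
                       n_iter = 10000,
                       thresholds = c(1e-4, 1e-3, 7.5e-3, 1e-2),
                       outlier_threshold = 1e-3, grid_n = 100, seed = 1,
                       out_dir = NULL) {
  if (!length(thresholds)) stop("threshold list must not be empty")
  stopifnot(all(thresholds > 0), all(thresholds < 1),
            outlier_threshold > 0, outlier_threshold < 1,
            n_iter >= 1, grid_n >= 10)
  if (is.character(genotypes) && !file.exists(genotypes)) {
    stop("genotype file not found: ", genotypes)
  }
  if (is.character(phenotypes) && !file.exists(phenotypes)) {
    stop("phenotype file not found: ", phenotypes)
  }
  structure(
    list(genotypes = genotypes, group_map = group_map,
         phenotypes = phenotypes, baseline = baseline, group_a = group_a,
         group_b = group_b, max_missing_frac = max_missing_frac,
         maf_min = maf_min, hwe_alpha = hwe_alpha,
         balance_alpha = balance_alpha, n_iter = n_iter,
         thresholds = sort(thresholds, decreasing = TRUE),
         outlier_threshold = outlier_threshold, grid_n = grid_n,
         seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys match the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> scan -> outlier classification -> polygenic score
#' sweeps -> survival surfaces, writing TSV reports when an output
#' directory is configured. Identical inputs and seed give identical
#' outputs; each stage failure aborts with a stage-named error, retaining
#' files already written.
#'
#' @param config a [run_config()].
#' @return A list: `genotypes` (filtered), `filter_report`,
#'   `balance_report`, `scan`, `outliers`, `classification`, `sweeps`
#'   (per trait), `surfaces` (per habitat), `survival_scores`, `tradeoff`,
#'   `summary` (named list of headline counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  save_tsv <- function(obj, fname, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, fname))
  }

  G <- stage("load", {
    if (inherits(config$genotypes, "genotype_matrix")) config$genotypes
    else load_genotypes(config$genotypes, group_map = config$group_map)
  })
  filt <- stage("filter", {
    filter_loci(G, config$max_missing_frac, config$maf_min,
                config$hwe_alpha)
  })
  save_tsv(filt$report, "filter_report.tsv", write_filter_report)
  G <- filt$genotypes
  balance_report <- NULL
  if (!is.null(config$balance_alpha) && !is.null(G$ref_depth)) {
    bal <- stage("allele_balance",
                 allele_balance_filter(G, config$balance_alpha))
    balance_report <- bal$report
    save_tsv(balance_report, "balance_report.tsv", write_filter_report)
    G <- bal$genotypes
  }

  scan <- stage("scan", {
    sgs_scan(G, config$group_a, config$group_b, baseline = config$baseline,
             n_iter = config$n_iter, seed = config$seed)
  })
  save_tsv(scan, "sgs_scan.tsv", write_scan_tsv)
  outliers <- outlier_loci(scan, config$outlier_threshold)
  classification <- stage("classify", classify_outliers_vs_baseline(scan))

  phen <- config$phenotypes
  sweeps <- NULL
  if (!is.null(phen)) {
    sweeps <- stage("sweep", {
      if (is.character(phen)) {
        phen <- utils::read.table(phen, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      }
      k <- condition_factor(phen$length_mm, phen$weight_g)
      z <- standardized_length(phen$length_mm, phen$habitat, phen$date)
      traits <- list(
        std_length = stats::setNames(z, phen$id),
        condition = stats::setNames(as.numeric(k), phen$id)
      )
      habitat <- stats::setNames(phen$habitat, phen$id)
      lapply(traits, function(tr) {
        list(
          A = threshold_sweep(scan, G, tr, habitat, config$thresholds,
                              score = "A"),
          B = threshold_sweep(scan, G, tr, habitat, config$thresholds,
                              score = "B")
        )
      })
    })
    if (!is.null(out_dir)) {
      for (tr in names(sweeps)) for (sc in names(sweeps[[tr]])) {
        utils::write.table(
          as.data.frame(sweeps[[tr]][[sc]]),
          file.path(out_dir, paste0("sweep_", tr, "_score", sc, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
    }
  }

  surfaces <- survival_scores <- tradeoff <- NULL
  if (length(outliers) >= 2) {
    surf_res <- stage("surface", {
      pcs <- pca_coordinates(G, locus_subset = outliers)
      base_ids <- group_ids(G, config$baseline)
      a_ids <- group_ids(G, config$group_a)
      b_ids <- group_ids(G, config$group_b)
      surf <- list(
        A = survival_surface(pcs[a_ids, ], pcs[base_ids, ],
                             grid_n = config$grid_n),
        B = survival_surface(pcs[b_ids, ], pcs[base_ids, ],
                             grid_n = config$grid_n)
      )
      juv_scores <- c(
        project_survival_scores(pcs[a_ids, ], surf$A),
        project_survival_scores(pcs[b_ids, ], surf$B)
      )
      st <- allele_frequencies(G)
      ori <- orient_alleles(st, config$group_a, config$group_b,
                            loci = outliers)
      psc <- polygenic_scores(G, ori)
      score_a <- stats::setNames(psc$score_a, psc$id)
      habitat <- stats::setNames(as.character(G$groups), names(G$groups))
      trd <- survival_tradeoff_ancova(juv_scores, score_a, habitat)
      list(surfaces = surf, scores = juv_scores, tradeoff = trd,
           base_ids = base_ids)
    })
    surfaces <- surf_res$surfaces
    survival_scores <- surf_res$scores
    tradeoff <- surf_res$tradeoff
    if (!is.null(out_dir)) {
      write_surface_tsv(surfaces$A, file.path(out_dir, "surface_A.tsv"))
      write_surface_tsv(surfaces$B, file.path(out_dir, "surface_B.tsv"))
      utils::write.table(
        data.frame(id = names(survival_scores),
                   survival_score = unname(survival_scores)),
        file.path(out_dir, "survival_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }

  summary <- list(
    n_loci_input = filt$report$n_tested,
    n_loci_retained = ncol(G$calls),
    n_outliers = length(outliers),
    outlier_threshold = config$outlier_threshold,
    outliers_per_threshold = vapply(
      config$thresholds, function(t) length(outlier_loci(scan, t)),
      integer(1)
    ),
    thresholds = config$thresholds,
    frac_baseline_intermediate = if (length(outliers))
      mean(classification$intermediate[classification$locus %in% outliers])
      else NA_real_,
    frac_outside_ci = if (length(outliers))
      mean(classification$outside_ci[classification$locus %in% outliers])
      else NA_real_
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genotypes = G, filter_report = filt$report,
       balance_report = balance_report, scan = scan, outliers = outliers,
       classification = classification, sweeps = sweeps,
       surfaces = surfaces, survival_scores = survival_scores,
       tradeoff = tradeoff, summary = summary)
}
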