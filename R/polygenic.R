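#' Orient alleles by between-habitat frequency contrast
#'
#' At each locus the allele at higher frequency in group A's survivors than
#' in group B's is labelled the A-favored allele (e.g. the "brackish
#' allele"); the other allele is B-favored. Ties are resolved to the
#' reference allele and flagged.
#'
#' @param stats a [allele_frequencies()] result (class `locus_stats`).
#' @param group_a,group_b the two post-selection group labels.
#' @param loci optional locus subset (default all loci in `stats`).
#' @return A data frame of class `polygenic_orientation`: `locus`,
#'   `a_allele` (`"ref"` or `"alt"`), `tie` (logical).
#' @export
orient_alleles <- function(stats, group_a, group_b, loci = NULL) {
  stopifnot(inherits(stats, "locus_stats"))
  pa <- stats[[paste0("p_", group_a)]]
  pb <- stats[[paste0("p_", group_b)]]
  if (is.null(pa) || is.null(pb)) stop("group frequencies missing from stats")
  keep <- rep(TRUE, nrow(stats))
  if (!is.null(loci)) keep <- stats$locus %in% loci
  usable <- keep & !is.na(pa) & !is.na(pb)
  if (!is.null(loci) && sum(usable) < length(loci)) {
    message(length(loci) - sum(usable), " locus/loci excluded (missing frequencies)")
  }
  out <- data.frame(
    locus = stats$locus[usable],
    a_allele = ifelse(pa[usable] >= pb[usable], "ref", "alt"),
    tie = pa[usable] == pb[usable],
    stringsAsFactors = FALSE
  )
  class(out) <- c("polygenic_orientation", "data.frame")
  out
}

#' Per-individual polygenic scores of habitat-favored alleles
#'
#' Counts, for each individual, the A-favored and B-favored alleles over the
#' chosen locus set. Missing calls contribute zero to both scores (no
#' missing-data correction), so with complete data
#' `score_a + score_b = 2 * number of loci` exactly.
#'
#' @param G a [genotype_matrix()].
#' @param orientation a [orient_alleles()] result.
#' @param locus_set locus ids to sum over (default: all oriented loci).
#' @return A data frame of class `score_set`: `id`, `score_a`, `score_b`,
#'   `n_missing`.
#' @export
polygenic_scores <- function(G, orientation, locus_set = NULL) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(orientation, "polygenic_orientation"))
  if (is.null(locus_set)) locus_set <- orientation$locus
  if (!length(locus_set)) stop("empty locus set")
  missing_or <- setdiff(locus_set, orientation$locus)
  if (length(missing_or)) {
    stop("locus/loci not in the orientation: ",
         paste(utils::head(missing_or, 5), collapse = ", "))
  }
  calls <- G$calls[, locus_set, drop = FALSE]
  a_ref <- orientation$a_allele[match(locus_set, orientation$locus)] == "ref"
  # A-favored allele count per call: g where A-favored is ref, else 2 - g
  a_counts <- sweep(calls, 2, ifelse(a_ref, 0, 2), function(g, k) abs(k - g))
  score_a <- rowSums(a_counts, na.rm = TRUE)
  score_b <- rowSums(2 - a_counts, na.rm = TRUE)
  out <- data.frame(id = rownames(calls), score_a = unname(score_a),
                    score_b = unname(score_b),
                    n_missing = unname(rowSums(is.na(calls))),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Threshold sweep of polygenic-score ANCOVAs
#'
#' For each nominal SGS threshold, selects the outlier loci, computes
#' polygenic scores over them, and fits `trait ~ habitat * score` by
#' [ancova_interaction()], recording the explained variance. Sweeping the
#' threshold locates the outlier set maximizing the phenotypic variance
#' explained in interaction with habitat.
#'
#' @param scan an `sgs_scan` over the juvenile groups.
#' @param G the [genotype_matrix()] the scan was computed from.
#' @param trait named numeric vector of trait values (names = individual
#'   ids; typically juveniles only).
#' @param habitat named habitat labels for the same individuals.
#' @param thresholds numeric vector of nominal P-value thresholds.
#' @param score `"A"` or `"B"`: which habitat's favored-allele score enters
#'   the model.
#' @return A data frame of class `sweep_result`: `threshold`, `n_loci`,
#'   `r_squared`, `model_p`, `interaction_p`, `empty`. The argmax-R^2
#'   threshold is in attribute `"best_threshold"`.
#' @export
threshold_sweep <- function(scan, G, trait, habitat, thresholds,
                            score = c("A", "B")) {
  score <- match.arg(score)
  stopifnot(inherits(scan, "sgs_scan"), inherits(G, "genotype_matrix"),
            length(thresholds) >= 1, all(thresholds > 0), all(thresholds <= 1))
  ids <- names(trait)
  if (is.null(ids) || is.null(names(habitat))) {
    stop("'trait' and 'habitat' must be named by individual id")
  }
  ids <- intersect(ids, rownames(G$calls))
  if (length(ids) < 10) stop("too few phenotyped individuals in the genotype matrix")
  thresholds <- sort(thresholds, decreasing = TRUE)
  st <- allele_frequencies(G)
  ga <- attr(scan, "group_a")
  gb <- attr(scan, "group_b")
  rows <- lapply(thresholds, function(t) {
    loci <- scan$locus[scan$p_value < t]
    if (!length(loci)) {
      return(data.frame(threshold = t, n_loci = 0L, r_squared = NA_real_,
                        model_p = NA_real_, interaction_p = NA_real_,
                        empty = TRUE))
    }
    ori <- orient_alleles(st, ga, gb, loci = loci)
    sc <- polygenic_scores(G, ori)
    v <- if (score == "A") sc$score_a else sc$score_b
    names(v) <- sc$id
    fit <- tryCatch(
      ancova_interaction(trait[ids], v[ids], habitat[ids]),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(threshold = t, n_loci = length(loci),
                        r_squared = NA_real_, model_p = NA_real_,
                        interaction_p = NA_real_, empty = TRUE))
    }
    data.frame(threshold = t, n_loci = length(loci),
               r_squared = fit$r_squared, model_p = fit$model_p,
               interaction_p = fit$interaction_p, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- which(!out$empty)
  attr(out, "best_threshold") <-
    if (length(ok)) out$threshold[ok[which.max(out$r_squared[ok])]] else NA_real_
  attr(out, "score") <- score
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Per-SNP genome-wide association models
#'
#' Ordinary least squares per SNP under three models: `simple`
#' (`y ~ g`), `covariate` (`y ~ g + E`) and `interaction`
#' (`y ~ g + E + g:E`). The reported P-value is the SNP term for the first
#' two models and the interaction term for the third. The genome-wide
#' Bonferroni threshold counts loci sharing a tag-of-origin as a single
#' effective test.
#'
#' @param G a [genotype_matrix()].
#' @param y named trait vector (names = individual ids).
#' @param E named binary environment vector (required for `covariate` and
#'   `interaction` models).
#' @param model `"simple"`, `"covariate"` or `"interaction"`.
#' @param alpha nominal genome-wide level before correction (default 0.05).
#' @return A data frame of class `gwa_result`: `locus`, `beta`, `p_value`,
#'   `skipped` (monomorphic loci), with the Bonferroni-corrected threshold
#'   in attribute `"threshold"` and the effective test count in
#'   `"n_effective"`.
#' @export
gwa_linear <- function(G, y, E = NULL, model = c("simple", "covariate",
                                                 "interaction"),
                       alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(names(y))) stop("'y' must be named by individual id")
  ids <- intersect(names(y), rownames(G$calls))
  y <- y[ids]
  if (model != "simple") {
    if (is.null(E)) stop("model '", model, "' needs an environment vector")
    E <- factor(as.character(E[ids]))
    if (nlevels(E) != 2) stop("'E' must be binary")
  }
  calls <- G$calls[ids, , drop = FALSE]
  loci <- colnames(calls)
  res <- lapply(seq_along(loci), function(j) {
    g <- as.numeric(calls[, j])
    ok <- !is.na(g) & is.finite(y)
    if (sum(ok) < 5 || stats::var(g[ok]) == 0) {
      return(data.frame(locus = loci[j], beta = NA_real_,
                        p_value = NA_real_, skipped = TRUE))
    }
    sm <- switch(
      model,
      simple = stats::summary.lm(stats::lm(y[ok] ~ g[ok])),
      covariate = stats::summary.lm(stats::lm(y[ok] ~ g[ok] + E[ok])),
      interaction = stats::summary.lm(stats::lm(y[ok] ~ g[ok] * E[ok]))
    )
    cf <- sm$coefficients
    term <- if (model == "interaction") nrow(cf) else 2L
    data.frame(locus = loci[j], beta = cf[term, 1],
               p_value = cf[term, 4], skipped = FALSE)
  })
  out <- do.call(rbind, res)
  tested <- out$locus[!out$skipped]
  n_eff <- if (is.null(G$tags)) length(tested) else
    length(unique(G$tags[tested]))
  attr(out, "threshold") <- alpha / max(n_eff, 1)
  attr(out, "n_effective") <- n_eff
  attr(out, "model") <- model
  class(out) <- c("gwa_result", "data.frame")
  out
}

#' Association between polygenic score and a trait in an independent sample
#'
#' Simple linear regression of a trait on a polygenic score in individuals
#' that were not used to detect the outlier loci. Overlap with the
#' discovery sample is an error, guarding the independence of the
#' replication.
#'
#' @param scores named numeric polygenic scores (names = individual ids).
#' @param trait named numeric trait values for the same individuals.
#' @param discovery_ids ids of the individuals used for outlier detection
#'   (optional; checked for overlap when given).
#' @return A list: `slope`, `r_squared`, `p_value`, `n`.
#' @export
independent_association <- function(scores, trait, discovery_ids = NULL) {
  if (is.null(names(scores)) || is.null(names(trait))) {
    stop("'scores' and 'trait' must be named by individual id")
  }
  ids <- intersect(names(scores), names(trait))
  if (length(ids) < 3) stop("too few individuals with both score and trait")
  if (!is.null(discovery_ids)) {
    ov <- intersect(ids, discovery_ids)
    if (length(ov)) {
      stop("individual(s) overlap the discovery sample: ",
           paste(utils::head(ov, 5), collapse = ", "))
    }
  }
  s <- scores[ids]; tr <- trait[ids]
  if (stats::var(s) == 0) stop("polygenic score is constant; slope undefined")
  sm <- stats::summary.lm(stats::lm(tr ~ s))
  list(slope = sm$coefficients[2, 1], r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n = length(ids))
}

#' Write polygenic scores to TSV
#'
#' @param scores a `score_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
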