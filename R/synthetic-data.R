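#' Generate a synthetic cohort with planted antagonistic selection
#'
#' Emulates the study design the package analyzes: one panmictic gene pool
#' sampled as a pre-selection baseline (larvae) plus two post-selection
#' juvenile groups grown in contrasting habitats, with a configurable subset
#' of loci under habitat-antagonistic viability selection and additive
#' environment-dependent effects on two fitness-proxy traits (growth and
#' condition).
#'
#' Baseline frequencies are drawn uniformly over `maf_range`, drift to the
#' standing cohort frequency via one binomial draw of `2 * N_pop` alleles,
#' and all baseline genotypes are HWE draws from the standing frequency.
#' Each juvenile group draws genotypes at selected loci from the
#' post-viability-selection genotype distribution
#' ([viability_selection_probs()]) with habitat-specific coefficients:
#' antagonistic mode plants `s_B = -s_A`, conditional-neutrality mode plants
#' `s_B = 0`. Traits are standardized environment-dependent linear
#' combinations of the planted genotypes plus Gaussian noise, scaled so the
#' habitat-by-score ANCOVA explains about `r2` of the trait variance, with
#' opposite slopes in the two habitats; lengths and weights are
#' back-transformed so [condition_factor()] and [standardized_length()]
#' recover the planted structure. Baseline individuals additionally receive
#' a larval growth trait driven by the same loci for independent
#' replication.
#'
#' @param n_baseline,n_juv_a,n_juv_b group sizes (defaults 44, 106, 106).
#' @param n_loci total simulated loci (default 5000).
#' @param n_selected planted selected loci (default 20).
#' @param s_range range of per-locus selection coefficients; a scalar plants
#'   the same `s` at every selected locus (default `c(0.2, 0.5)`).
#' @param maf_range range of baseline allele frequencies (default
#'   `c(0.05, 0.95)`).
#' @param trait_spec list with elements `growth` and `condition`, each
#'   `list(r2 = ..., score = "A" or "B")`: target ANCOVA R^2 and which
#'   habitat's favored alleles drive the trait. Defaults target a regime of
#'   a few percent explained variance (`growth` 0.04 via score B,
#'   `condition` 0.09 via score A); `larval_r2` sets the baseline growth
#'   association (default 0.2).
#' @param mode `"antagonistic"` or `"conditional"` selection across
#'   habitats.
#' @param N_pop finite population size behind the drift layer (default
#'   10000).
#' @param group_labels labels for (baseline, group A, group B); defaults
#'   `c("larvae", "brackish", "marine")`.
#' @param seed integer seed.
#' @return A list of class `synthetic_cohort`: `genotypes`
#'   (a [genotype_matrix()]), `phenotypes` (data frame: `id`, `length_mm`,
#'   `weight_g`, `habitat`, `date` for juveniles), `larval_growth` (named
#'   vector for baseline individuals), `truth` (class `cohort_truth`:
#'   planted loci, `s_a`, `s_b`, effect sizes, baseline and standing
#'   frequencies, seed).
#' @export
generate_cohort <- function(n_baseline = 44, n_juv_a = 106, n_juv_b = 106,
                            n_loci = 5000, n_selected = 20,
                            s_range = c(0.2, 0.5), maf_range = c(0.05, 0.95),
                            trait_spec = list(
                              growth = list(r2 = 0.04, score = "B"),
                              condition = list(r2 = 0.09, score = "A"),
                              larval_r2 = 0.2
                            ),
                            mode = c("antagonistic", "conditional"),
                            N_pop = 10000,
                            group_labels = c("larvae", "brackish", "marine"),
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_baseline >= 2, n_juv_a >= 2, n_juv_b >= 2, n_loci >= 1,
            n_selected >= 0, N_pop >= 1, length(group_labels) == 3)
  if (n_selected > n_loci) stop("n_selected cannot exceed n_loci")
  s_range <- rep_len(s_range, 2)
  set.seed(seed)

  p0 <- stats::runif(n_loci, maf_range[1], maf_range[2])
  p_pop <- stats::rbinom(n_loci, 2 * N_pop, p0) / (2 * N_pop)
  sel <- sort(sample.int(n_loci, n_selected))
  s_mag <- stats::runif(n_selected, s_range[1], s_range[2])
  # which allele is favored in habitat A: +1 -> reference allele
  dir_ref <- sample(c(1, -1), n_selected, replace = TRUE)
  s_a <- numeric(n_loci); s_b <- numeric(n_loci)
  s_a[sel] <- dir_ref * s_mag
  s_b[sel] <- if (mode == "antagonistic") -dir_ref * s_mag else 0

  locus_ids <- sprintf("snp%05d", seq_len(n_loci))
  draw_group <- function(n_ind, s_vec) {
    m <- matrix(NA_integer_, n_ind, n_loci)
    for (j in seq_len(n_loci)) {
      if (s_vec[j] == 0) {
        m[, j] <- stats::rbinom(n_ind, 2, p_pop[j])
      } else {
        pr <- viability_selection_probs(p_pop[j], s_vec[j])
        m[, j] <- c(2L, 1L, 0L)[
          sample.int(3, n_ind, replace = TRUE, prob = pr)]
      }
    }
    m
  }
  g_base <- draw_group(n_baseline, numeric(n_loci))
  g_a <- draw_group(n_juv_a, s_a)
  g_b <- draw_group(n_juv_b, s_b)
  calls <- rbind(g_base, g_a, g_b)
  ids <- c(sprintf("larv%03d", seq_len(n_baseline)),
           sprintf("juvA%03d", seq_len(n_juv_a)),
           sprintf("juvB%03d", seq_len(n_juv_b)))
  rownames(calls) <- ids
  colnames(calls) <- locus_ids
  groups <- rep(group_labels, c(n_baseline, n_juv_a, n_juv_b))
  # one tag per locus by default (RAD-tag grouping is upstream information)
  G <- genotype_matrix(calls, groups = groups, tags = locus_ids)

  # additive genetic value on the habitat-A-favored allele scale; effect
  # sizes proportional to |s| so strongly selected loci matter most
  truth_effects <- numeric(n_loci)
  truth_effects[sel] <- s_mag
  genetic_value <- function(m) {
    if (!length(sel)) return(numeric(nrow(m)))
    gv <- numeric(nrow(m))
    for (k in seq_along(sel)) {
      j <- sel[k]
      # center on the standing frequency of the A-favored allele so a
      # neutral individual has expected contribution zero at every locus
      if (dir_ref[k] > 0) {
        a_count <- m[, j]
        p_fav <- p_pop[j]
      } else {
        a_count <- 2 - m[, j]
        p_fav <- 1 - p_pop[j]
      }
      gv <- gv + s_mag[k] * (a_count - 2 * p_fav)
    }
    gv
  }
  gv_juv <- genetic_value(rbind(g_a, g_b))
  habitat <- rep(group_labels[2:3], c(n_juv_a, n_juv_b))
  hab_sign <- ifelse(habitat == group_labels[2], 1, -1)
  # scale by the within-habitat genetic spread: selection shifts the group
  # means apart, and the r2 target refers to the slope seen within habitats
  gv_centered <- gv_juv - stats::ave(gv_juv, habitat)
  gv_sd <- stats::sd(gv_centered)
  if (!is.finite(gv_sd) || gv_sd == 0) gv_sd <- 1

  make_trait <- function(spec) {
    g_std <- gv_juv / gv_sd
    # score B is the complementary count: flip the genetic axis
    if (spec$score == "B") g_std <- -g_std
    r2 <- min(max(spec$r2, 0), 0.95)
    sqrt(r2) * hab_sign * g_std +
      sqrt(1 - r2) * stats::rnorm(length(g_std))
  }
  z_growth <- make_trait(trait_spec$growth)
  z_cond <- make_trait(trait_spec$condition)

  # back-transform to lengths/weights; two sampling dates per habitat with
  # later dates yielding larger fish, brackish habitat more productive
  date <- sample(c("d1", "d2"), n_juv_a + n_juv_b, replace = TRUE)
  base_len <- ifelse(habitat == group_labels[2], 150, 120) +
    ifelse(date == "d2", 25, 0)
  length_mm <- base_len * exp(0.08 * z_growth)
  weight_g <- 1e-5 * length_mm^3.05 * exp(0.04 * z_cond)
  phenotypes <- data.frame(
    id = ids[(n_baseline + 1):length(ids)],
    length_mm = length_mm, weight_g = weight_g,
    habitat = habitat, date = date, stringsAsFactors = FALSE
  )

  larval_r2 <- if (is.null(trait_spec$larval_r2)) 0.2 else trait_spec$larval_r2
  gv_base <- genetic_value(g_base) / gv_sd
  # larval growth rate in um/day, driven by the B-favored (marine) alleles
  larval_growth <- 1.84 + 0.37 * (sqrt(larval_r2) * (-gv_base) +
                                    sqrt(1 - larval_r2) * stats::rnorm(n_baseline))
  names(larval_growth) <- ids[seq_len(n_baseline)]

  truth <- structure(
    list(selected = locus_ids[sel], s_a = s_a[sel], s_b = s_b[sel],
         a_allele = ifelse(dir_ref > 0, "ref", "alt"),
         effects = s_mag, p0 = p0, p_pop = p_pop, mode = mode,
         trait_spec = trait_spec, seed = seed),
    class = "cohort_truth"
  )
  structure(
    list(genotypes = G, phenotypes = phenotypes,
         larval_growth = larval_growth, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$genotypes$calls), "individuals,",
      ncol(x$genotypes$calls), "loci,",
      length(x$truth$selected), "under selection (", x$truth$mode, ")\n")
  invisible(x)
}

#' Simulate allele read depths for a genotype matrix
#'
#' Per-call total depth is Poisson with mean `mean_depth`; heterozygote
#' depth splits are binomial with reference-allele probability 0.5 except
#' at `bias_loci`, where it is `0.5 + bias_strength` (a systematic bias the
#' allele-balance filter should catch). Homozygotes carry all reads on
#' their allele; missing calls get missing depths.
#'
#' @param G a [genotype_matrix()].
#' @param mean_depth mean total read depth per call (default 20).
#' @param bias_loci locus ids (or indices) with biased heterozygote splits.
#' @param bias_strength added reference-allele read probability at biased
#'   loci (default 0.3).
#' @param seed integer seed.
#' @return The genotype matrix with `ref_depth` and `alt_depth` attached.
#' @export
generate_read_depths <- function(G, mean_depth = 20, bias_loci = NULL,
                                 bias_strength = 0.3, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), mean_depth > 0)
  set.seed(seed)
  calls <- G$calls
  total <- matrix(stats::rpois(length(calls), mean_depth), nrow(calls))
  biased <- rep(FALSE, ncol(calls))
  if (!is.null(bias_loci)) {
    idx <- if (is.character(bias_loci)) match(bias_loci, colnames(calls)) else bias_loci
    biased[idx] <- TRUE
  }
  p_ref <- matrix(0.5, nrow(calls), ncol(calls))
  p_ref[, biased] <- 0.5 + bias_strength
  ref <- matrix(NA_integer_, nrow(calls), ncol(calls))
  alt <- matrix(NA_integer_, nrow(calls), ncol(calls))
  het <- !is.na(calls) & calls == 1L
  ref[het] <- stats::rbinom(sum(het), total[het], p_ref[het])
  alt[het] <- total[het] - ref[het]
  hom_ref <- !is.na(calls) & calls == 2L
  ref[hom_ref] <- total[hom_ref]; alt[hom_ref] <- 0L
  hom_alt <- !is.na(calls) & calls == 0L
  ref[hom_alt] <- 0L; alt[hom_alt] <- total[hom_alt]
  dimnames(ref) <- dimnames(alt) <- dimnames(calls)
  G$ref_depth <- ref
  G$alt_depth <- alt
  G
}

#' Write a synthetic cohort to disk
#'
#' Writes the genotypes as VCF, the group map and phenotypes as TSV, the
#' larval growth trait as TSV, and the simulation truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_group_map(cohort$genotypes, file.path(dir, "groups.tsv"))
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = names(cohort$larval_growth),
               growth_um_day = unname(cohort$larval_growth)),
    file.path(dir, "larval_growth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- cohort$truth
  truth$p0 <- NULL  # per-locus vectors kept out of the summary json
  truth$p_pop <- NULL
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
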