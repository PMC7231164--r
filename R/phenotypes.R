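#' Relative condition factor
#'
#' Ratio of an individual's measured weight to the weight predicted by the
#' log-log ordinary least squares regression of weight against length fitted
#' over all individuals jointly. By construction the geometric mean of K is
#' 1, and K is unchanged when all weights are rescaled by a common factor.
#'
#' @param lengths positive total lengths (mm).
#' @param weights positive eviscerated weights (g).
#' @return Numeric vector of condition factors, with the fitted allometry
#'   coefficients `c(intercept, slope)` (log scale) as attribute
#'   `"allometry"`.
#' @export
condition_factor <- function(lengths, weights) {
  stopifnot(length(lengths) == length(weights), length(lengths) >= 3)
  if (any(!is.finite(lengths)) || any(!is.finite(weights)) ||
      any(lengths <= 0) || any(weights <= 0)) {
    stop("lengths and weights must be positive and finite")
  }
  fit <- stats::lm(log(weights) ~ log(lengths))
  k <- weights / exp(stats::fitted(fit))
  attr(k, "allometry") <- unname(stats::coef(fit))
  k
}

#' Standardized length index
#'
#' Z-scores total length within each habitat-by-sampling-date stratum,
#' removing between-stratum differences (e.g. due to heterochronous
#' sampling) so the index captures relative growth among fish sampled
#' together. Strata with fewer than two fish or zero length variance yield
#' `NA` with a warning.
#'
#' @param lengths positive total lengths (mm).
#' @param habitat habitat label per individual.
#' @param date sampling date (or any stratum key) per individual.
#' @return Numeric vector of within-stratum z-scores.
#' @export
standardized_length <- function(lengths, habitat, date) {
  stopifnot(length(lengths) == length(habitat),
            length(lengths) == length(date))
  stratum <- interaction(habitat, date, drop = TRUE)
  z <- rep(NA_real_, length(lengths))
  degenerate <- character(0)
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    if (length(idx) < 2 || stats::sd(lengths[idx]) == 0) {
      degenerate <- c(degenerate, s)
      next
    }
    z[idx] <- (lengths[idx] - mean(lengths[idx])) / stats::sd(lengths[idx])
  }
  if (length(degenerate)) {
    warning("stratum/strata without usable variance (z set to NA): ",
            paste(degenerate, collapse = ", "))
  }
  z
}

#' ANCOVA with group-by-covariate interaction
#'
#' Ordinary least squares fit of `y ~ group * x`, the model used for
#' habitat-dependent trait relationships: separate slope and intercept per
#' group, with the interaction F-test measuring whether slopes differ
#' between groups.
#'
#' @param y response vector.
#' @param x covariate vector.
#' @param group group labels (>= 2 levels).
#' @return An object of class `ancova_fit`: list with `slopes` and
#'   `intercepts` (named per group), `r_squared`, `model_p` (overall F),
#'   `interaction_p` (F-test of the interaction term), `residual_df`, `n`,
#'   and the underlying `lm` fit.
#' @export
ancova_interaction <- function(y, x, group) {
  stopifnot(length(y) == length(x), length(y) == length(group))
  keep <- is.finite(y) & is.finite(x) & !is.na(group)
  y <- y[keep]; x <- x[keep]
  group <- factor(as.character(group)[keep])
  if (nlevels(group) < 2) stop("ANCOVA needs at least two groups")
  if (length(y) <= 2 * nlevels(group)) stop("too few observations for the model")
  fit <- stats::lm(y ~ group * x)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient design; confounded term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  lev <- levels(group)
  slopes <- stats::setNames(
    cf["x"] + c(0, cf[paste0("group", lev[-1], ":x")]), lev)
  intercepts <- stats::setNames(
    cf["(Intercept)"] + c(0, cf[paste0("group", lev[-1])]), lev)
  an <- stats::anova(fit)  # sequential; interaction term is last
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(
    list(slopes = slopes, intercepts = intercepts,
         r_squared = sm$r.squared,
         model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
         interaction_p = an[["Pr(>F)"]][rownames(an) == "group:x"],
         residual_df = fit$df.residual, n = length(y), fit = fit),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("ANCOVA y ~ group * x  (n =", x$n, ")\n")
  cat("slopes:    ", paste(names(x$slopes), signif(x$slopes, 4),
                           sep = "=", collapse = ", "), "\n")
  cat("intercepts:", paste(names(x$intercepts), signif(x$intercepts, 4),
                           sep = "=", collapse = ", "), "\n")
  cat(sprintf("R^2 = %.4f, model P = %.3g, interaction P = %.3g\n",
              x$r_squared, x$model_p, x$interaction_p))
  invisible(x)
}
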