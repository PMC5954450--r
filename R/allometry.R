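#' Isometric scaling exponent from trait dimension
#'
#' Under geometric similarity (constant trabecular geometry), a trait whose
#' physical unit is length^d scales against a linear size proxy with
#' exponent d: dimensionless ratios (BV/TV, DA) with 0, linear measures
#' (TbTh, TbSp) with 1, surface density (BS/BV, length^-1) with -1, and
#' connectivity density (ConnD, length^-3) with -3.
#'
#' @param dimension length exponent of the trait's unit: one of -3, -1, 0, 1.
#' @return The isometric exponent `a_iso` (equal to `dimension`).
#' @export
isometric_exponent <- function(dimension) {
  if (!is.numeric(dimension) || length(dimension) != 1L ||
      !dimension %in% c(-3, -1, 0, 1))
    stop("unknown trait dimension: must be one of -3, -1, 0, 1")
  dimension
}

# length exponents of the standard trabecular parameters
trait_dimensions <- c(DA = 0, BVTV = 0, TbTh = 1, TbSp = 1,
                      BSBV = -1, ConnD = -3)

# p-value of a baseline-shift slope; a (numerically) zero slope in an exact
# fit (zero residual variance makes the t statistic 0/0 noise) carries no
# evidence of deviation
deviation_p <- function(fit, coefname) {
  p <- unname(fit$pval[coefname])
  exact <- fit$sigma2 < 1e-16 || !is.finite(p)
  if (exact && abs(coef(fit)[coefname]) < 1e-8) p <- 1
  p
}

#' Isometric exponent for a named trabecular parameter
#'
#' @param trait one of `"DA"`, `"BVTV"`, `"TbTh"`, `"TbSp"`, `"BSBV"`,
#'   `"ConnD"`.
#' @return The isometric exponent.
#' @export
isometric_exponent_for <- function(trait) {
  if (!trait %in% names(trait_dimensions))
    stop("unknown trait: ", trait)
  isometric_exponent(unname(trait_dimensions[trait]))
}

#' Allometric scaling test against dimensional isometry
#'
#' Fits `log(tp) ~ log(vl)` by phylogenetic GLS for the observed exponent
#' and coefficient of determination, then refits the baseline-shifted
#' response `log(tp) - a_iso * log(vl)` on `log(vl)` and tests its slope
#' against zero; the shifted slope equals `a_obs - a_iso` algebraically.
#' Classification: isometry when the deviation p-value is >= alpha,
#' otherwise positive (`"+allo"`) or negative (`"-allo"`) allometry
#' according to the sign of `a_obs - a_iso`. Raw data are natural
#' log-transformed internally, so all values must be positive.
#'
#' @param data trait table with `species`, `vl` and the trait column.
#' @param trait trait column name.
#' @param tree an `ape::phylo`.
#' @param a_iso isometric exponent; looked up from the trait name when
#'   `NULL`.
#' @param lambda `"REML"`, `"ML"` or fixed value for the PGLS fits.
#' @param alpha significance level for the classification.
#' @return An object of class `allometry_result`: `trait`, `a_iso`,
#'   `a_obs`, `r_squared`, `p_value`, `classification`, `lambda`, `n`.
#' @export
allometry_test <- function(data, trait, tree, a_iso = NULL, lambda = "REML",
                           alpha = 0.05) {
  if (is.null(a_iso)) a_iso <- isometric_exponent_for(trait)
  if (any(data[[trait]] <= 0) || any(data$vl <= 0))
    stop("all trait and vl values must be positive (log transform)")
  df <- data.frame(species = data$species,
                   log_tp = log(data[[trait]]),
                   log_vl = log(data$vl))
  fit <- pgls(log_tp ~ log_vl, df, tree, lambda = lambda)
  a_obs <- unname(coef(fit)["log_vl"])
  df$shifted <- df$log_tp - a_iso * df$log_vl
  fit0 <- pgls(shifted ~ log_vl, df, tree, lambda = lambda)
  p <- deviation_p(fit0, "log_vl")
  cls <- if (p >= alpha) "isometry" else
    if (a_obs > a_iso) "+allo" else "-allo"
  structure(list(trait = trait, a_iso = a_iso, a_obs = a_obs,
                 r_squared = fit$r.squared, p_value = p,
                 classification = cls, lambda = fit$lambda, n = fit$n,
                 fit = fit, fit_shifted = fit0),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("%s: a_iso = %g, a_obs = %.3f, r2 = %.3f, p = %.3g -> %s\n",
              x$trait, x$a_iso, x$a_obs, x$r_squared, x$p_value,
              x$classification))
  invisible(x)
}

#' Allometry table over all trabecular parameters
#'
#' @param data trait table.
#' @param tree phylogeny.
#' @param traits trait columns to test.
#' @param ... passed to [allometry_test()].
#' @return A data frame with one row per trait (trait, a_iso, a_obs,
#'   r_squared, p_value, classification, lambda).
#' @export
allometry_table <- function(data, tree,
                            traits = intersect(names(trait_dimensions),
                                               names(data)), ...) {
  rows <- lapply(traits, function(tp) {
    r <- allometry_test(data, tp, tree, ...)
    data.frame(trait = r$trait, a_iso = r$a_iso, a_obs = r$a_obs,
               r_squared = r$r_squared, p_value = r$p_value,
               classification = r$classification, lambda = r$lambda,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone step-up, clipped at 1), in input
#'   order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise lifestyle contrasts for one trait
#'
#' For every unordered pair of lifestyle categories with enough species,
#' the data are subset to the two groups, the tree pruned accordingly, and
#' `log(tp) ~ log(vl) + lifestyle` fitted by phylogenetic GLS; the
#' lifestyle indicator's coefficient is the size-adjusted contrast and its
#' p-value the raw test. P-values are Benjamini-Hochberg corrected within
#' the declared family (default: the pairs of this trait).
#'
#' @param data trait table with `species`, `lifestyle`, `vl`, trait column.
#' @param trait trait column name.
#' @param tree phylogeny.
#' @param lambda `"REML"`, `"ML"` or fixed value.
#' @param alpha significance level applied to adjusted p-values.
#' @param min_n minimum species per lifestyle in a pair.
#' @param adjust adjust within this trait (`TRUE`, the default family) or
#'   return raw p-values for adjustment in a wider family (`FALSE`).
#' @return A data frame of class `lifestyle_pairwise`: trait, pair, the two
#'   lifestyles, n, coefficient, p_raw and (if `adjust`) p_adj and
#'   significant.
#' @export
lifestyle_pairwise <- function(data, trait, tree, lambda = "REML",
                               alpha = 0.05, min_n = 3L, adjust = TRUE) {
  ls_levels <- sort(unique(as.character(data$lifestyle)))
  pairs <- utils::combn(ls_levels, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    sub <- data[data$lifestyle %in% pr, , drop = FALSE]
    n1 <- sum(sub$lifestyle == pr[1])
    n2 <- sum(sub$lifestyle == pr[2])
    if (n1 < min_n || n2 < min_n) {
      message("skipping pair (", pr[1], ", ", pr[2],
              "): fewer than ", min_n, " species in a group")
      next
    }
    df <- data.frame(species = sub$species,
                     log_tp = log(sub[[trait]]),
                     log_vl = log(sub$vl),
                     grp = factor(as.character(sub$lifestyle),
                                  levels = pr))
    fit <- pgls(log_tp ~ log_vl + grp, df, tree, lambda = lambda)
    cname <- paste0("grp", pr[2])
    rows[[length(rows) + 1L]] <-
      data.frame(trait = trait,
                 pair = paste(pr, collapse = ":"),
                 lifestyle1 = pr[1], lifestyle2 = pr[2],
                 n = n1 + n2,
                 coefficient = unname(coef(fit)[cname]),
                 p_raw = unname(fit$pval[cname]),
                 lambda = fit$lambda,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no lifestyle pair has enough species")
  if (adjust) {
    out$p_adj <- bh_adjust(out$p_raw)
    out$significant <- out$p_adj < alpha
  }
  class(out) <- c("lifestyle_pairwise", class(out))
  out
}

#' Pairwise lifestyle analysis over several traits
#'
#' Runs [lifestyle_pairwise()] per trait and applies the
#' Benjamini-Hochberg correction either within each trait's six pairs
#' (`family = "per_trait"`, the default, matching per-parameter reporting)
#' or across all traits and pairs at once (`family = "global"`).
#'
#' @param data trait table.
#' @param tree phylogeny.
#' @param traits trait columns.
#' @param family correction family scope.
#' @param alpha significance level.
#' @param ... passed to [lifestyle_pairwise()].
#' @return A data frame with one row per trait x pair.
#' @export
lifestyle_analysis <- function(data, tree,
                               traits = intersect(names(trait_dimensions),
                                                  names(data)),
                               family = c("per_trait", "global"),
                               alpha = 0.05, ...) {
  family <- match.arg(family)
  per <- lapply(traits, function(tp)
    lifestyle_pairwise(data, tp, tree, alpha = alpha,
                       adjust = (family == "per_trait"), ...))
  out <- do.call(rbind, per)
  if (family == "global") {
    out$p_adj <- bh_adjust(out$p_raw)
    out$significant <- out$p_adj < alpha
  }
  out
}

#' Validate the VOI edge length as a body-size proxy
#'
#' Log-log PGLS regression of body mass on `vl`, with a baseline-shift test
#' of the observed exponent against the isometric expectation of 3
#' (mass proportional to a length cubed).
#'
#' @param data trait table with `species`, `vl` and `mass` (g; `NA` rows
#'   dropped).
#' @param tree phylogeny.
#' @param lambda `"REML"`, `"ML"` or fixed value.
#' @return A list: `exponent`, `r_squared`, `p_vs_isometry`, `n`.
#' @export
validate_size_proxy <- function(data, tree, lambda = "REML") {
  keep <- !is.na(data$mass) & !is.na(data$vl)
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) < 10L) stop("need at least 10 species with body mass")
  df <- data.frame(species = sub$species,
                   log_m = log(sub$mass), log_vl = log(sub$vl))
  fit <- pgls(log_m ~ log_vl, df, tree, lambda = lambda)
  df$shifted <- df$log_m - 3 * df$log_vl
  fit0 <- pgls(shifted ~ log_vl, df, tree, lambda = lambda)
  list(exponent = unname(coef(fit)["log_vl"]),
       r_squared = fit$r.squared,
       p_vs_isometry = deviation_p(fit0, "log_vl"),
       n = nrow(sub))
}
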