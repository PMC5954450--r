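#' Phylogenetic trait covariance under Pagel's lambda
#'
#' The Brownian-motion covariance of tip values is the matrix of shared
#' root-to-ancestor path lengths; Pagel's lambda multiplies the
#' off-diagonal entries, leaving the tip variances (root-to-tip lengths)
#' untouched.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param lambda signal strength in \[0, 1\].
#' @return A species-by-species covariance matrix with the tree's tip
#'   labels as dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  V <- ape::vcv.phylo(tree)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model by generalized least squares whose error covariance
#' is the Brownian phylogenetic covariance with off-diagonals scaled by
#' Pagel's lambda. Lambda can be fixed or estimated by maximum likelihood
#' (profiled over \[0, 1\], jointly with the coefficients; coefficient
#' inference is conditional on the estimate). With `lambda = 0` the fit
#' reduces exactly to ordinary least squares.
#'
#' @param formula model formula; variables are looked up in `data`.
#' @param data data frame with one row per species and a `species` column
#'   matching tree tip labels.
#' @param tree an `ape::phylo`; pruned internally to the rows of `data`.
#' @param lambda `"REML"` (the default, restricted maximum likelihood, less
#'   biased in small samples), `"ML"`, or a fixed value in \[0, 1\].
#' @param species name of the column holding species labels.
#' @return An object of class `pgls` with methods for `print`, `summary`,
#'   `coef`, `vcov`, `residuals`, `fitted`, `predict`, `logLik`, `simulate`
#'   and `plot`.
#' @export
pgls <- function(formula, data, tree, lambda = "REML", species = "species") {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!species %in% names(data)) stop("data needs a `", species, "` column")
  sp <- as.character(data[[species]])
  if (anyDuplicated(sp)) stop("duplicated species in data")
  orphans <- setdiff(sp, tree$tip.label)
  if (length(orphans))
    stop("species absent from the tree: ", paste(orphans, collapse = ", "))
  tree <- ape::keep.tip(tree, sp)

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("need n >= p + 2 observations")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  V <- ape::vcv.phylo(tree)[sp, sp]

  fit_at <- function(lam) {
    Vl <- V * lam
    diag(Vl) <- diag(V)
    U <- chol(Vl)
    yt <- backsolve(U, y, transpose = TRUE)
    Xt <- backsolve(U, X, transpose = TRUE)
    colnames(Xt) <- colnames(X)
    f <- lm.fit(Xt, yt)
    rss <- sum(f$residuals^2)
    ldet <- 2 * sum(log(diag(U)))
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1) - ldet / 2
    # restricted likelihood profiles out the coefficients as well
    ldet_xx <- determinant(crossprod(Xt), logarithm = TRUE)$modulus
    llr <- -(n - p) / 2 * (log(2 * pi) + log(rss / (n - p)) + 1) -
      ldet / 2 - ldet_xx / 2
    list(beta = f$coefficients, rss = rss, loglik = ll, loglik_reml = llr,
         U = U, Xt = Xt, yt = yt)
  }

  if (identical(lambda, "ML") || identical(lambda, "REML")) {
    crit <- if (identical(lambda, "REML")) "loglik_reml" else "loglik"
    prof <- function(lam) fit_at(lam)[[crit]]
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    ll <- c(prof(0), opt$objective, prof(1))
    lambda_hat <- cand[which.max(ll)]
    lambda_method <- lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"REML\", \"ML\" or a number in [0, 1]")
    lambda_hat <- lambda
    lambda_method <- "fixed"
  }
  ft <- fit_at(lambda_hat)

  df <- n - p
  sigma2 <- ft$rss / df
  XtXi <- solve(crossprod(ft$Xt))
  vc <- sigma2 * XtXi
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- ft$beta / se
  pval <- 2 * pt(-abs(tstat), df)

  # GLS R^2 against the intercept-only model under the same covariance
  if ("(Intercept)" %in% colnames(X)) {
    ones_t <- backsolve(ft$U, rep(1, n), transpose = TRUE)
    f0 <- lm.fit(cbind(ones_t), ft$yt)
    tss <- sum(f0$residuals^2)
  } else {
    tss <- sum(ft$yt^2)
  }
  r2 <- 1 - ft$rss / tss

  fitted_vals <- setNames(drop(X %*% ft$beta), sp)
  structure(list(coefficients = ft$beta, se = se, tstat = tstat,
                 pval = pval, vcov = vc,
                 lambda = lambda_hat, lambda_method = lambda_method,
                 loglik = ft$loglik, loglik_reml = ft$loglik_reml,
                 sigma2 = sigma2, r.squared = r2,
                 n = n, p = p, df.residual = df,
                 fitted.values = fitted_vals,
                 residuals = setNames(unname(y) - unname(fitted_vals), sp),
                 residuals_normalized = ft$yt - drop(ft$Xt %*% ft$beta),
                 formula = formula, terms = attr(mf, "terms"),
                 species = sp, tree = tree, V = V,
                 call = match.call()),
            class = "pgls")
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, lambda = %.4g (%s), logLik = %.3f\n", x$n,
              x$lambda, x$lambda_method, x$loglik))
  cat("  coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$tstat,
               `Pr(>|t|)` = object$pval)
  structure(list(fit = object, coefficients = tab), class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  f <- x$fit
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  formula:", deparse(f$formula), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlambda = %.4g (%s)   sigma^2 = %.4g   R^2 = %.4f\n",
              f$lambda, f$lambda_method, f$sigma2, f$r.squared))
  cat(sprintf("logLik = %.3f   n = %d   residual df = %d\n",
              f$loglik, f$n, f$df.residual))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, class = "logLik")
}

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$residuals_normalized
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, newdata)
  X <- model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}

#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  Vl <- object$V * object$lambda
  diag(Vl) <- diag(object$V)
  U <- chol(Vl)
  draw <- function() object$fitted.values +
    sqrt(object$sigma2) * drop(crossprod(U, rnorm(object$n)))
  sims <- if (is.null(seed)) replicate(nsim, draw()) else
    withr::with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals_normalized,
                 xlab = "fitted", ylab = "normalized residual",
                 main = "PGLS residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
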