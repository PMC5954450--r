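test_that("phylogenetic covariance follows shared path lengths and lambda scaling", {
  # balanced 4-tip tree with unit branches: hand-computed path lengths
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  V <- phylo_covariance(tr, 1)
  expect_equal(unname(V[cbind(c("a", "a", "a"), c("a", "b", "c"))]),
               c(2, 1, 0))
  Vh <- phylo_covariance(tr, 0.5)
  expect_equal(Vh["a", "b"], 0.5)
  expect_equal(Vh["a", "a"], 2)

  # lambda = 0: diagonal
  expect_true(all(phylo_covariance(tr, 0)[upper.tri(V)] == 0))

  # two-tip cherry from the root shares no path: identical at any lambda
  tr2 <- ape::read.tree(text = "(a:3,b:1.5);")
  expect_equal(phylo_covariance(tr2, 0), phylo_covariance(tr2, 0.9))

  trn <- tr2
  trn$edge.length[1] <- -1
  expect_error(phylo_covariance(trn, 1), "negative")
  expect_error(phylo_covariance(tr, 2), "lambda")
})

test_that("pgls at lambda 0 reproduces ordinary least squares exactly", {
  withr::with_seed(7, {
    tr <- ape::rphylo(40, 1, 0)
    dat <- data.frame(species = tr$tip.label, x = rnorm(40))
    dat$y <- 1 + 0.5 * dat$x + rnorm(40, sd = 0.3)
  })
  f0 <- pgls(y ~ x, dat, tr, lambda = 0)
  fo <- summary(lm(y ~ x, dat))
  expect_equal(unname(coef(f0)), unname(fo$coefficients[, 1]),
               tolerance = 1e-12)
  expect_equal(unname(f0$se), unname(fo$coefficients[, 2]),
               tolerance = 1e-12)
  expect_equal(unname(f0$pval), unname(fo$coefficients[, 4]),
               tolerance = 1e-12)
  expect_equal(f0$r.squared, fo$r.squared, tolerance = 1e-12)

  # star tree with equal tip branches: lambda 1 also equals OLS
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  star$tip.label <- tr$tip.label
  f1 <- pgls(y ~ x, dat, star, lambda = 1)
  expect_equal(unname(coef(f1)), unname(fo$coefficients[, 1]),
               tolerance = 1e-12)
  expect_equal(unname(f1$pval), unname(fo$coefficients[, 4]),
               tolerance = 1e-12)
})

test_that("pgls agrees with the reference GLS implementation (nlme + corPagel)", {
  skip_if_not_installed("nlme")
  s <- simulate_comparative_dataset(simulation_spec(n_species = 40,
                                                    seed = 3))
  df <- data.frame(species = s$traits$species, y = log(s$traits$TbTh),
                   x = log(s$traits$vl))
  rownames(df) <- df$species
  for (method in c("ML", "REML")) {
    f <- pgls(y ~ x, df, s$tree, lambda = method)
    g <- nlme::gls(y ~ x, df,
                   correlation = ape::corPagel(0.5, s$tree,
                                               form = ~species),
                   method = method)
    lam_g <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
    expect_equal(f$lambda, unname(lam_g), tolerance = 1e-4)
    expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(f$se["x"]),
                 unname(summary(g)$tTable["x", "Std.Error"]),
                 tolerance = 1e-4)
    if (method == "ML")
      expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  }
})

test_that("pgls recovers slope and lambda from simulated data", {
  res <- vapply(1:80, function(i) {
    s <- simulate_comparative_dataset(
      simulation_spec(n_species = 64, lambda_true = 0.7, bm_sigma = 0.3,
                      slopes = c(TbTh = 0.835),
                      intercepts = log(c(TbTh = 0.1)),
                      lifestyle_counts = c(arboreal = 25, fossorial = 18,
                                           semifossorial = 13, aerial = 8),
                      n_genera = 30, seed = i))
    d <- data.frame(species = s$traits$species, y = log(s$traits$TbTh),
                    x = log(s$traits$vl))
    f <- pgls(y ~ x, d, s$tree)
    c(slope = unname(coef(f)["x"]), lambda = f$lambda)
  }, c(slope = 0, lambda = 0))
  mcse <- sd(res["slope", ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res["slope", ]) - 0.835), 2 * mcse)
  expect_lt(abs(mean(res["lambda", ]) - 0.7), 0.1)
})

test_that("pgls validates its inputs and supports the standard methods", {
  s <- simulate_comparative_dataset(simulation_spec(n_species = 20,
                                                    lifestyle_counts =
                                                      c(arboreal = 8,
                                                        fossorial = 5,
                                                        semifossorial = 4,
                                                        aerial = 3),
                                                    n_genera = 8, seed = 1))
  d <- data.frame(species = s$traits$species, y = log(s$traits$DA),
                  x = log(s$traits$vl))
  d$x2 <- 2 * d$x
  expect_error(pgls(y ~ x + x2, d, s$tree), "collinear")
  d_bad <- d
  d_bad$species[1] <- "missing_sp"
  expect_error(pgls(y ~ x, d_bad, s$tree), "missing_sp")

  f <- pgls(y ~ x, d, s$tree)
  expect_s3_class(f, "pgls")
  expect_length(coef(f), 2)
  expect_equal(dim(vcov(f)), c(2, 2))
  expect_equal(unname(predict(f, d[1:3, ])), unname(fitted(f)[1:3]))
  expect_equal(unname(fitted(f) + residuals(f)), d$y)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(20L, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
  expect_output(print(summary(f)), "lambda")
  expect_s3_class(logLik(f), "logLik")
})
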