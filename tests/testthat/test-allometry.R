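test_that("isometric exponents follow the trait dimensions", {
  expect_identical(isometric_exponent(-3), -3)
  expect_identical(isometric_exponent(-1), -1)
  expect_identical(isometric_exponent(0), 0)
  expect_identical(isometric_exponent(1), 1)
  expect_error(isometric_exponent(2), "unknown")
  expect_identical(isometric_exponent_for("ConnD"), -3)
  expect_identical(isometric_exponent_for("BSBV"), -1)
  expect_identical(isometric_exponent_for("TbTh"), 1)
  expect_identical(isometric_exponent_for("TbSp"), 1)
  expect_identical(isometric_exponent_for("DA"), 0)
  expect_identical(isometric_exponent_for("BVTV"), 0)
  expect_error(isometric_exponent_for("SMI"), "unknown")
})

noiseless_sim <- function(slope, trait = "TbSp", n = 24, seed = 3) {
  counts <- c(arboreal = 9, fossorial = 7, semifossorial = 5, aerial = 3)
  slopes <- setNames(slope, trait)
  simulate_comparative_dataset(
    simulation_spec(n_species = n, bm_sigma = 0, slopes = slopes,
                    intercepts = setNames(log(0.25), trait),
                    lifestyle_counts = counts, n_genera = 10, seed = seed))
}

test_that("allometry classification is exact on noiseless data", {
  # slope exactly isometric: shifted slope 0, classified isometry
  s_iso <- noiseless_sim(1.0)
  r_iso <- allometry_test(s_iso$traits, "TbSp", s_iso$tree)
  expect_equal(r_iso$a_obs, 1.0, tolerance = 1e-10)
  expect_identical(r_iso$classification, "isometry")

  # slope a_iso + 0.5: positive allometry, exponent recovered exactly
  s_pos <- noiseless_sim(1.5)
  r_pos <- allometry_test(s_pos$traits, "TbSp", s_pos$tree)
  expect_equal(r_pos$a_obs, 1.5, tolerance = 1e-10)
  expect_identical(r_pos$classification, "+allo")

  s_neg <- noiseless_sim(0.593)
  r_neg <- allometry_test(s_neg$traits, "TbSp", s_neg$tree)
  expect_identical(r_neg$classification, "-allo")
  expect_error(allometry_test(s_neg$traits, "TbSp", s_neg$tree,
                              a_iso = NULL, lambda = 2), "lambda")
})

test_that("the shifted-response slope equals a_obs - a_iso to machine precision", {
  for (seed in 1:5) {
    s <- simulate_comparative_dataset(simulation_spec(seed = seed))
    r <- allometry_test(s$traits, "ConnD", s$tree)
    shift <- unname(coef(r$fit_shifted)["log_vl"])
    expect_equal(shift, r$a_obs - r$a_iso, tolerance = 1e-9)
  }
})

test_that("a strong allometric signal is detected in nearly all replicates", {
  # trabecular separation with the observed exponent 0.593 against the
  # isometric baseline of 1 at the study sample size
  rej <- vapply(1:200, function(i) {
    s <- simulate_comparative_dataset(simulation_spec(seed = i))
    allometry_test(s$traits, "TbSp", s$tree)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.95)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  # equal raw p-values are a fixed point
  expect_equal(bh_adjust(rep(0.001, 6)), rep(0.001, 6))
  p1 <- c(0.5, 1.0, 0.02)
  expect_equal(bh_adjust(p1)[2], 1.0)
  withr::with_seed(1, {
    for (i in 1:20) {
      p <- runif(sample(2:12, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # rank-preserving
    }
  })
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise lifestyle contrasts detect a planted aerial effect", {
  off <- matrix(0, 4, 6,
                dimnames = list(c("arboreal", "fossorial", "semifossorial",
                                  "aerial"),
                                c("DA", "ConnD", "TbTh", "TbSp", "BVTV",
                                  "BSBV")))
  off["aerial", "TbTh"] <- 0.4
  hits <- vapply(1:200, function(i) {
    s <- simulate_comparative_dataset(
      simulation_spec(seed = i, bm_sigma = 0.1, lifestyle_offsets = off))
    sub <- s$traits[s$traits$lifestyle %in% c("aerial", "fossorial"), ]
    res <- suppressMessages(lifestyle_pairwise(sub, "TbTh", s$tree))
    res$p_adj[res$pair == "aerial:fossorial"] < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.8)

  # pairs without enough species are skipped with a message
  s <- simulate_comparative_dataset(simulation_spec(seed = 1))
  few <- s$traits[c(which(s$traits$lifestyle == "aerial")[1:2],
                    which(s$traits$lifestyle == "fossorial"),
                    which(s$traits$lifestyle == "arboreal")), ]
  expect_message(res <- lifestyle_pairwise(few, "TbTh", s$tree),
                 "skipping")
  expect_false(any(grepl("aerial", res$pair)))
})

test_that("lifestyle analysis supports per-trait and global correction families", {
  s <- simulate_comparative_dataset(simulation_spec(seed = 4))
  per <- lifestyle_analysis(s$traits, s$tree, traits = c("TbTh", "TbSp"))
  glob <- lifestyle_analysis(s$traits, s$tree, traits = c("TbTh", "TbSp"),
                             family = "global")
  expect_identical(nrow(per), 12L)
  expect_equal(per$p_raw, glob$p_raw)
  # per-trait adjustment within 6 tests, global within 12
  tb <- per$trait == "TbTh"
  expect_equal(per$p_adj[tb], bh_adjust(per$p_raw[tb]))
  expect_equal(glob$p_adj, bh_adjust(glob$p_raw))
  expect_true(all(per$p_adj >= per$p_raw - 1e-15))
})

test_that("the VOI edge validates as a size proxy against the cube law", {
  s <- simulate_comparative_dataset(
    simulation_spec(n_species = 30, mass_sigma = 0,
                    lifestyle_counts = c(arboreal = 12, fossorial = 8,
                                         semifossorial = 6, aerial = 4),
                    n_genera = 12, seed = 2))
  v <- validate_size_proxy(s$traits, s$tree)
  expect_equal(v$exponent, 3, tolerance = 1e-8)
  expect_gt(v$p_vs_isometry, 0.99)

  # with the calibrated noise level the deviation test rarely rejects
  res <- vapply(1:50, function(i) {
    s <- simulate_comparative_dataset(
      simulation_spec(n_species = 64,
                      lifestyle_counts = c(arboreal = 25, fossorial = 18,
                                           semifossorial = 13, aerial = 8),
                      n_genera = 30, seed = i))
    v <- validate_size_proxy(s$traits, s$tree)
    c(r2 = v$r_squared, ns = v$p_vs_isometry > 0.05)
  }, c(r2 = 0, ns = 0))
  expect_equal(mean(res["r2", ]), 0.92, tolerance = 0.05)
  expect_gt(mean(res["ns", ]), 0.8)

  # shuffled masses carry no signal
  sh <- s$traits
  sh$mass <- withr::with_seed(9, sample(sh$mass))
  expect_lt(validate_size_proxy(sh, s$tree)$r_squared, 0.3)

  expect_error(validate_size_proxy(s$traits[1:5, ], s$tree), "at least 10")
})
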