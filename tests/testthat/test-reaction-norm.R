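test_that("build_kernels produces the documented kernel structure", {
  # unrelated founders, one record per line -> K_a = I
  A <- diag(4)
  dimnames(A) <- list(paste0("L", 1:4), paste0("L", 1:4))
  rec <- data.frame(line = paste0("L", 1:4), env = "E1")
  ks <- build_kernels(A, rec, model = "AE")
  expect_equal(ks$kernels$a, diag(4))
  expect_equal(ks$kernels$E, matrix(1, 4, 4))

  # same line in two environments: K_aE entry 0, K_a entry = diag of A
  ped <- six_pedigree()
  A6 <- build_A(ped)
  rec2 <- data.frame(line = c("E", "E"), env = c("X", "Y"))
  ks2 <- build_kernels(A6, rec2, model = "AE-AxE")
  expect_equal(ks2$kernels$aE[1, 2], 0)
  expect_equal(ks2$kernels$a[1, 2], A6["E", "E"])

  # 4-record toy: full sibs C,D in environments X,Y; hand Hadamard
  rec3 <- data.frame(line = c("C", "D", "C", "D"),
                     env = c("X", "X", "Y", "Y"))
  ks3 <- build_kernels(A6, rec3, model = "AE-AxE")
  KE <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
              c(0, 0, 1, 1), c(0, 0, 1, 1))
  Ka <- A6[c("C", "D", "C", "D"), c("C", "D", "C", "D")]
  dimnames(Ka) <- NULL
  expect_equal(ks3$kernels$E, KE)
  expect_equal(ks3$kernels$aE, Ka * KE)

  # covariate kernel is centered/scaled and 1/q-scaled
  set.seed(8)
  W <- matrix(rnorm(6), 2, 3, dimnames = list(c("X", "Y"), NULL))
  ks4 <- build_kernels(A6, rec3, W = W, model = "AE-AxE-W-AxW")
  Ws <- scale(W)
  Kw_env <- tcrossprod(Ws) / 3
  expect_equal(ks4$kernels$W[1, 3], Kw_env["X", "Y"])
  expect_equal(ks4$kernels$aW, ks4$kernels$a * ks4$kernels$W)

  expect_error(build_kernels(A6, data.frame(line = "nope", env = "X")),
               "mapping error")
})

test_that("fixed-variance posterior mean equals the kernel-ridge solution", {
  set.seed(31)
  ped <- simulate_pedigree(sim_spec(n_cycles = 2L, lines_per_cycle = 9L,
                                    n_founders = 6L, sub_blocks = 5L,
                                    seed = 2L))
  A <- build_A(ped)
  lines <- rownames(A)[5:24]
  rec <- data.frame(line = lines, env = "E1")
  ks <- build_kernels(A, rec, model = "AE")
  ks$kernels <- ks$kernels["a"]
  y <- rnorm(20)
  fit <- fit_gibbs(y, ks, fix_variances = c(a = 0.5, residual = 0.2))
  # oracle: direct solve of the (sigma2_a K + sigma2_e I) system
  K <- A[lines, lines]
  Vi <- solve(0.5 * K + diag(0.2, 20))
  mu <- sum(Vi %*% y) / sum(Vi)
  pred <- as.numeric(mu + 0.5 * K %*% Vi %*% (y - mu))
  expect_equal(fit$predictions, pred, tolerance = 1e-6)

  # held-out record gets the conditional-mean prediction
  y2 <- y; y2[20] <- NA
  fit2 <- fit_gibbs(y2, ks, fix_variances = c(a = 0.5, residual = 0.2))
  Vi19 <- solve(0.5 * K[1:19, 1:19] + diag(0.2, 19))
  mu19 <- sum(Vi19 %*% y[1:19]) / sum(Vi19)
  pr20 <- mu19 + 0.5 * K[20, 1:19] %*% Vi19 %*% (y[1:19] - mu19)
  expect_equal(fit2$yhat_test, as.numeric(pr20), tolerance = 1e-6)
})

test_that("the Gibbs sampler is seeded-deterministic and flags bad settings", {
  set.seed(32)
  A <- diag(8); dimnames(A) <- list(paste0("L", 1:8), paste0("L", 1:8))
  rec <- data.frame(line = rep(paste0("L", 1:8), 2),
                    env = rep(c("E1", "E2"), each = 8))
  ks <- build_kernels(A, rec, model = "AE")
  y <- rnorm(16)
  f1 <- fit_gibbs(y, ks, n_iter = 600, burn_in = 100, thin = 2,
                  n_chains = 1L, seed = 5)
  f2 <- fit_gibbs(y, ks, n_iter = 600, burn_in = 100, thin = 2,
                  n_chains = 1L, seed = 5)
  expect_identical(f1$variances, f2$variances)
  expect_identical(f1$predictions, f2$predictions)
  expect_error(fit_gibbs(y, ks, n_iter = 300, burn_in = 200, thin = 2),
               "settings error")
  # non-PSD kernel rejected
  ks_bad <- ks
  ks_bad$kernels$a <- ks$kernels$a - diag(0.5, 16)
  expect_error(fit_gibbs(y, ks_bad, n_iter = 600, burn_in = 100,
                         n_chains = 1L), "positive semidefinite")
})

test_that("degenerate constant response yields constant predictions", {
  A <- diag(6); dimnames(A) <- list(paste0("L", 1:6), paste0("L", 1:6))
  rec <- data.frame(line = paste0("L", 1:6), env = "E1")
  ks <- build_kernels(A, rec, model = "AE")
  y <- rep(2.5, 6)
  fit <- fit_gibbs(y, ks, n_iter = 600, burn_in = 100, thin = 2,
                   n_chains = 1L, seed = 3)
  expect_lt(max(abs(fit$predictions - 2.5)), 0.2)
  expect_lt(fit$variances$mean[fit$variances$component == "a"], 0.05)
})

test_that("pvt computes percentages of total variance", {
  x <- structure(list(variances = data.frame(
    component = c("a", "E", "residual"),
    mean = c(0.06, 1.49, 0.07), sd = 0)), class = "posterior_summary")
  p <- pvt(x)
  expect_equal(round(unname(p), 1), c(3.7, 92.0, 4.3))
  expect_equal(sum(p), 100)
  expect_equal(unname(pvt(c(a = 2, b = 2, c = 2))),
               rep(100 / 3, 3))
  expect_equal(unname(pvt(c(only = 5))), 100)
  expect_error(pvt(c(a = 0, b = 0)), "all components")
})

test_that("predictive_correlation behaves at the extremes and by group", {
  s <- list(yhat_test = c(1, 2, 3, 4, 5, 6))
  expect_equal(predictive_correlation(s, c(1, 2, 3, 4, 5, 6)), 1)
  expect_equal(predictive_correlation(s, -c(1, 2, 3, 4, 5, 6)), -1)
  g <- rep(c("T1", "T2"), each = 3)
  r <- predictive_correlation(s, c(1, 2, 3, 6, 5, 4), groups = g)
  expect_equal(unname(r), c(1, -1))
  expect_warning(predictive_correlation(list(yhat_test = c(1, 2)),
                                        c(1, 2)), "fewer than 3")
  expect_warning(predictive_correlation(list(yhat_test = rep(1, 5)),
                                        c(1, 2, 3, 4, 5)),
                 "zero variance")
})

test_that("covariate-aware model beats AE when covariate effects exist", {
  # paired comparison on a few seeds; W carries real signal
  spec <- sim_spec(rn_variances = list(sigma2_a = 0.05, sigma2_E = 0.3,
                                       sigma2_aE = 0.05, sigma2_W = 0.6,
                                       sigma2_aW = 0.05, sigma2_e = 0.2),
                   seed = 1L)
  ped <- simulate_pedigree(sim_spec(n_cycles = 2L, n_founders = 20L,
                                    seed = 40L))
  A <- build_A(ped)
  lines <- grep("^L", rownames(A), value = TRUE)[1:30]
  set.seed(41)
  W <- matrix(rnorm(16 * 8), 16, 8,
              dimnames = list(paste0("E", 1:16), paste0("w", 1:8)))
  diffs <- sapply(1:20, function(s) {
    sim <- simulate_reaction_norm(spec, A, W, lines = lines,
                                  envs = rownames(W), seed = 100L + s)
    y <- sim$records$y
    test <- sim$records$env %in% c("E15", "E16")
    y_tr <- y; y_tr[test] <- NA
    fit_w <- fit_gibbs(y_tr, build_kernels(A, sim$records[, 1:2], W = W,
                                           model = "AE-AxE-W-AxW"),
                       n_iter = 800, burn_in = 200, thin = 2,
                       n_chains = 1L, seed = s)
    fit_0 <- fit_gibbs(y_tr, build_kernels(A, sim$records[, 1:2],
                                           model = "AE"),
                       n_iter = 800, burn_in = 200, thin = 2,
                       n_chains = 1L, seed = s)
    predictive_correlation(fit_w, y[test]) -
      predictive_correlation(fit_0, y[test])
  })
  expect_gt(mean(diffs), 0)
})
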