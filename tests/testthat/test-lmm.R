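test_that("balanced one-way REML equals the ANOVA closed form", {
  set.seed(10)
  g <- 8L; n <- 6L
  geno <- rep(sprintf("G%d", 1:g), each = n)
  y <- 5 + rep(rnorm(g, 0, sqrt(0.4)), each = n) +
    rnorm(g * n, 0, sqrt(0.3))
  tt <- as_trial_table(data.frame(
    cycle_year = 2010L, site_id = "s1", group_label = "1",
    group_kind = "TPE", replicate = rep(1:n, times = g), sub_block = 1L,
    genotype_id = geno, is_local_check = FALSE, grain_yield = y))
  vc <- fit_reml(tt, model_spec("eq7"), nr = n, ne = 1L)
  means <- tapply(y, geno, mean)
  ms_within <- sum((y - means[geno])^2) / (g * (n - 1))
  ms_between <- n * sum((means - mean(y))^2) / (g - 1)
  expect_equal(unname(vc$components[["g"]]),
               (ms_between - ms_within) / n, tolerance = 1e-6)
  expect_equal(unname(vc$components[["residual"]]), ms_within,
               tolerance = 1e-6)

  # within-group-(near-)constant data: residual ~0, genotype variance =
  # variance of the group means (REML of the balanced one-way layout);
  # a sub-numerical jitter keeps the optimizer's linear algebra finite
  y2 <- rep(c(1, 3, 5, 7, 9, 11, 13, 15), each = n) +
    rnorm(g * n, 0, 1e-3)
  tt2 <- tt
  tt2$grain_yield <- y2
  vc2 <- fit_reml(as_trial_table(as.data.frame(tt2)), model_spec("eq7"),
                  nr = n, ne = 1L)
  expect_equal(unname(vc2$components[["residual"]]), 0, tolerance = 1e-6)
  means2 <- tapply(y2, geno, mean)
  expect_equal(unname(vc2$components[["g"]]),
               var(as.numeric(means2)), tolerance = 1e-3)
})

test_that("REML equals the brute-force restricted-likelihood grid maximizer", {
  # 3 genotypes x 2 environments x 2 replicates, eq3 structure
  set.seed(21)
  d <- expand.grid(genotype_id = c("G1", "G2", "G3"),
                   site_id = c("sA", "sB"), replicate = 1:2,
                   stringsAsFactors = FALSE)
  d$cycle_year <- 2010L; d$group_label <- "1"; d$group_kind <- "TPE"
  d$sub_block <- 1L; d$is_local_check <- FALSE
  g_eff <- c(G1 = -0.8, G2 = 0.1, G3 = 0.7)
  ge_eff <- rnorm(6, 0, 0.4)
  names(ge_eff) <- paste(rep(c("G1", "G2", "G3"), 2),
                         rep(c("sA", "sB"), each = 3))
  d$grain_yield <- 5 + (d$site_id == "sB") * 0.5 +
    g_eff[d$genotype_id] + ge_eff[paste(d$genotype_id, d$site_id)] +
    rnorm(12, 0, 0.3)
  tt <- as_trial_table(d)
  vc <- fit_reml(tt, model_spec("eq3"))

  env <- paste(d$site_id, d$cycle_year, sep = "_")
  X <- cbind(1, as.integer(d$site_id == "sB"))
  Z <- list(r = Zmat(d$replicate),
            r_e = Zmat(paste(env, d$replicate)),
            g = Zmat(d$genotype_id),
            g_e = Zmat(paste(d$genotype_id, env)))
  oracle <- grid_reml(d$grain_yield, X, Z, upper = 2, n_grid = 7L,
                      n_rounds = 12L)
  expect_lt(abs(vc$components[["g"]] - oracle[["g"]]), 1e-4)
  expect_lt(abs(vc$components[["g_e"]] - oracle[["g_e"]]), 1e-4)
  expect_lt(abs(vc$components[["residual"]] - oracle[["residual"]]), 1e-4)
})

test_that("heritability implements the entry-mean formulas", {
  # plug-in with the published multi-year average components
  expect_equal(round(heritability("plugin",
                                  v_g_total = 0.0311 + 0.0118,
                                  v_z = 0.06), 2), 0.72)
  # across-environment arithmetic oracle
  expect_equal(heritability("across_env", v_g = 0.05, v_ge = 0.16,
                            v_r = 0.20, ne = 14, nr = 2),
               0.05 / (0.05 + 0.16 / 14 + 0.20 / 28), tolerance = 1e-12)
  expect_equal(round(heritability("across_env", v_g = 0.05, v_ge = 0.16,
                                  v_r = 0.20, ne = 14, nr = 2), 4),
               0.7292)
  # noiseless limit
  expect_equal(heritability("across_env", v_g = 0.3, v_ge = 0, v_r = 0,
                            ne = 5, nr = 2), 1)
  # monotone in ne and nr
  h <- sapply(1:6, function(ne) heritability("across_env", v_g = 0.1,
                                             v_ge = 0.2, v_r = 0.3,
                                             ne = ne, nr = 2))
  expect_true(all(diff(h) > 0))
  expect_true(is.na(heritability("plugin", v_g_total = 0, v_z = 0)))
})

test_that("fit_blues reduces to genotype means and recovers known shifts", {
  # no random effects, balanced -> arithmetic genotype means
  tt <- make_trials(n_sites = 1L, n_reps = 3L, n_geno = 4L,
                    geno_shift = c(G01 = 0, G02 = 0.5, G03 = -0.2,
                                   G04 = 1), noise_sd = 0)
  b <- fit_blues(tt, random = character(0))
  means <- tapply(tt$grain_yield, tt$genotype_id, mean)
  expect_equal(setNames(b$blue, b$genotype_id),
               setNames(as.numeric(means), names(means)),
               tolerance = 1e-10)

  # +0.5 t/ha shift for G02 recovered under noise and site effects
  tt2 <- make_trials(n_sites = 6L, n_reps = 2L, n_geno = 5L,
                     geno_shift = c(G01 = 0, G02 = 0.5, G03 = 0,
                                    G04 = 0, G05 = 0),
                     noise_sd = 0.2, seed = 33L)
  b2 <- fit_blues(tt2, random = c("env", "env:rep"))
  diff <- b2$blue[b2$genotype_id == "G02"] -
    b2$blue[b2$genotype_id == "G01"]
  expect_lt(abs(diff - 0.5), 0.2)

  # genotype absent from the group is flagged NA by met_blues
  tt3 <- as.data.frame(tt2)
  tt3 <- tt3[tt3$genotype_id != "G05" | tt3$site_id != "S01", ]
  tt3b <- tt3[tt3$site_id == "S01", ]
  long <- met_blues(as_trial_table(rbind(tt3b)), kind = "TPE")
  expect_false("G05" %in% long$genotype_id[!is.na(long$blue)])
})

test_that("eq4 and eq8 fits recover generator structure on a small network", {
  spec <- small_sim_spec(seed = 8L)
  sim <- simulate_trials(spec)
  tpe <- sim$trials[sim$trials$group_kind == "TPE" &
                      sim$trials$cycle_year == spec$years[1L], ]
  vc <- fit_reml(as_trial_table(tpe), model_spec("eq4"))
  expect_true(all(vc$components >= 0))
  expect_true(vc$h2 >= 0 && vc$h2 <= 1)
  expect_true(vc$v_z >= vc$components[["g"]] + vc$components[["g_tpe"]])
  expect_equal(vc$ne, length(unique(paste(tpe$site_id, tpe$cycle_year))))
  se <- sim$trials[sim$trials$group_kind == "SE" &
                     sim$trials$cycle_year == spec$years[1L], ]
  vc8 <- fit_reml(as_trial_table(se), model_spec("eq8"))
  expect_equal(vc8$ne, 5L)
  expect_named(vc8$blups)
})
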