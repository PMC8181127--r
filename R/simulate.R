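#' Simulation specification for a synthetic ESWYT-like trial network
#'
#' Defaults state the structure of the real network the analysis targets:
#' 41 Indian sites in 3 TPE groups (15/8/18), 13 annual cycles with no
#' genotype connectivity between cycles (49 lines plus one site-specific
#' local check, 2 replicates, 5 alpha-lattice sub-blocks of 10 entries),
#' 5 managed selection environments at one station, TPE-level covariate
#' means from the published network summary, and variance components at
#' the published multi-year averages (in (t/ha)^2).
#'
#' @param n_cycles Number of annual cycles.
#' @param lines_per_cycle Lines per cycle (a local check is added per
#'   site).
#' @param sites_per_tpe Integer vector of sites in each TPE.
#' @param n_se Number of selection environments.
#' @param replicates,sub_blocks Replicates and sub-blocks per replicate;
#'   `(lines_per_cycle + 1)` must be divisible by `sub_blocks`.
#' @param mu Overall mean yield, t/ha.
#' @param tpe_means Fixed TPE mean yields, t/ha.
#' @param se_means Named SE mean yields, t/ha.
#' @param variances Named list of ANOVA-mode components, (t/ha)^2:
#'   `v_e` environment-within-TPE, `v_g` genotype, `v_g_tpe`
#'   genotype-by-TPE, `v_ge` genotype-by-environment within TPE, `v_r`
#'   replicate-within-environment, `v_sb` sub-block, `v_res` residual.
#' @param se_variances Named list for the SE side: `v_g`, `v_g_se`,
#'   `v_sb`, `v_res`.
#' @param rho_se_tpe Genetic correlation between a line's SE-side and
#'   TPE-side genotypic effects.
#' @param p_dropout Probability a site-year trial is not grown (the real
#'   network realizes 245 of 533 site-year cells, i.e. ~54% dropout).
#' @param covariate_dispersion Site/year/daily noise of the covariate
#'   generator, as fractions of each variable's between-TPE standard
#'   deviation.
#' @param n_cov_years Years of daily weather per site.
#' @param rn_variances Reaction-norm-mode components: `sigma2_a`,
#'   `sigma2_E`, `sigma2_aE`, `sigma2_W`, `sigma2_aW`, `sigma2_e`.
#' @param n_founders Pedigree founders.
#' @param seed RNG seed recorded in the spec.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_cycles = 13L, lines_per_cycle = 49L,
                     sites_per_tpe = c(15L, 8L, 18L), n_se = 5L,
                     replicates = 2L, sub_blocks = 5L,
                     mu = 4.7,
                     tpe_means = c(5.1, 3.7, 4.8),
                     se_means = c(B5IR = 7.1, B2IR = 4.8, BLHT = 3.7,
                                  F5IR = 6.7, FDRT = 2.5),
                     variances = list(v_e = 1.6364, v_g = 0.0311,
                                      v_g_tpe = 0.0118, v_ge = 0.1611,
                                      v_r = 0.0152, v_sb = 0.0504,
                                      v_res = 0.1967),
                     se_variances = list(v_g = 0.1046, v_g_se = 0.0447,
                                         v_sb = 0.1164, v_res = 0.1531),
                     rho_se_tpe = 0.6,
                     p_dropout = 0.54,
                     covariate_dispersion = list(site = 0.2, year = 0.2,
                                                 daily = 0.5),
                     n_cov_years = 3L,
                     rn_variances = list(sigma2_a = 0.05, sigma2_E = 1.0,
                                         sigma2_aE = 0.05, sigma2_W = 0.3,
                                         sigma2_aW = 0.02, sigma2_e = 0.2),
                     n_founders = 60L,
                     seed = 1L) {
  stopifnot(all(unlist(variances) >= 0), all(unlist(se_variances) >= 0),
            all(unlist(rn_variances) >= 0),
            p_dropout >= 0, p_dropout < 1)
  if ((lines_per_cycle + 1L) %% sub_blocks != 0L)
    stop("design error: sub_blocks must divide lines_per_cycle + 1")
  years <- if (n_cycles == 13L) c(2001L, 2005:2016)
           else seq(2001L, length.out = n_cycles)
  structure(list(n_cycles = n_cycles, years = years,
                 lines_per_cycle = lines_per_cycle,
                 sites_per_tpe = sites_per_tpe, n_se = n_se,
                 replicates = replicates, sub_blocks = sub_blocks,
                 mu = mu, tpe_means = tpe_means, se_means = se_means,
                 variances = variances, se_variances = se_variances,
                 rho_se_tpe = rho_se_tpe, p_dropout = p_dropout,
                 covariate_dispersion = covariate_dispersion,
                 n_cov_years = n_cov_years, rn_variances = rn_variances,
                 n_founders = n_founders, seed = as.integer(seed)),
            class = "sim_spec")
}

line_ids <- function(spec) {
  lapply(seq_len(spec$n_cycles), function(c) {
    sprintf("L%04d_%02d", spec$years[c], seq_len(spec$lines_per_cycle))
  })
}

#' Simulate a multi-cycle pedigree
#'
#' Founders are unrelated and non-inbred; each cycle's lines are biparental
#' crosses of parents drawn from the previous cycle (founders for cycle 1),
#' so the additive relationship matrix connects trial years that share no
#' genotypes.
#'
#' @param spec A `sim_spec`.
#' @param seed Optional seed overriding `spec$seed`.
#' @return A topologically ordered `pedigree_table`.
#' @export
simulate_pedigree <- function(spec = sim_spec(), seed = spec$seed) {
  if (spec$n_founders < 2L) stop("need at least 2 founders")
  set.seed(seed)
  founders <- sprintf("F%03d", seq_len(spec$n_founders))
  ids <- founders
  p1 <- rep(NA_character_, length(founders))
  p2 <- rep(NA_character_, length(founders))
  pool <- founders
  for (lines in line_ids(spec)) {
    pa <- character(length(lines)); pb <- character(length(lines))
    for (i in seq_along(lines)) {
      pr <- sample(pool, 2L, replace = FALSE)
      pa[i] <- pr[1L]; pb[i] <- pr[2L]
    }
    ids <- c(ids, lines); p1 <- c(p1, pa); p2 <- c(p2, pb)
    pool <- lines
  }
  as_pedigree_table(data.frame(id = ids, parent1 = p1, parent2 = p2,
                               stringsAsFactors = FALSE))
}

#' Simulate daily meteorological series and the windowed covariate table
#'
#' Each site inherits its TPE's published mean for every variable, plus a
#' site offset, a year offset, and daily noise (all Gaussian, with
#' standard deviations set as fractions of the variable's between-TPE
#' standard deviation); soil variables are static per site. With all
#' dispersions zero every site's windowed means equal its TPE means
#' exactly.
#'
#' @param spec A `sim_spec`.
#' @param seed Optional seed.
#' @return List: `daily` (site_id, year, variable, date, value), `soil`
#'   (site_id, variable, value), `covariates` (site x 63 matrix from
#'   [window_aggregate()]), `tpe_labels` (named integer ground truth).
#' @export
simulate_covariates <- function(spec = sim_spec(), seed = spec$seed) {
  set.seed(seed + 1L)
  means <- load_reference_table("covariate_means")
  disp <- spec$covariate_dispersion
  n_tpe <- length(spec$sites_per_tpe)
  site_tpe <- rep(seq_len(n_tpe), spec$sites_per_tpe)
  sites <- sprintf("S%02d_T%d", seq_along(site_tpe), site_tpe)
  names(site_tpe) <- sites
  years <- seq(2014L, length.out = spec$n_cov_years)
  span <- 120L
  mv <- means[means$type == "MV", ]
  sv <- means[means$type == "SV", ]
  daily <- list()
  for (v in seq_len(nrow(mv))) {
    tpe_mu <- as.numeric(mv[v, c("tpe1", "tpe2", "tpe3")])[site_tpe]
    sd_b <- sd(as.numeric(mv[v, c("tpe1", "tpe2", "tpe3")]))
    site_dev <- rnorm(length(sites), 0, disp$site * sd_b)
    for (yi in seq_along(years)) {
      year_dev <- rnorm(length(sites), 0, disp$year * sd_b)
      vals <- rep(tpe_mu + site_dev + year_dev, each = span) +
        rnorm(length(sites) * span, 0, disp$daily * sd_b)
      start <- as.Date(paste0(years[yi], "-11-23"))
      daily[[length(daily) + 1L]] <- data.frame(
        site_id = rep(sites, each = span),
        year = years[yi],
        variable = mv$variable[v],
        date = rep(start + 0:(span - 1L), times = length(sites)),
        value = vals, stringsAsFactors = FALSE)
    }
  }
  daily <- do.call(rbind, daily)
  soil <- do.call(rbind, lapply(seq_len(nrow(sv)), function(v) {
    tpe_mu <- as.numeric(sv[v, c("tpe1", "tpe2", "tpe3")])[site_tpe]
    sd_b <- sd(as.numeric(sv[v, c("tpe1", "tpe2", "tpe3")]))
    data.frame(site_id = sites, variable = sv$variable[v],
               value = tpe_mu + rnorm(length(sites), 0, disp$site * sd_b),
               stringsAsFactors = FALSE)
  }))
  covariates <- window_aggregate(daily, soil = soil)
  list(daily = daily, soil = soil, covariates = covariates,
       tpe_labels = site_tpe)
}

# alpha-lattice incidence: entries shuffled into sub_blocks blocks per rep
alpha_blocks <- function(entries, sub_blocks) {
  shuffled <- sample(entries)
  split(shuffled, rep(seq_len(sub_blocks),
                      each = length(entries) / sub_blocks))
}

#' Simulate trial phenotypes with known ground truth
#'
#' ANOVA mode draws every effect of the across-TPE trial model (genotype,
#' genotype-by-TPE, genotype-by-environment, environment-within-TPE,
#' replicate, sub-block, residual) from zero-mean Gaussians at the spec's
#' variances, plus fixed TPE/SE means; each cycle uses a fresh line set
#' (connected across cycles only through the pedigree when one is given,
#' in which case line effects are drawn with covariance `sigma2_a * A`).
#' Selection-environment records are generated at a single station with
#' SE-specific means, sharing line genetic effects with the TPE side at
#' genetic correlation `rho_se_tpe`. Site-year dropout makes the network
#' unbalanced.
#'
#' @param spec A `sim_spec`.
#' @param pedigree Optional ordered `pedigree_table`; its A matrix then
#'   structures the line effects.
#' @param covariates Optional result of [simulate_covariates()] (used only
#'   for its ground-truth TPE labels; otherwise labels are generated).
#' @param seed Optional seed.
#' @return List: `trials` (a `trial_table` with TPE and SE records) and
#'   `truth` (line effects, environment effects, variance components, TPE
#'   labels, seed).
#' @export
simulate_trials <- function(spec = sim_spec(), pedigree = NULL,
                            covariates = NULL, seed = spec$seed) {
  set.seed(seed + 2L)
  v <- spec$variances
  vs <- spec$se_variances
  n_tpe <- length(spec$sites_per_tpe)
  if (!is.null(covariates)) {
    site_tpe <- covariates$tpe_labels
  } else {
    site_tpe <- rep(seq_len(n_tpe), spec$sites_per_tpe)
    names(site_tpe) <- sprintf("S%02d_T%d", seq_along(site_tpe), site_tpe)
  }
  sites <- names(site_tpe)
  ids_by_cycle <- line_ids(spec)
  A_chol <- NULL
  if (!is.null(pedigree)) {
    A <- build_A(pedigree)
    all_lines <- unlist(ids_by_cycle)
    if (!all(all_lines %in% rownames(A)))
      stop("pedigree does not cover the simulated line ids")
    A_chol <- chol(A[all_lines, all_lines] +
                   diag(1e-8, length(all_lines)))
  }
  n_lines_tot <- spec$n_cycles * spec$lines_per_cycle
  base_u <- if (is.null(A_chol)) rnorm(n_lines_tot)
            else as.numeric(crossprod(A_chol, rnorm(n_lines_tot)))
  names(base_u) <- unlist(ids_by_cycle)
  indep_u <- rnorm(n_lines_tot)
  g_tpe_side <- sqrt(v$v_g) * base_u
  g_se_side <- sqrt(vs$v_g) * (spec$rho_se_tpe * base_u +
                               sqrt(1 - spec$rho_se_tpe^2) * indep_u)
  names(g_se_side) <- names(base_u)

  trial_rows <- list()
  env_rows <- list()
  entries_n <- spec$lines_per_cycle + 1L
  for (ci in seq_len(spec$n_cycles)) {
    yr <- spec$years[ci]
    lines <- ids_by_cycle[[ci]]
    g_x_tpe <- matrix(rnorm(length(lines) * n_tpe, 0, sqrt(v$v_g_tpe)),
                      length(lines), n_tpe, dimnames = list(lines, NULL))
    grown <- sites[runif(length(sites)) >= spec$p_dropout]
    if (!length(grown)) grown <- sample(sites, 1L)
    for (s in grown) {
      k <- site_tpe[[s]]
      e_eff <- rnorm(1, 0, sqrt(v$v_e))
      env_rows[[paste(s, yr)]] <- data.frame(site_id = s, cycle_year = yr,
                                             tpe = k, effect = e_eff)
      ge <- setNames(rnorm(length(lines), 0, sqrt(v$v_ge)), lines)
      check_id <- paste0("CHK_", s)
      check_mean <- rnorm(1, 0, sqrt(v$v_g))
      entries <- c(lines, check_id)
      gvals <- c(g_tpe_side[lines] + g_x_tpe[lines, k] + ge[lines],
                 setNames(check_mean, check_id))
      for (r in seq_len(spec$replicates)) {
        r_eff <- rnorm(1, 0, sqrt(v$v_r))
        blocks <- alpha_blocks(entries, spec$sub_blocks)
        sb_eff <- rnorm(spec$sub_blocks, 0, sqrt(v$v_sb))
        gid <- unlist(blocks, use.names = FALSE)
        blk <- rep(seq_along(blocks), lengths(blocks))
        y <- spec$tpe_means[k] + e_eff + gvals[gid] + r_eff +
          sb_eff[blk] + rnorm(length(gid), 0, sqrt(v$v_res))
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          cycle_year = yr, site_id = s, group_label = as.character(k),
          group_kind = "TPE", replicate = r, sub_block = blk,
          genotype_id = gid, is_local_check = gid == check_id,
          grain_yield = unname(y), stringsAsFactors = FALSE)
      }
    }
    # selection environments at one station
    g_x_se <- matrix(rnorm(length(lines) * spec$n_se, 0, sqrt(vs$v_g_se)),
                     length(lines), spec$n_se, dimnames = list(lines, NULL))
    se_check <- "CHK_OBREGON"
    se_check_mean <- rnorm(1, 0, sqrt(vs$v_g))
    gvals_se <- c(g_se_side[lines], setNames(se_check_mean, se_check))
    entries_se <- c(lines, se_check)
    for (si in seq_len(spec$n_se)) {
      se_lab <- names(spec$se_means)[si]
      gx <- c(g_x_se[lines, si], setNames(0, se_check))
      for (r in seq_len(spec$replicates)) {
        blocks <- alpha_blocks(entries_se, spec$sub_blocks)
        sb_eff <- rnorm(spec$sub_blocks, 0, sqrt(vs$v_sb))
        gid <- unlist(blocks, use.names = FALSE)
        blk <- rep(seq_along(blocks), lengths(blocks))
        y <- spec$se_means[[si]] + gvals_se[gid] + gx[gid] +
          sb_eff[blk] + rnorm(length(gid), 0, sqrt(vs$v_res))
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          cycle_year = yr, site_id = "OBREGON", group_label = se_lab,
          group_kind = "SE", replicate = r, sub_block = blk,
          genotype_id = gid, is_local_check = gid == se_check,
          grain_yield = unname(y), stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  # physical floor: yields cannot be negative; the Gaussian tail below 0
  # is censored (a fraction of a percent of records at default variances)
  trials$grain_yield[trials$grain_yield < 0] <- 0
  trials <- as_trial_table(trials)
  truth <- list(
    line_effects = data.frame(genotype_id = names(base_u),
                              u = base_u, g_tpe_side = g_tpe_side,
                              g_se_side = g_se_side,
                              stringsAsFactors = FALSE),
    env_effects = do.call(rbind, env_rows),
    variances = v, se_variances = vs, tpe_labels = site_tpe,
    seed = seed)
  list(trials = trials, truth = truth)
}

#' Simulate line-by-environment records under the reaction-norm model
#'
#' Generative counterpart of the covariate-kernel prediction model:
#' `y = mu + E_i + a_j + aE_ij + t_ij + at_ij + e`, where `a ~ N(0,
#' sigma2_a A)`, the line-by-environment term has the Hadamard covariance
#' `(Z A Z') o (Z_E Z_E')`, `t = W gamma` with iid covariate effects, and
#' `at` has covariance `(Z A Z') o (W W'/q)`.
#'
#' @param spec A `sim_spec` (components read from `spec$rn_variances`).
#' @param A Additive relationship matrix over the lines.
#' @param W Environment x covariate matrix (centered/scaled internally).
#' @param lines,envs Character vectors naming lines (rows of `A`) and
#'   environments (rows of `W`).
#' @param mu Intercept.
#' @param seed Seed.
#' @return List: `records` (line, env, y), `truth` (the drawn effects and
#'   the variance components).
#' @export
simulate_reaction_norm <- function(spec = sim_spec(), A, W, lines = rownames(A),
                                   envs = rownames(W), mu = 0,
                                   seed = spec$seed) {
  set.seed(seed + 3L)
  p <- spec$rn_variances
  A <- A[lines, lines]
  W <- scale(W[envs, , drop = FALSE])
  W <- W[, apply(W, 2L, function(x) all(is.finite(x))), drop = FALSE]
  q <- ncol(W)
  nl <- length(lines); nE <- length(envs)
  L <- chol(A + diag(1e-8, nl))
  a <- sqrt(p$sigma2_a) * as.numeric(crossprod(L, rnorm(nl)))
  E <- rnorm(nE, 0, sqrt(p$sigma2_E))
  aE <- sqrt(p$sigma2_aE) *
    vapply(seq_len(nE), function(i) as.numeric(crossprod(L, rnorm(nl))),
           numeric(nl))                       # lines x envs
  gamma <- rnorm(q, 0, sqrt(p$sigma2_W / q))
  t_env <- as.numeric(W %*% gamma)            # per environment
  at <- matrix(0, nl, nE)
  for (k in seq_len(q)) {
    zk <- as.numeric(crossprod(L, rnorm(nl)))
    at <- at + outer(zk, W[, k] / sqrt(q))
  }
  at <- sqrt(p$sigma2_aW) * at
  rec <- expand.grid(line = lines, env = envs, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  li <- match(rec$line, lines); ei <- match(rec$env, envs)
  rec$y <- mu + E[ei] + a[li] + aE[cbind(li, ei)] + t_env[ei] +
    at[cbind(li, ei)] + rnorm(nrow(rec), 0, sqrt(p$sigma2_e))
  list(records = rec,
       truth = list(a = setNames(a, lines), E = setNames(E, envs),
                    t = setNames(t_env, envs), variances = p, W = W))
}
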