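#' Describe a mixed-model template for trial analysis
#'
#' The four templates mirror the standard multi-environment trial models
#' for this kind of network:
#' \itemize{
#'   \item `eq3` — per-year analysis across sites: environment fixed;
#'     replicate, replicate-within-environment, genotype and
#'     genotype-by-environment random.
#'   \item `eq4` — per-year analysis across sites with TPE structure: TPE
#'     fixed; genotype, genotype-by-TPE, genotype-by-environment(within
#'     TPE), environment(within TPE), replicate-within-environment and
#'     sub-block random.
#'   \item `eq7` — single selection-environment trial: replicate,
#'     sub-block-within-replicate and genotype random.
#'   \item `eq8` — across selection environments: SE fixed; replicate,
#'     sub-block-within-SE-and-replicate, genotype and genotype-by-SE
#'     random.
#' }
#'
#' @param template One of `"eq3"`, `"eq4"`, `"eq7"`, `"eq8"`.
#' @param response Response column, default `"grain_yield"`.
#' @param drop_checks Exclude local-check rows (they differ by site, so
#'   they carry no across-site genetic signal). Default `TRUE`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(template = c("eq3", "eq4", "eq7", "eq8"),
                       response = "grain_yield", drop_checks = TRUE) {
  template <- match.arg(template)
  structure(list(template = template, response = response,
                 drop_checks = drop_checks), class = "model_spec")
}

# factor columns used by the formula templates
prepare_met_frame <- function(data, spec) {
  df <- as.data.frame(data)
  if (spec$drop_checks && "is_local_check" %in% names(df))
    df <- df[!df$is_local_check, , drop = FALSE]
  df <- df[!is.na(df[[spec$response]]), , drop = FALSE]
  df$y <- df[[spec$response]]
  df$genotype <- factor(df$genotype_id)
  df$env <- factor(paste(df$site_id, df$cycle_year, sep = "_"))
  df$rep_f <- factor(df$replicate)
  df$sb_f <- factor(df$sub_block)
  if (spec$template %in% c("eq4"))
    df$tpe <- factor(df$group_label)
  if (spec$template %in% c("eq8"))
    df$se <- factor(df$group_label)
  df
}

met_formula <- function(template) {
  switch(template,
    eq3 = y ~ env + (1 | rep_f) + (1 | env:rep_f) + (1 | genotype) +
      (1 | genotype:env),
    eq4 = y ~ tpe + (1 | genotype) + (1 | genotype:tpe) +
      (1 | genotype:env) + (1 | env) + (1 | env:rep_f) +
      (1 | env:rep_f:sb_f),
    eq7 = y ~ 1 + (1 | rep_f) + (1 | rep_f:sb_f) + (1 | genotype),
    eq8 = y ~ se + (1 | rep_f) + (1 | se:rep_f:sb_f) + (1 | genotype) +
      (1 | genotype:se))
}

# canonical component names from lme4 grouping-factor names
component_name <- function(grp) {
  map <- c("genotype" = "g",
           "genotype:tpe" = "g_tpe",
           "genotype:env" = "g_e",
           "genotype:se" = "g_se",
           "env" = "e",
           "rep_f" = "r",
           "env:rep_f" = "r_e",
           "env:rep_f:sb_f" = "sb",
           "rep_f:sb_f" = "sb",
           "se:rep_f:sb_f" = "sb")
  out <- unname(map[grp])
  out[is.na(out)] <- grp[is.na(out)]
  out
}

#' Fit a trial mixed model by REML
#'
#' Fits the requested template with \pkg{lme4}; variance components are
#' constrained to be nonnegative (boundary estimates are reported as exact
#' zeros). Returns the named variance components, the phenotypic variance
#' on an entry-mean basis, broad-sense heritability, and genotype BLUPs.
#'
#' @param data A `trial_table` (usually one cycle year).
#' @param spec A `model_spec`.
#' @param nr Number of replicates entering the entry-mean variance;
#'   defaults to the maximum replicate number in the data.
#' @param ne Number of environments; defaults to the number of site-year
#'   (or SE) levels contributing data.
#' @return A `variance_components` list with elements `components`
#'   (named numeric, residual included as `"residual"`), `v_z`, `h2`,
#'   `ne`, `nr`, `blups` (genotype effects), `logLik`, `fit`.
#' @export
fit_reml <- function(data, spec = model_spec("eq3"), nr = NULL, ne = NULL) {
  df <- prepare_met_frame(data, spec)
  for (col in all.vars(met_formula(spec$template))) {
    if (col == "y") next
    if (is.factor(df[[col]]) && nlevels(droplevels(df[[col]])) < 2L &&
        col %in% c("genotype"))
      stop("rank warning: fewer than 2 levels for random factor ", col)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(met_formula(spec$template), data = df, REML = TRUE,
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.rankZ = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov, component_name(vc$grp))
  resid_v <- comp[["Residual"]]
  comp <- comp[names(comp) != "Residual"]
  comp[comp < 1e-10] <- 0
  if (is.null(nr)) nr <- max(df$replicate)
  if (is.null(ne)) {
    ne <- if (spec$template == "eq8") nlevels(droplevels(df$se))
          else if (spec$template == "eq7") 1L
          else nlevels(droplevels(df$env))
  }
  h <- met_heritability(comp, resid_v, spec$template, ne, nr)
  blups <- tryCatch({
    re <- lme4::ranef(fit)$genotype
    setNames(re[, 1L], rownames(re))
  }, error = function(e) NULL)
  structure(list(components = c(comp, residual = unname(resid_v)),
                 v_z = h$v_z, h2 = h$h2, ne = ne, nr = nr,
                 template = spec$template,
                 logLik = as.numeric(stats::logLik(fit)),
                 blups = blups, fit = fit),
            class = "variance_components")
}

met_heritability <- function(comp, v_r, template, ne, nr) {
  g <- function(nm) if (nm %in% names(comp)) comp[[nm]] else 0
  if (template == "eq4") {
    num <- g("g") + g("g_tpe")
    v_z <- num + g("g_e") / ne + v_r / (nr * ne)
  } else if (template == "eq8") {
    num <- g("g")
    v_z <- num + g("g_se") / ne + v_r / (nr * ne)
  } else if (template == "eq7") {
    num <- g("g")
    v_z <- num + v_r / nr
  } else {
    num <- g("g")
    v_z <- num + g("g_e") / ne + v_r / (nr * ne)
  }
  list(h2 = if (v_z > 0) num / v_z else NA_real_, v_z = v_z)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Three modes: `across_env` uses `Vg / (Vg + Vge/ne + Vr/(nr ne))`;
#' `across_tpe` adds the genotype-by-TPE variance to the numerator and the
#' within-TPE GE variance to the denominator,
#' `(Vg + Vgtpe) / (Vg + Vgtpe + Vge_tpe/ne + Vr/(nr ne))`; `plugin`
#' divides a total genotypic variance by a phenotypic variance directly.
#'
#' @param mode Heritability form.
#' @param v_g Genotypic variance.
#' @param v_ge Genotype-by-environment variance (across_env mode).
#' @param v_r Residual variance.
#' @param ne,nr Numbers of environments and replicates.
#' @param v_g_tpe Genotype-by-TPE variance (across_tpe mode).
#' @param v_ge_tpe GE-within-TPE variance (across_tpe mode).
#' @param v_g_total,v_z Numerator and phenotypic variance (plugin mode).
#' @return Heritability in [0, 1], or `NA` if the phenotypic variance is 0.
#' @export
heritability <- function(mode = c("across_env", "across_tpe", "plugin"),
                         v_g = NULL, v_ge = 0, v_r = 0, ne = 1, nr = 1,
                         v_g_tpe = 0, v_ge_tpe = 0,
                         v_g_total = NULL, v_z = NULL) {
  mode <- match.arg(mode)
  if (mode == "plugin") {
    if (is.null(v_g_total) || is.null(v_z))
      stop("plugin mode needs v_g_total and v_z")
    if (v_z == 0) return(NA_real_)
    return(v_g_total / v_z)
  }
  if (ne < 1 || nr < 1) stop("ne and nr must be >= 1")
  if (mode == "across_env") {
    denom <- v_g + v_ge / ne + v_r / (nr * ne)
    num <- v_g
  } else {
    denom <- v_g + v_g_tpe + v_ge_tpe / ne + v_r / (nr * ne)
    num <- v_g + v_g_tpe
  }
  if (denom == 0) return(NA_real_)
  num / denom
}

#' Genotype BLUEs for one environment group
#'
#' Fits the group's records with genotype as a fixed effect (cell-means
#' coding, so each coefficient is directly the genotype's adjusted mean)
#' and the supplied design terms as random effects by REML. With no random
#' terms the fit reduces to ordinary least squares, i.e. arithmetic
#' genotype means for balanced data.
#'
#' @param data A `trial_table` subset for one group (e.g. one TPE-year or
#'   one SE-year combination), or any data.frame with the trial columns.
#' @param random Character vector of random terms among `"env"`, `"rep"`,
#'   `"env:rep"`, `"rep:sb"`, `"se:rep:sb"`, `"se"`.
#' @param response Response column.
#' @param drop_checks Exclude local-check rows.
#' @return data.frame of class `blue_table` with columns `genotype_id`,
#'   `blue`; genotypes with no data in the group are absent (callers
#'   merging groups should treat absence as a flagged missing BLUE).
#' @export
fit_blues <- function(data, random = c("env", "env:rep"),
                      response = "grain_yield", drop_checks = TRUE) {
  spec <- list(template = "blue", response = response,
               drop_checks = drop_checks)
  df <- as.data.frame(data)
  if (drop_checks && "is_local_check" %in% names(df))
    df <- df[!df$is_local_check, , drop = FALSE]
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  df$y <- df[[response]]
  df$genotype <- factor(df$genotype_id)
  df$env <- factor(paste(df$site_id, df$cycle_year, sep = "_"))
  df$rep_f <- factor(df$replicate)
  df$sb_f <- factor(df$sub_block)
  if ("group_label" %in% names(df)) df$se <- factor(df$group_label)
  term_map <- c("env" = "(1 | env)", "rep" = "(1 | rep_f)",
                "env:rep" = "(1 | env:rep_f)",
                "rep:sb" = "(1 | rep_f:sb_f)",
                "se" = "(1 | se)",
                "se:rep:sb" = "(1 | se:rep_f:sb_f)")
  random <- random[random %in% names(term_map)]
  # drop random terms whose grouping has a single level (inestimable)
  keep <- vapply(random, function(tm) {
    f <- switch(tm, "env" = df$env, "rep" = df$rep_f,
                "env:rep" = interaction(df$env, df$rep_f, drop = TRUE),
                "rep:sb" = interaction(df$rep_f, df$sb_f, drop = TRUE),
                "se" = df$se,
                "se:rep:sb" = interaction(df$se, df$rep_f, df$sb_f,
                                          drop = TRUE))
    nlevels(droplevels(f)) >= 2L
  }, logical(1))
  random <- random[keep]
  if (length(random)) {
    fml <- stats::as.formula(paste("y ~ 0 + genotype +",
                                   paste(term_map[random], collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.rankZ = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))))
    est <- lme4::fixef(fit)
  } else {
    fit <- lm(y ~ 0 + genotype, data = df)
    est <- coef(fit)
  }
  est <- est[startsWith(names(est), "genotype")]
  out <- data.frame(genotype_id = sub("^genotype", "", names(est)),
                    blue = unname(est), stringsAsFactors = FALSE)
  class(out) <- c("blue_table", "data.frame")
  out
}

#' BLUEs per environment group for a whole trial table
#'
#' Convenience wrapper: splits the table into TPE-year or SE-year groups
#' and computes genotype BLUEs in each with the design terms appropriate
#' for that group kind (sites and replicates-within-site random for TPE
#' groups; sub-blocks random for the SE station groups). Genotypes missing
#' from a group get `NA`.
#'
#' @param trials A `trial_table`.
#' @param kind `"TPE"` for per TPE-year BLUEs, `"SE"` for per-year BLUEs
#'   across all selection environments, `"SE_each"` for per SE-year BLUEs.
#' @param response Response column.
#' @return Long data.frame: `group_label`, `cycle_year`, `genotype_id`,
#'   `blue` (NA when the genotype is absent from the group).
#' @export
met_blues <- function(trials, kind = c("TPE", "SE", "SE_each"),
                      response = "grain_yield") {
  kind <- match.arg(kind)
  df <- as.data.frame(trials)
  if (kind == "TPE") {
    df <- df[df$group_kind == "TPE", ]
    key <- interaction(df$group_label, df$cycle_year, drop = TRUE)
    random <- c("env", "env:rep")
  } else if (kind == "SE") {
    df <- df[df$group_kind == "SE", ]
    key <- factor(df$cycle_year)
    random <- c("se", "se:rep:sb")
  } else {
    df <- df[df$group_kind == "SE", ]
    key <- interaction(df$group_label, df$cycle_year, drop = TRUE)
    random <- c("rep", "rep:sb")
  }
  genos <- sort(unique(df$genotype_id[!df$is_local_check]))
  pieces <- split(df, key)
  rows <- lapply(names(pieces), function(nm) {
    d <- pieces[[nm]]
    b <- fit_blues(d, random = random, response = response)
    full <- merge(data.frame(genotype_id = sort(unique(
      d$genotype_id[!d$is_local_check]))), b, all.x = TRUE)
    data.frame(group_label = if (kind == "SE") "SE"
               else as.character(d$group_label[1L]),
               cycle_year = d$cycle_year[1L],
               genotype_id = full$genotype_id, blue = full$blue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restricted log-likelihood of a variance-component model
#'
#' Direct dense-matrix evaluation of the REML log-likelihood for
#' `y = X b + sum_k u_k + e`, `u_k ~ N(0, s2_k Z_k Z_k')`,
#' `e ~ N(0, s2_e I)`. Intended as an independent oracle for checking REML
#' fits (e.g. by grid search); O(n^3), use on small data only.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full column rank).
#' @param Z_list List of random-effect incidence matrices.
#' @param s2 Vector of variance components, one per element of `Z_list`.
#' @param s2_e Residual variance (> 0).
#' @return Restricted log-likelihood (including constants, comparable to
#'   `logLik` of an lme4 REML fit).
#' @export
restricted_loglik <- function(y, X, Z_list, s2, s2_e) {
  n <- length(y)
  V <- diag(s2_e, n)
  for (k in seq_along(Z_list)) V <- V + s2[k] * tcrossprod(Z_list[[k]])
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  p <- ncol(X)
  -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] +
          sum(r * Vi_r) + (n - p) * log(2 * pi))
}
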