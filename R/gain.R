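#' Genetic gain per TPE by regressing pedigree-model predictions on year
#'
#' For each TPE, fits the two-kernel pedigree model `y = mu + E + a + e`
#' (environment = TPE-year combination, `a ~ N(0, sigma2_a A)`) to the
#' per-cycle genotype BLUEs, with the variance components estimated by
#' REML on the kernel eigenstructure, then regresses the model's predicted
#' line values (`mu + E + a`, the BLUP of each line's performance in its
#' TPE-year) on the cycle year by ordinary least squares. The slope (in
#' kg/ha/year for t/ha responses) is the estimated rate of yield gain.
#'
#' Regressing the full prediction rather than the additive BLUP alone is
#' deliberate: with entries replaced every cycle, a common per-year
#' genetic shift is confounded with the environment term and identifiable
#' only through the pedigree prior, whereas the fitted line value carries
#' the trend however the model partitions it.
#'
#' @param blues data.frame with columns `genotype_id`, `group_label`
#'   (TPE), `cycle_year`, `blue` (t/ha).
#' @param A Additive relationship matrix covering the genotypes.
#' @param variances Optional named vector `c(a=, E=, residual=)` fixing
#'   the variance components instead of estimating them.
#' @param per_line Regress per-line predictions (default); `FALSE`
#'   regresses per-year means of the predictions.
#' @return data.frame of class `gain_estimate`: one row per TPE with
#'   `slope_kg_ha_year`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
estimate_gain <- function(blues, A, variances = NULL, per_line = TRUE) {
  stopifnot(all(c("genotype_id", "group_label", "cycle_year", "blue") %in%
                names(blues)))
  blues <- blues[!is.na(blues$blue), , drop = FALSE]
  rows <- lapply(sort(unique(blues$group_label)), function(g) {
    d <- blues[blues$group_label == g, ]
    yrs <- sort(unique(d$cycle_year))
    if (length(yrs) < 3L)
      stop("insufficient-data error: TPE ", g, " has fewer than 3 years")
    miss <- setdiff(unique(d$genotype_id), rownames(A))
    if (length(miss))
      stop("mapping error: line(s) missing from A: ",
           paste(head(miss, 5L), collapse = ", "))
    env <- paste0(g, "_", d$cycle_year)
    fit <- pedigree_blup(d$blue, d$genotype_id, env, A,
                         variances = variances)
    pred <- fit$mu + fit$E[env] + fit$a[d$genotype_id]
    agg <- aggregate(data.frame(blup = pred),
                     by = list(genotype_id = d$genotype_id,
                               year = d$cycle_year), FUN = mean)
    df <- data.frame(year = as.numeric(agg$year), blup = agg$blup)
    if (!per_line)
      df <- aggregate(blup ~ year, data = df, FUN = mean)
    ols <- lm(blup ~ I(year - mean(year)), data = df)
    sm <- summary(ols)
    data.frame(group_label = g,
               slope_kg_ha_year = 1000 * coef(ols)[[2L]],
               se_slope_kg_ha_year = 1000 * sm$coefficients[2L, 2L],
               intercept = coef(ols)[[1L]],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2L, 4L],
               n = nrow(df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gain_estimate", "data.frame")
  out
}

# REML fit of y = mu + Z_E E + Z_a a + e with a ~ N(0, s2_a A);
# small dense solver used by the gain module.
pedigree_blup <- function(y, line, env, A, variances = NULL) {
  lines <- sort(unique(line))
  envs <- sort(unique(env))
  li <- match(line, lines); ei <- match(env, envs)
  n <- length(y)
  Asub <- A[lines, lines]
  K_a <- Asub[li, li]
  K_E <- outer(ei, ei, "==") * 1
  if (is.null(variances)) {
    obj <- function(lpar) {
      s2 <- exp(lpar)
      V <- s2[1L] * K_a + s2[2L] * K_E + diag(s2[3L], n)
      cV <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(cV)) return(1e10)
      X <- matrix(1, n, 1L)
      Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
      Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(Vi_X, y))
      r <- y - X %*% beta
      Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
      as.numeric(2 * sum(log(diag(cV))) + log(XtViX[1L, 1L]) +
                   crossprod(r, Vi_r))
    }
    vy <- var(y)
    opt <- optim(log(c(vy / 3, vy / 3, vy / 3)), obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9))
    s2 <- setNames(exp(opt$par), c("a", "E", "residual"))
  } else {
    s2 <- variances
  }
  V <- s2[["a"]] * K_a + s2[["E"]] * K_E + diag(s2[["residual"]], n)
  Vi <- solve(V)
  ones <- rep(1, n)
  mu <- as.numeric(crossprod(ones, Vi %*% y) / crossprod(ones, Vi %*% ones))
  alpha <- Vi %*% (y - mu)
  # line-level additive BLUP: s2_a * A Z' V^{-1} r
  Z <- matrix(0, n, length(lines)); Z[cbind(seq_len(n), li)] <- 1
  a_hat <- s2[["a"]] * as.numeric(Asub %*% crossprod(Z, alpha))
  ZE <- matrix(0, n, length(envs)); ZE[cbind(seq_len(n), ei)] <- 1
  E_hat <- s2[["E"]] * as.numeric(crossprod(ZE, alpha))
  list(a = setNames(a_hat, lines), E = setNames(E_hat, envs), mu = mu,
       variances = s2)
}
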