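#' Build covariance kernels for the reaction-norm prediction models
#'
#' For records linking lines to environments: `K_a = Z_p A Z_p'` (additive),
#' `K_E = Z_E Z_E'` (environment membership), `K_aE = K_a o K_E`
#' (entrywise product, the reaction-norm structure on GE), `K_w = W W'/q`
#' (environmental-covariate kernel, columns of `W` centered and scaled,
#' divided by the covariate count so its variance parameter is on the
#' variance scale), and `K_aw = K_a o K_w`. Only the kernels the chosen
#' model needs are materialized.
#'
#' @param A Additive relationship matrix (lines).
#' @param records data.frame with columns `line` and `env`.
#' @param W Environment x covariate matrix (rows named by environment);
#'   required for the covariate model.
#' @param model `"AE"`, `"AE-AxE"` or `"AE-AxE-W-AxW"`.
#' @return A `kernel_set`: list of record-level kernels plus the records.
#' @export
build_kernels <- function(A, records, W = NULL,
                          model = c("AE", "AE-AxE", "AE-AxE-W-AxW")) {
  model <- match.arg(model)
  miss <- setdiff(unique(records$line), rownames(A))
  if (length(miss))
    stop("mapping error: line(s) missing from pedigree: ",
         paste(head(miss, 5L), collapse = ", "))
  li <- match(records$line, rownames(A))
  envs <- unique(records$env)
  ei <- match(records$env, envs)
  K_a <- A[li, li, drop = FALSE]
  dimnames(K_a) <- NULL
  K_E <- outer(ei, ei, "==") * 1
  kernels <- list(a = K_a, E = K_E)
  if (model %in% c("AE-AxE", "AE-AxE-W-AxW"))
    kernels$aE <- K_a * K_E
  if (model == "AE-AxE-W-AxW") {
    if (is.null(W)) stop("mapping error: model needs covariate matrix W")
    miss_e <- setdiff(envs, rownames(W))
    if (length(miss_e))
      stop("mapping error: environment(s) missing from W: ",
           paste(head(miss_e, 5L), collapse = ", "))
    Ws <- scale(W[envs, , drop = FALSE])
    Ws <- Ws[, apply(Ws, 2L, function(x) all(is.finite(x))), drop = FALSE]
    Wr <- Ws[ei, , drop = FALSE]
    K_w <- tcrossprod(Wr) / ncol(Wr)
    kernels$W <- K_w
    kernels$aW <- K_a * K_w
  }
  structure(list(kernels = kernels, records = records, model = model),
            class = "kernel_set")
}

# eigendecompose with PSD check and rank truncation
kernel_eigen <- function(K, jitter = 1e-8, label = "kernel") {
  K <- K + diag(jitter, nrow(K))
  eig <- eigen(K, symmetric = TRUE)
  mx <- max(eig$values)
  if (min(eig$values) < -1e-6 * max(mx, 1))
    stop("numerical error: ", label, " is not positive semidefinite ",
         "after jitter (min eigenvalue ", signif(min(eig$values), 3), ")")
  keep <- eig$values > mx * 1e-10
  list(vectors = eig$vectors[, keep, drop = FALSE],
       values = eig$values[keep])
}

rinvchisq <- function(df, scale) df * scale / stats::rchisq(1L, df)

#' Fit a reaction-norm model by Gibbs sampling
#'
#' Bayesian variance-component model `y = mu + sum_k u_k + e` with
#' `u_k ~ N(0, sigma2_k K_k)`; each kernel is eigendecomposed once and its
#' effect sampled in the eigenbasis (independent Gaussian coordinates),
#' with scaled-inverse-chi-squared conjugate updates for the variances.
#' Records with `NA` response are treated as held out: their responses are
#' imputed each sweep (data augmentation) and their posterior-mean linear
#' predictor is reported as the prediction. Priors are scaled inverse
#' chi-squared with `df_prior` degrees of freedom, scale set so each
#' component's prior mode is an equal share of the sample variance of the
#' observed responses.
#'
#' When `fix_variances` is supplied the posterior of the effects is
#' Gaussian with known covariance, so the posterior mean is computed in
#' closed form (no Monte Carlo) — useful for verification against direct
#' mixed-model solves.
#'
#' @param y Response, `NA` for held-out records; optionally centered and
#'   scaled beforehand (set `standardize = TRUE` to have the sampler do
#'   it and report components on the standardized scale).
#' @param kernels A `kernel_set`.
#' @param n_iter,burn_in,thin Chain settings (defaults 12000/2000/5).
#' @param n_chains Number of independent chains (split-Rhat uses >= 2).
#' @param seed RNG seed; chains are seeded deterministically from it.
#' @param df_prior Prior degrees of freedom.
#' @param fix_variances Optional named vector of variances (names matching
#'   the kernels plus `"residual"`); switches to the exact closed form.
#' @param standardize Center and scale `y` before fitting.
#' @param jitter Diagonal jitter added before eigendecomposition.
#' @return A `posterior_summary`: `variances` (posterior mean and sd per
#'   component), `pvt` (percent of total variance), `mu`, `predictions`
#'   (posterior-mean linear predictor for all records), `yhat_test`
#'   (held-out predictions), `diagnostics` (split-Rhat per variance),
#'   `settings`.
#' @export
fit_gibbs <- function(y, kernels, n_iter = 12000L, burn_in = 2000L,
                      thin = 5L, n_chains = 2L, seed = 1L, df_prior = 5,
                      fix_variances = NULL, standardize = FALSE,
                      jitter = 1e-8) {
  stopifnot(inherits(kernels, "kernel_set"))
  K <- kernels$kernels
  n <- length(y)
  if (n != nrow(K[[1L]])) stop("length(y) must match kernel dimension")
  obs <- which(!is.na(y))
  test <- which(is.na(y))
  if (length(obs) < 2L) stop("settings error: too few observed records")
  y_scale <- 1; y_center <- 0
  if (standardize) {
    y_center <- mean(y[obs]); y_scale <- sd(y[obs])
    y <- (y - y_center) / y_scale
  }
  if (!is.null(fix_variances))
    return(fit_fixed_variance(y, K, obs, test, fix_variances,
                              y_center, y_scale))
  n_keep <- floor((n_iter - burn_in) / thin)
  if (n_keep < 100L)
    stop("settings error: fewer than 100 post-burn-in samples ",
         "(n_iter=", n_iter, ", burn_in=", burn_in, ", thin=", thin, ")")
  eigs <- lapply(names(K), function(nm)
    kernel_eigen(K[[nm]], jitter = jitter, label = paste0("K_", nm)))
  names(eigs) <- names(K)
  vy <- max(var(y[obs]), 1e-8)  # floor keeps a constant response finite
  n_comp <- length(K) + 1L
  # prior scales follow the standard Bayesian-GBLUP default: half the
  # sample variance is split equally among the kernel terms (normalized
  # by each kernel's mean diagonal so the split is on the record scale),
  # the other half goes to the residual; df_prior degrees of freedom
  R2 <- 0.5
  S0 <- vapply(K, function(k)
    vy * R2 / (length(K) * mean(diag(k))) * (df_prior + 2) / df_prior,
    numeric(1))
  S0 <- c(S0, residual = vy * (1 - R2) * (df_prior + 2) / df_prior)
  comp_names <- c(names(K), "residual")
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed * 1000L + ch)
    yc <- y
    if (length(test)) yc[test] <- mean(y[obs])
    mu <- mean(yc)
    s2 <- setNames(S0 * df_prior / (df_prior + 2), comp_names)
    u <- lapply(K, function(k) numeric(n))
    delta <- lapply(eigs, function(e) numeric(length(e$values)))
    keep_var <- matrix(NA_real_, n_keep, n_comp,
                       dimnames = list(NULL, comp_names))
    keep_pred <- numeric(n)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      # residual excluding each component in turn
      lin <- mu + Reduce(`+`, u)
      for (knm in names(K)) {
        e_k <- yc - (lin - u[[knm]])
        G <- eigs[[knm]]
        d <- crossprod(G$vectors, e_k)
        pvar <- 1 / (1 / (s2[[knm]] * G$values) + 1 / s2[["residual"]])
        pmean <- pvar * d / s2[["residual"]]
        delta[[knm]] <- as.numeric(pmean + sqrt(pvar) *
                                     rnorm(length(G$values)))
        u_new <- as.numeric(G$vectors %*% delta[[knm]])
        lin <- lin - u[[knm]] + u_new
        u[[knm]] <- u_new
        ssq <- sum(delta[[knm]]^2 / G$values)
        s2[[knm]] <- rinvchisq(df_prior + length(G$values),
                               (df_prior * S0[[knm]] + ssq) /
                                 (df_prior + length(G$values)))
      }
      res <- yc - lin
      s2[["residual"]] <- rinvchisq(df_prior + n,
                                    (df_prior * S0[["residual"]] +
                                       sum(res^2)) / (df_prior + n))
      mu_new <- rnorm(1L, mean(yc - (lin - mu)),
                      sqrt(s2[["residual"]] / n))
      lin <- lin - mu + mu_new
      mu <- mu_new
      if (length(test))
        yc[test] <- lin[test] + rnorm(length(test),
                                      0, sqrt(s2[["residual"]]))
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        keep_var[kept, ] <- s2
        keep_pred <- keep_pred + lin
      }
    }
    chains[[ch]] <- list(var = keep_var, pred = keep_pred / kept)
  }
  all_var <- do.call(rbind, lapply(chains, `[[`, "var"))
  pm <- colMeans(all_var) * y_scale^2
  psd <- apply(all_var, 2L, sd) * y_scale^2
  pred <- Reduce(`+`, lapply(chains, `[[`, "pred")) / n_chains
  pred <- pred * y_scale + y_center
  rhat <- split_rhat(lapply(chains, `[[`, "var"))
  out <- list(variances = data.frame(component = comp_names, mean = pm,
                                     sd = psd, row.names = NULL),
              mu = mean(pred) , predictions = pred,
              yhat_test = if (length(test)) pred[test] else numeric(0),
              test_idx = test,
              diagnostics = rhat,
              settings = list(n_iter = n_iter, burn_in = burn_in,
                              thin = thin, n_chains = n_chains,
                              seed = seed, df_prior = df_prior,
                              standardize = standardize),
              model = kernels$model)
  out$pvt <- pvt(out)
  class(out) <- "posterior_summary"
  out
}

# exact posterior mean of the linear predictor when variances are fixed
fit_fixed_variance <- function(y, K, obs, test, s2, y_center, y_scale) {
  comp_names <- names(K)
  if (!all(c(comp_names, "residual") %in% names(s2)))
    stop("fix_variances must name every kernel plus 'residual'")
  n <- length(y)
  V <- diag(s2[["residual"]], length(obs))
  for (nm in comp_names) V <- V + s2[[nm]] * K[[nm]][obs, obs]
  ones <- rep(1, length(obs))
  Vi <- solve(V)
  mu <- as.numeric(crossprod(ones, Vi %*% y[obs]) /
                   crossprod(ones, Vi %*% ones))
  r <- y[obs] - mu
  alpha <- Vi %*% r
  pred <- rep(mu, n)
  for (nm in comp_names)
    pred <- pred + s2[[nm]] * as.numeric(K[[nm]][, obs] %*% alpha)
  pred <- pred * y_scale + y_center
  vars <- data.frame(component = c(comp_names, "residual"),
                     mean = unname(s2[c(comp_names, "residual")]) *
                       y_scale^2,
                     sd = 0, row.names = NULL)
  out <- list(variances = vars, mu = mu * y_scale + y_center,
              predictions = pred,
              yhat_test = if (length(test)) pred[test] else numeric(0),
              test_idx = test, diagnostics = NULL,
              settings = list(fixed = TRUE), model = NULL)
  out$pvt <- pvt(out)
  class(out) <- "posterior_summary"
  out
}

# split-Rhat over chains for each variance component
split_rhat <- function(var_chains) {
  halves <- list()
  for (m in var_chains) {
    h <- nrow(m) %/% 2L
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1L):(2L * h), , drop = FALSE]))
  }
  sapply(colnames(var_chains[[1L]]), function(cn) {
    draws <- sapply(halves, function(m) m[, cn])
    mns <- colMeans(draws); vrs <- apply(draws, 2L, var)
    nn <- nrow(draws); mm <- ncol(draws)
    B <- nn * var(mns); Wv <- mean(vrs)
    if (!is.finite(Wv) || Wv == 0) return(1)
    sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
  })
}

#' Proportion of variance relative to the total
#'
#' Each component's posterior-mean variance divided by the sum over all of
#' the model's components (residual included), in percent.
#'
#' @param summary A `posterior_summary`, or a named numeric vector of
#'   variance components.
#' @return Named percentages summing to 100.
#' @export
pvt <- function(summary) {
  v <- if (inherits(summary, "posterior_summary") || is.list(summary))
    setNames(summary$variances$mean, summary$variances$component)
  else summary
  if (any(v < 0)) stop("components must be >= 0")
  tot <- sum(v)
  if (tot == 0) stop("undefined: all components are zero")
  100 * v / tot
}

#' Predictive correlation between held-out observations and predictions
#'
#' @param summary A `posterior_summary` with held-out predictions.
#' @param observed Observed values for the held-out records (same order
#'   as `summary$yhat_test`).
#' @param groups Optional grouping factor (e.g. TPE) of the held-out
#'   records; one correlation per group is returned.
#' @return Pearson correlation(s); `NA` with a warning for groups with
#'   fewer than 3 records or zero-variance predictions.
#' @export
predictive_correlation <- function(summary, observed, groups = NULL) {
  pred <- summary$yhat_test
  stopifnot(length(pred) == length(observed))
  one <- function(p, o) {
    ok <- is.finite(p) & is.finite(o)
    p <- p[ok]; o <- o[ok]
    if (length(p) < 3L) {
      warning("fewer than 3 held-out records"); return(NA_real_)
    }
    if (sd(p) == 0 || sd(o) == 0) {
      warning("zero variance in predictions or observations")
      return(NA_real_)
    }
    cor(p, o)
  }
  if (is.null(groups)) return(one(pred, observed))
  vapply(split(seq_along(pred), groups),
         function(ix) one(pred[ix], observed[ix]), numeric(1))
}
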