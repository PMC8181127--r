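make_daily <- function(values_by_day, site = "s1", year = 2015L,
                       variable = "avg_temp", start = "2015-11-23") {
  data.frame(site_id = site, year = year, variable = variable,
             date = as.Date(start) + seq_along(values_by_day) - 1L,
             value = values_by_day, stringsAsFactors = FALSE)
}

test_that("window_aggregate computes window means and column layout", {
  # constant series -> all six window means equal the constant
  d <- make_daily(rep(5, 120))
  m <- window_aggregate(d)
  expect_equal(unname(m["s1", paste0("avg_temp_w", 1:6)]), rep(5, 6))

  # arithmetic oracle: days 1..20 in window 1 -> mean 10.5
  d2 <- make_daily(c(1:20, rep(0, 100)))
  m2 <- window_aggregate(d2)
  expect_equal(unname(m2["s1", "avg_temp_w1"]), 10.5)
  expect_equal(unname(m2["s1", "avg_temp_w2"]), 0)

  # 9 MVs x 6 windows + 9 SVs = 63 columns
  mv <- do.call(rbind, lapply(sprintf("mv%d", 1:9), function(v)
    make_daily(rnorm(120), variable = v)))
  soil <- data.frame(site_id = "s1", variable = sprintf("sv%d", 1:9),
                     value = rnorm(9))
  m3 <- window_aggregate(mv, soil = soil)
  expect_equal(ncol(m3), 63L)

  # multi-year data: window means averaged over years
  d3 <- rbind(make_daily(rep(2, 120)),
              make_daily(rep(4, 120), year = 2016L, start = "2016-11-23"))
  m4 <- window_aggregate(d3)
  expect_equal(unname(m4["s1", "avg_temp_w1"]), 3)

  # insufficient coverage
  expect_error(window_aggregate(make_daily(rep(1, 60))), "coverage error")
})

test_that("pca_correlation matches closed forms", {
  # two variables with correlation r -> eigenvalues 1 + r, 1 - r
  set.seed(1)
  x1 <- rnorm(40)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(40)
  X <- cbind(a = x1, b = x2)
  r <- cor(x1, x2)
  p <- pca_correlation(X)
  expect_equal(sort(p$variance_explained * 2, decreasing = TRUE),
               c(1 + r, 1 - r), tolerance = 1e-12)
  expect_equal(sum(p$variance_explained), 1)

  # single informative variable, others constant -> PC1 explains 100%
  X2 <- cbind(info = rnorm(10), flat = rep(1, 10), flat2 = rep(2, 10))
  expect_warning(p2 <- pca_correlation(X2), "zero-variance")
  expect_equal(p2$variance_explained[1L], 1)

  # scores have diagonal covariance
  set.seed(2)
  X3 <- matrix(rnorm(60), 20, 3)
  p3 <- pca_correlation(X3)
  cv <- cov(p3$scores)
  expect_equal(cv[upper.tri(cv)], rep(0, 3), tolerance = 1e-10)

  expect_error(pca_correlation(X3[1, , drop = FALSE]), "input error")
})

test_that("hcluster_tpe cuts, orders and degenerates correctly", {
  set.seed(3)
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 5, 0.1), 5, 2))
  colnames(X) <- c("avg_temp_w1", "prec_w1")
  rownames(X) <- paste0("s", 1:10)
  asg <- hcluster_tpe(X, k = 2)
  # label 1 must be the cooler block (rows 1..5)
  expect_equal(unname(asg$assignment), rep(c(1L, 2L), each = 5L))

  # k = n -> singletons
  asg_n <- hcluster_tpe(X, k = 10, order_by = NULL)
  expect_equal(length(unique(asg_n$assignment)), 10L)

  # duplicate rows land in the same cluster
  X2 <- rbind(X, s11 = X["s1", ])
  asg_d <- hcluster_tpe(X2, k = 2)
  expect_equal(asg_d$assignment[["s11"]], asg_d$assignment[["s1"]])

  expect_error(hcluster_tpe(X, k = 11), "input error")

  # invariance to column permutation
  asg_p <- hcluster_tpe(X[, c(2, 1)], k = 2)
  expect_equal(asg_p$assignment, asg$assignment)
})

test_that("clustering recovers planted TPE structure from the generator", {
  spec <- sim_spec(sites_per_tpe = c(5L, 4L, 5L), n_cov_years = 1L,
                   seed = 12L)
  cov <- simulate_covariates(spec)
  expect_equal(ncol(cov$covariates), 63L)
  asg <- hcluster_tpe(cov$covariates, k = 3)
  ari <- adjusted_rand_index(asg$assignment[names(cov$tpe_labels)],
                             cov$tpe_labels)
  expect_equal(ari, 1)
})

test_that("site_proportions sums to 100 and reproduces the published split", {
  sites <- load_reference_table("sites")
  props <- site_proportions(setNames(sites$tpe, sites$site_id))
  expect_equal(round(unname(props), 1), c(36.6, 19.5, 43.9))
  expect_equal(sum(props), 100)
  expect_equal(unname(site_proportions(rep(1, 7))), 100)
  expect_equal(unname(site_proportions(c(1, 2))), c(50, 50))
  expect_error(site_proportions(integer(0)), "empty")
})

test_that("thin-plate spline interpolates, smooths and matches a direct solve", {
  set.seed(4)
  x <- cbind(runif(10), runif(10))
  # affine data -> zero residuals for any lambda
  y_aff <- 2 + 3 * x[, 1] - x[, 2]
  for (lam in c(0, 1, 100)) {
    fit <- tps_fit(y_aff, x, lambda = lam)
    expect_equal(tps_predict(fit, x), y_aff, tolerance = 1e-8)
  }
  # lambda = 0 interpolates scattered data
  y <- rnorm(10)
  fit0 <- tps_fit(y, x, lambda = 0)
  expect_equal(tps_predict(fit0, x), y, tolerance = 1e-6)

  # lambda = 1 matches an independently built augmented linear system
  lam <- 1
  eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  E <- eta(as.matrix(dist(x)))
  T_ <- cbind(1, x)
  M <- rbind(cbind(E + diag(lam, 10), T_), cbind(t(T_), matrix(0, 3, 3)))
  sol <- solve(M, c(y, 0, 0, 0))
  fit1 <- tps_fit(y, x, lambda = lam)
  expect_equal(fit1$c, unname(sol[1:10]), tolerance = 1e-10)
  expect_equal(fit1$d, unname(sol[11:13]), tolerance = 1e-10)

  # lambda -> Inf tends to the affine least-squares fit
  fit_inf <- tps_fit(y, x, lambda = 1e8)
  ls <- lm(y ~ x)
  expect_equal(tps_predict(fit_inf, x), unname(fitted(ls)),
               tolerance = 1e-4)

  # collinear coordinates are rejected
  xc <- cbind(1:5, 2 * (1:5))
  expect_error(tps_fit(rnorm(5), xc, lambda = 0), "rank error")
})

test_that("adjusted_rand_index behaves at the extremes", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(5)
  a <- rep(1:4, each = 25)
  b <- sample(a)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.2)
})
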