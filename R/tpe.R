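#' Aggregate daily meteorological series into fixed-length windows
#'
#' Each meteorological variable is averaged over consecutive windows
#' (default six windows of 20 days) starting from a fixed calendar date
#' (default November 23, the median planting date of the network); sites
#' with several years of data are averaged over years after windowing.
#' Static soil variables are appended unchanged.
#'
#' @param daily data.frame with columns `site_id`, `year`, `variable`,
#'   `date` (Date or "YYYY-MM-DD"), `value`.
#' @param soil Optional data.frame with columns `site_id`, `variable`,
#'   `value` of static soil covariates.
#' @param start_mmdd Window start as "MM-DD" within each `year`.
#' @param window_days Days per window.
#' @param n_windows Number of windows.
#' @return Site x covariate matrix; windowed columns are named
#'   `<variable>_w<window>`, soil columns keep their names.
#' @export
window_aggregate <- function(daily, soil = NULL, start_mmdd = "11-23",
                             window_days = 20L, n_windows = 6L) {
  daily$date <- as.Date(daily$date)
  span <- window_days * n_windows
  key <- paste(daily$site_id, daily$year, daily$variable, sep = "\r")
  pieces <- split(daily, key)
  rows <- lapply(pieces, function(d) {
    start <- as.Date(paste0(d$year[1L], "-", start_mmdd))
    offs <- as.integer(d$date - start)
    keep <- offs >= 0L & offs < span
    d <- d[keep, ]
    offs <- offs[keep]
    if (length(unique(offs)) < span)
      stop("coverage error: site ", d$site_id[1L], " year ", d$year[1L],
           " variable ", d$variable[1L], " does not cover ", span,
           " days from ", start)
    win <- offs %/% window_days + 1L
    means <- tapply(d$value, win, mean)
    data.frame(site_id = d$site_id[1L], variable = d$variable[1L],
               window = as.integer(names(means)), value = as.numeric(means))
  })
  long <- do.call(rbind, rows)
  # average over years happens implicitly: rows above are per site-year;
  # collapse to per-site means per (variable, window)
  agg <- aggregate(value ~ site_id + variable + window, data = long,
                   FUN = mean)
  agg$col <- paste0(agg$variable, "_w", agg$window)
  sites <- sort(unique(agg$site_id))
  vars <- unique(daily$variable)
  cols <- as.vector(t(outer(vars, seq_len(n_windows),
                            function(v, w) paste0(v, "_w", w))))
  m <- matrix(NA_real_, length(sites), length(cols),
              dimnames = list(sites, cols))
  m[cbind(match(agg$site_id, sites), match(agg$col, cols))] <- agg$value
  if (!is.null(soil)) {
    svars <- unique(soil$variable)
    sm <- matrix(NA_real_, length(sites), length(svars),
                 dimnames = list(sites, svars))
    sagg <- aggregate(value ~ site_id + variable, data = soil, FUN = mean)
    sm[cbind(match(sagg$site_id, sites), match(sagg$variable, svars))] <-
      sagg$value
    m <- cbind(m, sm)
  }
  if (anyNA(m)) stop("coverage error: missing covariate cells after ",
                     "aggregation")
  m
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the site covariates;
#' zero-variance columns are dropped with a warning (they carry no
#' between-site information).
#'
#' @param X Site x covariate matrix with at least 2 rows.
#' @return List with `scores` (sites x components), `loadings`
#'   (eigenvectors), `variance_explained` (fractions summing to 1) and
#'   `dropped` (names of constant columns).
#' @export
pca_correlation <- function(X) {
  if (nrow(X) < 2L) stop("input error: PCA needs at least 2 sites")
  sds <- apply(X, 2L, sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  Z <- scale(X)
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  list(scores = Z %*% eig$vectors,
       loadings = eig$vectors,
       variance_explained = ev / sum(ev),
       dropped = dropped)
}

#' Hierarchically cluster sites into TPEs
#'
#' Covariates are centered and scaled to unit variance, sites are clustered
#' on Euclidean distance with Ward linkage, and the tree is cut at `k`
#' clusters. Cluster labels are relabelled so cluster 1 has the lowest mean
#' of the average-temperature covariates (cool to warm), a reproducible
#' naming convention.
#'
#' @param X Site x covariate matrix.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param linkage `hclust` method; Ward ("ward.D2") by default, single and
#'   average linkage are accepted alternatives.
#' @param order_by Prefix of the covariate used for label ordering;
#'   set `NULL` to keep the cut order.
#' @return A `tpe_assignment` list: `assignment` (named integer vector),
#'   `tree` (hclust), `variance_explained` (PCA fractions).
#' @export
hcluster_tpe <- function(X, k = 3L, linkage = c("ward.D2", "single",
                                                "average"),
                         order_by = "avg_temp") {
  linkage <- match.arg(linkage)
  if (k < 1L || k > nrow(X))
    stop("input error: k must be in [1, n_sites]")
  sds <- apply(X, 2L, sd)
  keep <- sds > 0 & !is.na(sds)
  Z <- scale(X[, keep, drop = FALSE])
  tree <- hclust(dist(Z), method = linkage)
  raw <- cutree(tree, k = k)
  labels <- raw
  if (!is.null(order_by)) {
    cols <- grep(paste0("^", order_by), colnames(X), value = TRUE)
    if (length(cols)) {
      key <- rowMeans(X[, cols, drop = FALSE])
      cl_means <- tapply(key, raw, mean)
      remap <- setNames(rank(cl_means, ties.method = "first"),
                        names(cl_means))
      labels <- as.integer(remap[as.character(raw)])
      names(labels) <- names(raw)
    }
  }
  pca <- pca_correlation(X)
  structure(list(assignment = labels, tree = tree,
                 variance_explained = pca$variance_explained),
            class = "tpe_assignment")
}

#' Percentage of sites per cluster
#'
#' @param assignment A `tpe_assignment` or a vector of cluster labels.
#' @return Named numeric vector of percentages summing to 100.
#' @export
site_proportions <- function(assignment) {
  labels <- if (inherits(assignment, "tpe_assignment"))
    assignment$assignment else assignment
  if (!length(labels)) stop("input error: empty assignment")
  tab <- table(labels)
  setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return Adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# thin-plate radial basis for d = 2, m = 2
tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit a thin-plate spline surface
#'
#' Minimizes `||y - g||^2 + lambda * J(g)` where J is the order-2
#' thin-plate penalty in d = 2 dimensions; the radial basis is
#' `r^2 log(r)`. `lambda = 0` interpolates the data; `lambda -> Inf` tends
#' to the unpenalized affine least-squares fit (affine functions span the
#' null space of J). When `lambda` is `NULL` it is chosen by generalized
#' cross-validation on a log grid.
#'
#' @param y Response at the knots.
#' @param x Two-column coordinate matrix (e.g. longitude, latitude).
#' @param lambda Smoothing parameter `>= 0`, or `NULL` for GCV.
#' @return A `tps_model` with knots, coefficients and lambda.
#' @export
tps_fit <- function(y, x, lambda = 0) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("tps_fit expects 2-column coordinates")
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (n < 3L) stop("rank error: need at least 3 points")
  if (qr(cbind(1, x))$rank < 3L)
    stop("rank error: collinear coordinates, affine part not estimable")
  E <- tps_eta(as.matrix(dist(x)))
  T_ <- cbind(1, x)
  # null-space algorithm: write c = Q2 z with T' c = 0 enforced by the QR
  # of T, solve the reduced positive-definite system, then recover the
  # affine part; numerically stable down to lambda = 0
  qrT <- qr(T_)
  Q <- qr.Q(qrT, complete = TRUE)
  Q1 <- Q[, 1:3, drop = FALSE]
  Q2 <- Q[, 4:n, drop = FALSE]
  R1 <- qr.R(qrT)
  solve_tps <- function(lam) {
    M <- crossprod(Q2, (E + diag(lam, n)) %*% Q2)
    z <- solve(M, crossprod(Q2, y))
    cc <- as.numeric(Q2 %*% z)
    d <- backsolve(R1, crossprod(Q1, y - (E + diag(lam, n)) %*% cc))
    list(c = cc, d = as.numeric(d))
  }
  if (is.null(lambda)) {
    grid <- 10^seq(-8, 3, by = 0.5)
    gcv <- vapply(grid, function(lam) {
      # influence matrix trace via column-by-column solve (n is small)
      M <- rbind(cbind(E + diag(lam, n), T_),
                 cbind(t(T_), matrix(0, 3L, 3L)))
      Minv <- solve(M)
      Hy <- cbind(E, T_) %*% Minv[, 1:n]
      fits <- Hy %*% y
      trH <- sum(diag(Hy))
      denom <- max(n - trH, 1e-8)
      n * sum((y - fits)^2) / denom^2
    }, numeric(1))
    lambda <- grid[which.min(gcv)]
  }
  if (lambda < 0) stop("lambda must be >= 0")
  sol <- solve_tps(lambda)
  structure(list(knots = x, c = sol$c, d = sol$d, lambda = lambda,
                 m = 2L, dim = 2L), class = "tps_model")
}

#' Evaluate a fitted thin-plate spline
#'
#' @param model A `tps_model`.
#' @param xstar Two-column matrix of prediction coordinates.
#' @return Predicted surface values.
#' @export
tps_predict <- function(model, xstar) {
  xstar <- matrix(as.numeric(xstar), ncol = 2L)
  K <- outer(seq_len(nrow(xstar)), seq_len(nrow(model$knots)),
             function(i, j) {
               tps_eta(sqrt(rowSums((xstar[i, , drop = FALSE] -
                                     model$knots[j, , drop = FALSE])^2)))
             })
  as.numeric(K %*% model$c + cbind(1, xstar) %*% model$d)
}
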