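#' Phenotypic correlation between two groups' genotype BLUEs
#'
#' Pearson correlation over the genotypes shared by the two groups,
#' pairwise-complete. Needs at least 3 shared genotypes with data in both
#' groups; otherwise (or when one group's BLUEs are constant) the
#' correlation is undefined and `NA` is returned with a warning.
#'
#' @param blues_i,blues_j `blue_table`s (or data.frames with
#'   `genotype_id`, `blue`).
#' @return Pearson correlation, or `NA`.
#' @export
phenotypic_correlation <- function(blues_i, blues_j) {
  m <- merge(blues_i[, c("genotype_id", "blue")],
             blues_j[, c("genotype_id", "blue")],
             by = "genotype_id", suffixes = c("_i", "_j"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3L) {
    warning("fewer than 3 shared genotypes; correlation undefined")
    return(NA_real_)
  }
  if (sd(m$blue_i) == 0 || sd(m$blue_j) == 0) {
    warning("zero variance in one group's BLUEs; correlation undefined")
    return(NA_real_)
  }
  cor(m$blue_i, m$blue_j)
}

#' Genetic correlation from a phenotypic correlation and heritabilities
#'
#' `r_ij = p_ij / sqrt(h2_i * h2_j)`. The raw value can exceed 1 in
#' magnitude when estimated heritabilities are small; both the raw value
#' (used downstream in the correlated-response formula) and a copy clamped
#' to [-1, 1] are returned.
#'
#' @param p_ij Phenotypic correlation.
#' @param h2_i,h2_j Heritabilities in (0, 1].
#' @return List with `raw` and `clamped`; both `NA` if either heritability
#'   is zero or missing.
#' @export
genetic_correlation <- function(p_ij, h2_i, h2_j) {
  if (is.na(p_ij) || is.na(h2_i) || is.na(h2_j) ||
      h2_i <= 0 || h2_j <= 0)
    return(list(raw = NA_real_, clamped = NA_real_))
  raw <- p_ij / sqrt(h2_i * h2_j)
  list(raw = raw, clamped = max(-1, min(1, raw)))
}

#' Correlated response to indirect selection
#'
#' Relative efficiency of selecting in the selection environments for a
#' target population of environments:
#' `CR = r_bar * sqrt(H2_SE / H2_TPE)`, with `r_bar` the mean genetic
#' correlation over years of testing.
#'
#' @param r_bar Average genetic correlation (raw, not clamped).
#' @param h2_se Broad-sense heritability across selection environments.
#' @param h2_tpe Broad-sense heritability across the TPE's sites (> 0).
#' @return CR, or `NA` when `h2_tpe` is 0 or missing.
#' @export
correlated_response <- function(r_bar, h2_se, h2_tpe) {
  if (is.na(r_bar) || is.na(h2_se) || is.na(h2_tpe) || h2_tpe <= 0)
    return(NA_real_)
  r_bar * sqrt(h2_se / h2_tpe)
}

#' Direct response to selection
#'
#' `DR = i * V_g_total / sqrt(V_z)`: total genotypic variance (including
#' genotype-by-TPE variance in across-TPE analyses) divided by the square
#' root of phenotypic variance, at selection intensity `i` (default 1,
#' i.e. disregarding selection intensity). Units follow the response
#' (t/ha here).
#'
#' @param v_g_total Total genotypic variance.
#' @param v_z Phenotypic variance (> 0).
#' @param i Selection intensity.
#' @return DR, or `NA` when `v_z <= 0`.
#' @export
direct_response <- function(v_g_total, v_z, i = 1) {
  if (is.na(v_g_total) || is.na(v_z) || v_z <= 0) return(NA_real_)
  i * v_g_total / sqrt(v_z)
}

#' Assemble a per-year selection-response table
#'
#' For each year and target group, combines the phenotypic correlation of
#' the group's BLUEs with the across-SE BLUEs, the genetic correlation,
#' the correlated response (using mean genetic correlation over years and
#' mean heritabilities, matching how multi-year summaries are usually
#' reported), and the direct response from the group's variance
#' components.
#'
#' @param blues_tpe Long BLUE table for TPE-year groups (from
#'   [met_blues()] with `kind = "TPE"`).
#' @param blues_se Long BLUE table for across-SE per-year groups (from
#'   [met_blues()] with `kind = "SE"`).
#' @param h2_tpe Named numeric: per-group-year `"<group>_<year>"`
#'   heritabilities for the TPE side.
#' @param h2_se Named numeric: per-year heritabilities across SEs (names =
#'   years).
#' @param v_g_total,v_z Optional named numerics (same names as `h2_tpe`)
#'   for the DR column.
#' @return data.frame of class `response_table`: one row per (group,
#'   year) with `p`, `r_raw`, `r_clamped`, and per-group `cr` computed
#'   from means over available years, plus `dr` when variances are given.
#' @export
response_table <- function(blues_tpe, blues_se, h2_tpe, h2_se,
                           v_g_total = NULL, v_z = NULL) {
  groups <- unique(blues_tpe$group_label)
  years <- sort(unique(blues_tpe$cycle_year))
  rows <- list()
  for (g in groups) for (yr in years) {
    bi <- blues_tpe[blues_tpe$group_label == g & blues_tpe$cycle_year == yr, ]
    bj <- blues_se[blues_se$cycle_year == yr, ]
    if (!nrow(bi) || !nrow(bj)) next
    key <- paste0(g, "_", yr)
    p <- suppressWarnings(phenotypic_correlation(bi, bj))
    h2i <- h2_tpe[[key]]
    h2j <- h2_se[[as.character(yr)]]
    r <- genetic_correlation(p, h2i, h2j)
    dr <- if (!is.null(v_g_total) && !is.null(v_z))
      direct_response(v_g_total[[key]], v_z[[key]]) else NA_real_
    rows[[key]] <- data.frame(group_label = g, cycle_year = yr, p = p,
                              r_raw = r$raw, r_clamped = r$clamped,
                              h2_tpe = if (is.null(h2i)) NA_real_ else h2i,
                              h2_se = if (is.null(h2j)) NA_real_ else h2j,
                              dr = dr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # per-group CR from means over available years
  out$cr <- NA_real_
  for (g in groups) {
    sel <- out$group_label == g
    r_bar <- mean(out$r_raw[sel], na.rm = TRUE)
    h2t <- mean(out$h2_tpe[sel], na.rm = TRUE)
    h2s <- mean(out$h2_se[sel], na.rm = TRUE)
    out$cr[sel] <- correlated_response(r_bar, h2s, h2t)
  }
  class(out) <- c("response_table", "data.frame")
  out
}
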