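#' @importFrom stats aggregate as.dist coef complete.cases cor cov cutree
#'   dist hclust lm optim pnorm pt qt rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

TRIAL_COLUMNS <- c("cycle_year", "site_id", "group_label", "group_kind",
                   "replicate", "sub_block", "genotype_id", "is_local_check",
                   "grain_yield")

SE_LABELS <- c("B5IR", "F5IR", "B2IR", "FDRT", "BLHT")

#' Read a long-format trial table
#'
#' Reads delimited phenotype records for a multi-environment trial network.
#' Each row is one plot: a genotype grown in one replicate and sub-block of
#' one site-year trial, with the site assigned either to a target population
#' of environments (TPE) or to a managed selection environment (SE).
#'
#' @param path Path to a delimited text file with a header naming at least
#'   the columns `cycle_year`, `site_id`, `group_label`, `group_kind`,
#'   `replicate`, `sub_block`, `genotype_id`, `is_local_check`,
#'   `grain_yield`.
#' @param delim Field delimiter, default comma.
#' @return A `trial_table`: a data.frame with typed columns. Missing yields
#'   are kept as `NA`, never dropped or imputed.
#' @export
read_trials <- function(path, delim = ",") {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  as_trial_table(df)
}

#' Coerce a data.frame to a validated trial table
#'
#' @param df data.frame carrying the trial-table columns.
#' @return A `trial_table`.
#' @export
as_trial_table <- function(df) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$cycle_year <- as.integer(df$cycle_year)
  df$site_id <- as.character(df$site_id)
  df$group_label <- as.character(df$group_label)
  df$group_kind <- as.character(df$group_kind)
  if (nrow(df) && !all(df$group_kind %in% c("TPE", "SE")))
    stop("schema error: group_kind must be 'TPE' or 'SE'")
  df$replicate <- as.integer(df$replicate)
  df$sub_block <- as.integer(df$sub_block)
  df$genotype_id <- as.character(df$genotype_id)
  df$is_local_check <- as.logical(df$is_local_check)
  df$grain_yield <- as.numeric(df$grain_yield)
  if (nrow(df)) {
    if (any(df$replicate < 1L) || any(df$sub_block < 1L))
      stop("schema error: replicate and sub_block must be >= 1")
    # a "trial" is a site-year combination, split further by group label
    # when several managed environments share one station
    key <- paste(df$site_id, df$group_label, df$cycle_year, df$replicate,
                 df$sub_block, df$genotype_id, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      offenders <- unique(key[dup])
      stop("integrity error: duplicate (site, year, rep, sub_block, genotype) ",
           "records: ", paste(gsub("\r", "/", head(offenders, 5L)),
                              collapse = "; "))
    }
    neg <- !is.na(df$grain_yield) & df$grain_yield < 0
    if (any(neg)) stop("schema error: negative grain_yield in ",
                       sum(neg), " record(s)")
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a three-column pedigree file
#'
#' @param path CSV with columns `id`, `parent1`, `parent2`; `"0"`, empty or
#'   `NA` denote an unknown parent.
#' @param delim Field delimiter.
#' @return A `pedigree_table` data.frame with `NA` for unknown parents.
#' @export
read_pedigree <- function(path, delim = ",") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 na.strings = c("", "NA", "0"))
  need <- c("id", "parent1", "parent2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  as_pedigree_table(df[, need])
}

#' @rdname read_pedigree
#' @param df data.frame with columns id, parent1, parent2.
#' @export
as_pedigree_table <- function(df) {
  df$id <- as.character(df$id)
  df$parent1 <- as.character(df$parent1)
  df$parent2 <- as.character(df$parent2)
  df$parent1[df$parent1 %in% c("0", "")] <- NA_character_
  df$parent2[df$parent2 %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id))
    stop("integrity error: duplicate pedigree ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  class(df) <- c("pedigree_table", "data.frame")
  df
}

#' Read long-format environmental covariates
#'
#' Long format: one row per (site, variable, window); `window` 0 flags a
#' static soil variable, windows 1..n are 20-day means of a meteorological
#' variable.
#'
#' @param path CSV with columns `site_id`, `variable`, `window`, `value`.
#' @param delim Field delimiter.
#' @return data.frame of class `covariate_long`.
#' @export
read_covariates <- function(path, delim = ",") {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("site_id", "variable", "window", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  df$variable <- as.character(df$variable)
  df$window <- as.integer(df$window)
  df$value <- as.numeric(df$value)
  class(df) <- c("covariate_long", "data.frame")
  df
}

#' Convert long-format covariates to the site x covariate matrix
#'
#' Column names are `variable_w<window>` for windowed meteorological
#' variables and the bare variable name for static soil variables.
#'
#' @param long A `covariate_long` data.frame.
#' @return Numeric matrix, rows named by site.
#' @export
covariates_to_matrix <- function(long) {
  colkey <- ifelse(long$window == 0L, long$variable,
                   paste0(long$variable, "_w", long$window))
  sites <- unique(long$site_id)
  cols <- unique(colkey)
  m <- matrix(NA_real_, length(sites), length(cols),
              dimnames = list(sites, cols))
  m[cbind(match(long$site_id, sites), match(colkey, cols))] <- long$value
  if (anyNA(m)) stop("coverage error: missing covariate cells after pivot")
  m
}

#' Write a pipeline result to delimited text
#'
#' Tables (data.frames, matrices) go to CSV with full floating-point
#' precision so that read-back reproduces the numbers bit-exactly; nested
#' results (variance components, posterior summaries, gain estimates) go to
#' JSON.
#'
#' @param object A pipeline result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  if (is.matrix(object)) {
    df <- as.data.frame(object)
    df <- cbind(row_id = rownames(object), df)
    write_table_exact(df, path)
  } else if (is.data.frame(object)) {
    write_table_exact(object, path)
  } else if (inherits(object, "variance_components") ||
             inherits(object, "posterior_summary") ||
             inherits(object, "gain_estimate") || is.list(object)) {
    jsonlite::write_json(unclass_deep(object), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null", pretty = TRUE)
  } else {
    stop("write_results: unsupported object of class ",
         paste(class(object), collapse = "/"))
  }
  invisible(path)
}

# CSV writer preserving doubles exactly (17 significant digits round-trips
# IEEE754); logicals as TRUE/FALSE, everything else as-is.
write_table_exact <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) {
      out <- formatC(col, digits = 17, format = "g")
      out[is.na(col)] <- ""
      trimws(out)
    } else if (is.logical(col)) {
      ifelse(is.na(col), "", ifelse(col, "TRUE", "FALSE"))
    } else {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L,
                                      dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.matrix(x)) {
    apply(x, 1L, identity, simplify = FALSE)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # keep names in JSON objects
  } else x
}

#' Load one of the bundled published ESWYT summary tables
#'
#' The package ships, as plain CSV, published summary statistics of the
#' ESWYT India trial network: site list with TPE labels, TPE-level covariate
#' means, per-year variance-component summaries across TPE sites and across
#' selection environments, and the per-TPE response summaries. These serve
#' as worked-example inputs and as generator defaults.
#'
#' @param name One of `"sites"`, `"covariate_means"`, `"tpe_variance"`,
#'   `"se_variance"`, `"tpe_response"`.
#' @return data.frame.
#' @export
load_reference_table <- function(name = c("sites", "covariate_means",
                                          "tpe_variance", "se_variance",
                                          "tpe_response")) {
  name <- match.arg(name)
  file <- switch(name,
    sites = "eswyt_india_sites.csv",
    covariate_means = "eswyt_tpe_covariate_means.csv",
    tpe_variance = "eswyt_tpe_variance_summary.csv",
    se_variance = "eswyt_se_variance_summary.csv",
    tpe_response = "eswyt_tpe_response_summary.csv")
  path <- system.file("extdata", file, package = "tpemet")
  if (!nzchar(path)) stop("reference table not found: ", file)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build a run configuration
#'
#' Records every knob of a pipeline run, including the seed, so runs are
#' reproducible; a short digest of the configuration is embedded in output
#' files.
#'
#' @param seed Integer RNG seed (always recorded).
#' @param ... Named options (paths, model choices, windowing, clustering k).
#' @return A `run_config` list with a `digest` field.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), ...)
  cfg$digest <- config_digest(cfg)
  class(cfg) <- "run_config"
  cfg
}

# FNV-1a over the deparsed config; dependency-free stand-in for a crypto
# digest, adequate for tagging outputs.
config_digest <- function(cfg) {
  cfg$digest <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
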