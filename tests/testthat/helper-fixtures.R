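# fixture builders shared across test files

# balanced trial table: sites x reps x genotypes, optional effects
make_trials <- function(n_sites = 3L, n_reps = 2L, n_geno = 5L,
                        n_sub = 1L, year = 2010L, kind = "TPE",
                        group = "1", mu = 5, geno_shift = NULL,
                        noise_sd = 0, seed = 42L) {
  set.seed(seed)
  sites <- sprintf("S%02d", seq_len(n_sites))
  genos <- sprintf("G%02d", seq_len(n_geno))
  if (is.null(geno_shift)) geno_shift <- setNames(rep(0, n_geno), genos)
  grid <- expand.grid(site_id = sites, replicate = seq_len(n_reps),
                      genotype_id = genos, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sub_block <- ((match(grid$genotype_id, genos) - 1L) %%
                       n_sub) + 1L
  grid$cycle_year <- year
  grid$group_label <- group
  grid$group_kind <- kind
  grid$is_local_check <- FALSE
  grid$grain_yield <- mu + geno_shift[grid$genotype_id] +
    rnorm(nrow(grid), 0, noise_sd)
  as_trial_table(grid)
}

# six-individual pedigree used in the kinship tests:
# founders A,B; full sibs C,D; E = C x D; F = selfing of E
six_pedigree <- function() {
  as_pedigree_table(data.frame(
    id = c("A", "B", "C", "D", "E", "F"),
    parent1 = c(NA, NA, "A", "A", "C", "E"),
    parent2 = c(NA, NA, "B", "B", "D", "E"),
    stringsAsFactors = FALSE))
}

small_sim_spec <- function(seed = 1L, ...) {
  sim_spec(n_cycles = 2L, lines_per_cycle = 19L,
           sites_per_tpe = c(3L, 2L, 3L), sub_blocks = 4L,
           n_cov_years = 1L, p_dropout = 0, seed = seed, ...)
}
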