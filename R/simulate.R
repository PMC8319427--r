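# Synthetic multibreed herd generator.
#
# Emulates a graded Angus-Brahman spectrum: six breed groups spanning 0-100%
# Brahman, breed-graded allele frequencies, compositional taxon abundances
# with a detection floor, additive-genetic taxon effects with chosen
# heritability, and phenotypes (weight gain, IgG1) with chosen microbiability.
# Every draw flows from one seed so downstream stages are testable against
# planted truth.

# Brahman-fraction ranges of the six breed groups. BG3 is a fixed 62.5/37.5
# Angus/Brahman cross, i.e. a degenerate range.
.bg_ranges <- rbind(c(0.00, 0.20),
                    c(0.21, 0.40),
                    c(0.375, 0.375),
                    c(0.41, 0.60),
                    c(0.61, 0.80),
                    c(0.81, 1.00))

.stage_age <- list(preweaning  = c(mean = 90,  sd = 10),
                   postweaning = c(mean = 365, sd = 15),
                   fattening   = c(mean = 540, sd = 20))

#' Configuration for the synthetic herd generator
#'
#' Bundles and validates all generator parameters. Defaults describe a
#' single-stage cohort of 200 animals genotyped at 2,000 independent SNPs
#' with 100 taxa; see the methods vignette for the rationale behind each
#' default.
#'
#' @param n_individuals number of animals.
#' @param n_snps number of simulated SNPs (>= 2, no linkage disequilibrium).
#' @param n_taxa number of simulated taxa.
#' @param stage growth stage of the cohort, one of `"preweaning"`,
#'   `"postweaning"`, `"fattening"`.
#' @param detection_floor relative abundance below which a value is recorded
#'   as zero. Default is twice the half-detection-limit constant 0.00004613,
#'   i.e. the implied detection limit 0.00009226.
#' @param taxon_h2 target heritability per taxon (recycled), each in `[0, 1)`.
#' @param breed_slope effect of Brahman fraction on latent log abundance per
#'   taxon (recycled).
#' @param sex_effect additive effect of male sex on latent log abundance.
#' @param intercept_sd spread of per-taxon baseline log abundances; controls
#'   how uneven the simulated composition is.
#' @param phenotype_m2 target microbiability for the simulated phenotypes
#'   (length 1, or length 2 as `c(WG, IgG1)`), each in `[0, 1)`.
#' @param graded_freq if `TRUE` (default), Angus and Brahman reference allele
#'   frequencies are drawn independently per SNP so allele frequency grades
#'   with breed composition; if `FALSE`, the two breeds share frequencies
#'   (a genetically homogeneous herd).
#' @param allele_freq_range range from which per-breed allele frequencies are
#'   drawn uniformly.
#' @param seed integer seed; required, the generator never silently seeds
#'   from the clock.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_individuals = 200, n_snps = 2000, n_taxa = 100,
                       stage = c("preweaning", "postweaning", "fattening"),
                       detection_floor = 2 * 0.00004613,
                       taxon_h2 = 0.25, breed_slope = 0.5, sex_effect = 0.2,
                       intercept_sd = 1.5, phenotype_m2 = 0.1,
                       graded_freq = TRUE,
                       allele_freq_range = c(0.05, 0.95), seed) {
  if (missing(seed)) stop("'seed' is required; clock seeding is not allowed",
                          call. = FALSE)
  stage <- match.arg(stage)
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals"),
    n_snps = check_count(n_snps, "n_snps", min = 2L),
    n_taxa = check_count(n_taxa, "n_taxa"),
    stage = stage,
    detection_floor = check_prob(detection_floor, "detection_floor",
                                 open_lo = TRUE, open_hi = TRUE),
    taxon_h2 = check_prob(taxon_h2, "taxon_h2", open_hi = TRUE),
    breed_slope = breed_slope,
    sex_effect = sex_effect,
    intercept_sd = intercept_sd,
    phenotype_m2 = check_prob(phenotype_m2, "phenotype_m2", open_hi = TRUE),
    graded_freq = isTRUE(graded_freq),
    allele_freq_range = check_prob(allele_freq_range, "allele_freq_range",
                                   open_lo = TRUE, open_hi = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$phenotype_m2) == 1L) {
    cfg$phenotype_m2 <- rep(cfg$phenotype_m2, 2L)
  }
  stopifnot(length(cfg$phenotype_m2) == 2L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multibreed population: breed structure and genotypes
#'
#' Animals are spread evenly over the six breed groups; each animal's Brahman
#' fraction is drawn uniformly within its group's range. Per SNP, the allele
#' frequency of an animal with Brahman fraction `b` is
#' `p(b) = p_A + b * (p_B - p_A)` and genotypes are independent
#' `Binomial(2, p(b))` draws (no linkage disequilibrium). Sex is Bernoulli(1/2)
#' and age is drawn around the stage-typical mean.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"herd_population"` with elements
#'   `genotypes` (a [genotype_matrix()]), `meta` (data frame with `animal`,
#'   `breed_group`, `brahman_fraction`, `sex`, `age`, `stage`) and `truth`
#'   (per-SNP `p_A`, `p_B` and the config).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_individuals
  P <- config$n_snps

  bg <- sample(rep_len(1:6, n))
  bf <- runif(n, .bg_ranges[bg, 1], .bg_ranges[bg, 2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ag <- .stage_age[[config$stage]]
  age <- round(rnorm(n, ag["mean"], ag["sd"]))

  rng <- config$allele_freq_range
  p_A <- runif(P, rng[1], rng[2])
  p_B <- if (config$graded_freq) runif(P, rng[1], rng[2]) else p_A
  pm <- matrix(p_A, n, P, byrow = TRUE) + bf %o% (p_B - p_A)
  calls <- matrix(rbinom(n * P, 2L, pm), n, P)

  ids <- sprintf("A%04d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(P))
  map <- data.frame(snp = snp_ids,
                    chrom = as.character(rep_len(1:29, P)),
                    pos = 1e5L * (seq_len(P) %/% 29 + 1L) + seq_len(P),
                    stringsAsFactors = FALSE)
  dimnames(calls) <- list(ids, snp_ids)

  meta <- data.frame(animal = ids, breed_group = bg, brahman_fraction = bf,
                     sex = sex, age = age, stage = config$stage,
                     stringsAsFactors = FALSE)
  structure(list(genotypes = genotype_matrix(calls, map),
                 meta = meta,
                 truth = list(p_A = p_A, p_B = p_B, config = config)),
            class = "herd_population")
}

#' Draw correlated random effects with covariance `K * sigma2`
#'
#' Uses the lower Cholesky factor of `K + 1e-8 I` (ridge for numerical
#' positive semi-definiteness of Gram-type matrices).
#'
#' @param K relationship matrix (genomic or microbial).
#' @param sigma2 variance of the effect.
#' @param n_draws number of independent vectors to draw (columns).
#' @return An `nrow(K) x n_draws` matrix.
#' @export
simulate_polygenic_values <- function(K, sigma2, n_draws = 1L) {
  L <- chol_psd(as.matrix(K))
  L %*% matrix(rnorm(nrow(L) * n_draws, sd = sqrt(sigma2)), nrow(L), n_draws)
}

#' Simulate compositional taxon abundances with planted heritabilities
#'
#' Per taxon, a latent (natural-log) abundance is built as
#' `intercept + breed_slope * brahman_fraction + sex_effect * male + g + e`
#' where `g` has covariance `G * sigma2_u` (G from the simulated genotypes,
#' VanRaden) and `e` is iid normal, with
#' `sigma2_u / (sigma2_u + sigma2_e)` equal to the taxon's target
#' heritability (total latent variance 1). Latent values are exponentiated,
#' renormalized per sample to sum to one, and values below the detection
#' floor are set to exactly zero.
#'
#' @param population a [simulate_population()] result.
#' @param config the same [sim_config()] object.
#' @return A list of class `"herd_taxa"`: `abundance` (samples x taxa
#'   relative-abundance matrix, post-floor), `latent` (pre-compositional
#'   latent log abundances), `genetic` (the drawn genetic values, for
#'   oracle checks), `truth` (per-taxon targets), `G` (the GRM used).
#' @export
simulate_taxa <- function(population, config) {
  stopifnot(inherits(population, "herd_population"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_individuals
  TT <- config$n_taxa
  h2 <- rep_len(check_prob(config$taxon_h2, "taxon_h2", open_hi = TRUE), TT)
  slope <- rep_len(config$breed_slope, TT)

  G <- grm_vanraden(population$genotypes)
  L <- chol_psd(G)

  intercept <- rnorm(TT, mean = 0, sd = config$intercept_sd)
  bf <- population$meta$brahman_fraction
  male <- as.numeric(population$meta$sex == "M")

  gmat <- L %*% matrix(rnorm(n * TT), n, TT) %*% diag(sqrt(h2), TT)
  emat <- matrix(rnorm(n * TT), n, TT) %*% diag(sqrt(1 - h2), TT)
  latent <- matrix(intercept, n, TT, byrow = TRUE) +
    bf %o% slope + config$sex_effect * male + gmat + emat

  rel <- exp(latent)
  rel <- rel / rowSums(rel)
  floored <- rel
  floored[floored < config$detection_floor] <- 0

  taxa <- sprintf("taxon_%03d", seq_len(TT))
  dimnames(floored) <- dimnames(latent) <- dimnames(gmat) <-
    list(population$meta$animal, taxa)

  structure(list(abundance = floored, latent = latent, genetic = gmat,
                 truth = data.frame(taxon = taxa, h2 = h2, slope = slope,
                                    intercept = intercept,
                                    stringsAsFactors = FALSE),
                 G = G),
            class = "herd_taxa")
}

# Stage-specific names of the initial/final body-weight columns.
.stage_bw <- list(
  preweaning  = c(initial = "BW_newborn",    final = "BW_preweaning"),
  postweaning = c(initial = "BW_preweaning", final = "BW_postweaning"),
  fattening   = c(initial = "BW_postweaning", final = "BW_fattening"))

#' Simulate phenotypes (weight gain, IgG1) with planted microbiability
#'
#' Builds the microbial relationship matrix `M = OO'/n` from the core-filtered,
#' floor-adjusted log10 abundances, then draws for each phenotype a microbiome
#' effect `m ~ N(0, M * sigma2_m)` and residual `e ~ N(0, I * sigma2_e)` with
#' `sigma2_m / (sigma2_m + sigma2_e)` equal to the target microbiability.
#' Weight gain satisfies `WG_stage = BW_stage - BW_initial` by construction.
#'
#' @param population a [simulate_population()] result.
#' @param taxa a [simulate_taxa()] result on the same animals.
#' @param config the same [sim_config()] object.
#' @return A list of class `"herd_phenotypes"`: `meta` (the population
#'   metadata with body weights, `WG`, `IgG1` filled in), `truth`
#'   (planted m2 and the realized microbiome effects), `M` (the microbial
#'   relationship matrix used).
#' @export
simulate_phenotypes <- function(population, taxa, config) {
  stopifnot(inherits(population, "herd_population"),
            inherits(taxa, "herd_taxa"),
            identical(rownames(taxa$abundance), population$meta$animal))
  set.seed(derive_seed(config$seed, 3L))
  meta <- population$meta
  n <- nrow(meta)
  m2 <- check_prob(config$phenotype_m2, "phenotype_m2", open_hi = TRUE)

  core <- core_taxa_filter(taxa$abundance)
  O <- log10_floor_transform(core)
  M <- microbial_relationship(O)
  Lm <- chol_psd(M)

  male <- as.numeric(meta$sex == "M")
  age_c <- meta$age - mean(meta$age)

  draw <- function(m2_t) {
    m <- drop(Lm %*% rnorm(n)) * sqrt(m2_t)
    e <- rnorm(n, sd = sqrt(1 - m2_t))
    list(m = m, e = e)
  }

  bw_names <- .stage_bw[[config$stage]]
  bw_initial <- rnorm(n, mean = c(preweaning = 30, postweaning = 120,
                                  fattening = 260)[[config$stage]], sd = 6)
  wg_part <- draw(m2[1])
  # fixed part + scaled (m + e); scale 12 kg keeps the variance ratio intact
  wg <- 80 + 10 * male + 0.25 * age_c + 0.3 * (bw_initial - mean(bw_initial)) +
    12 * (wg_part$m + wg_part$e)
  igg_part <- draw(m2[2])
  igg <- 20 - 5 * meta$brahman_fraction + 2 * male + 0.02 * age_c +
    6 * (igg_part$m + igg_part$e)

  meta[[bw_names["initial"]]] <- bw_initial
  meta[[bw_names["final"]]] <- bw_initial + wg
  meta[[paste0("WG_", config$stage)]] <- wg
  meta$WG <- wg
  meta$IgG1 <- igg

  structure(list(meta = meta,
                 truth = list(m2 = stats::setNames(m2, c("WG", "IgG1")),
                              m_WG = wg_part$m, m_IgG1 = igg_part$m),
                 M = M),
            class = "herd_phenotypes")
}

#' Simulate a complete herd (population, taxa, phenotypes)
#'
#' Convenience wrapper chaining [simulate_population()], [simulate_taxa()]
#' and [simulate_phenotypes()].
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"herd_sim"` with elements `population`, `taxa`,
#'   `phenotypes` and `meta` (the fully populated metadata table).
#' @export
simulate_herd <- function(config) {
  population <- simulate_population(config)
  taxa <- simulate_taxa(population, config)
  phenotypes <- simulate_phenotypes(population, taxa, config)
  structure(list(population = population, taxa = taxa,
                 phenotypes = phenotypes, meta = phenotypes$meta),
            class = "herd_sim")
}
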