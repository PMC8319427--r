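# Pipeline orchestration: run the per-stage workflow (QC -> core filter &
# log transform -> diversity/PERMANOVA -> heritability -> association scans
# -> GWAS -> microbiability -> network -> genotype-breed correlation) on
# file inputs or on a simulated herd, writing TSV results and a JSON run
# manifest with every threshold and seed.

.pipeline_stages <- c("qc", "diversity", "heritability", "breed_assoc",
                      "pheno_assoc", "gwas", "microbiability", "network",
                      "snp_breed")

#' Default pipeline configuration
#'
#' All thresholds default to the published values of the filter chain and
#' scans: QC thresholds from [qc_thresholds()], core prevalence 0.5, floor
#' constant 0.00004613, network thresholds 0.25 / 0.001, PERMANOVA with 999
#' permutations, GWAS FDR 0.05.
#'
#' @param seed master seed (required).
#' @param stages which stages to run (default: all, in order).
#' @param simulate `NULL`, or a list of [sim_config()] arguments (seed is
#'   filled in from the pipeline seed if absent); when set, inputs are
#'   generated rather than read.
#' @param genotypes,abundance,metadata input file paths (ignored in
#'   simulate mode).
#' @param gwas_taxa taxa to scan genome-wide (default: the first core taxon).
#' @param n_perm PERMANOVA permutations.
#' @param thresholds a [qc_thresholds()] list.
#' @param core_prevalence,half_floor,min_rho,max_q,gwas_fdr stage thresholds.
#' @param outlier_filters forward to [apply_qc()].
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(seed, stages = .pipeline_stages, simulate = NULL,
                            genotypes = NULL, abundance = NULL,
                            metadata = NULL, gwas_taxa = 1L, n_perm = 999,
                            thresholds = qc_thresholds(),
                            core_prevalence = 0.5, half_floor = 0.00004613,
                            min_rho = 0.25, max_q = 0.001, gwas_fdr = 0.05,
                            outlier_filters = TRUE) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  cfg <- list(seed = check_count(seed, "seed", min = 0L), stages = stages,
              simulate = simulate, genotypes = genotypes,
              abundance = abundance, metadata = metadata,
              gwas_taxa = gwas_taxa, n_perm = n_perm,
              thresholds = thresholds, core_prevalence = core_prevalence,
              half_floor = half_floor, min_rho = min_rho, max_q = max_q,
              gwas_fdr = gwas_fdr, outlier_filters = isTRUE(outlier_filters))
  if (is.null(cfg$simulate)) {
    for (f in c("genotypes", "abundance", "metadata")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop(sprintf("input file for '%s' is missing", f), call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `simulate`
#' block holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (argument precedence:
#'   explicit call > YAML > defaults).
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order and writes each stage's result
#' tables under `output_dir`, plus `manifest.json` recording package and R
#' versions, the seed, every threshold consumed by any stage, the design
#' decisions in force, and the files written. Two runs from the same config
#' and seed produce identical result files.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param output_dir results directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name, writer = write.table) {
    path <- file.path(output_dir, name)
    if (identical(writer, write.table))
      write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else writer(obj, path)
    files <<- c(files, name)
    path
  }
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    scfg <- do.call(sim_config, sim_args)
    herd <- simulate_herd(scfg)
    geno <- herd$population$genotypes
    abundance <- herd$taxa$abundance
    meta <- herd$meta
    emit(geno, "genotypes.tsv", write_genotypes_tsv)
    emit(abundance, "abundance.tsv", write_abundance_tsv)
    emit(meta, "metadata.csv", write_metadata_csv)
    truth <- herd$taxa$truth
    truth$m2_WG <- herd$phenotypes$truth$m2["WG"]
    truth$m2_IgG1 <- herd$phenotypes$truth$m2["IgG1"]
    emit(truth, "truth.tsv")
  } else {
    geno <- read_genotypes(config$genotypes)
    abundance <- read_abundance_tsv(config$abundance)
    meta <- read_metadata_csv(config$metadata)
  }
  ord <- match(meta$animal, rownames(abundance))
  if (anyNA(ord)) stop("metadata and abundance samples do not match",
                       call. = FALSE)
  abundance <- abundance[ord, , drop = FALSE]

  # ---- QC ----
  if ("qc" %in% config$stages) {
    qc <- stage("qc", apply_qc(geno, config$thresholds,
                               outlier_filters = config$outlier_filters))
    geno <- qc$genotypes
    keep <- meta$animal %in% rownames(geno$calls)
    meta <- meta[keep, , drop = FALSE]
    abundance <- abundance[meta$animal, , drop = FALSE]
    write_qc_report(qc$report, file.path(output_dir, "qc"))
    files <- c(files, file.path("qc", c("removed_individuals.tsv",
                                        "removed_snps.tsv", "snp_stats.tsv")))
    results$qc <- qc$report
  }

  # ---- preprocessing shared by later stages ----
  core <- core_taxa_filter(abundance, config$core_prevalence)
  logab <- log10_floor_transform(core, config$half_floor)
  K <- NULL
  get_K <- function() {
    if (is.null(K)) K <<- grm_vanraden(geno)
    K
  }

  # ---- diversity ----
  if ("diversity" %in% config$stages) {
    results$diversity <- stage("diversity", {
      shannon <- apply(abundance, 1L, shannon_index)
      D <- bray_curtis(abundance)
      ord2 <- pcoa(D, k = 2)
      perm <- permanova(D, meta$breed_group, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, 21L))
      emit(data.frame(sample = names(shannon), shannon = shannon),
           "shannon.tsv")
      emit(D, "bray_curtis.tsv", write_square_tsv)
      emit(data.frame(sample = rownames(ord2$points), ord2$points),
           "pcoa.tsv")
      emit(data.frame(term = "breed_group", pseudo_f = perm$f, p = perm$p,
                      n_perm = perm$n_perm, exhaustive = perm$exhaustive),
           "permanova.tsv")
      list(shannon = shannon, pcoa = ord2, permanova = perm)
    })
  }

  # ---- heritability per core taxon ----
  if ("heritability" %in% config$stages) {
    results$heritability <- stage("heritability", {
      Kg <- get_K()
      dat <- meta
      h2 <- lapply(colnames(logab), function(tx) {
        dat$y <- logab[, tx]
        fit <- animal_model(y ~ age + sex, data = dat, K = Kg)
        vc <- fit$varcomp
        data.frame(taxon = tx, h2 = vc$ratio, sigma2_u = vc$sigma2_u,
                   sigma2_e = vc$sigma2_e, flat = vc$flat_likelihood)
      })
      h2 <- do.call(rbind, h2)
      emit(h2, "heritability.tsv")
      h2
    })
  }

  # ---- breed-composition association scan ----
  if ("breed_assoc" %in% config$stages) {
    results$breed_assoc <- stage("breed_assoc", {
      scan <- breed_association_scan(logab, meta)
      emit(scan, "breed_association.tsv")
      emit(scan_summary(scan), "breed_association_summary.tsv")
      scan
    })
  }

  # ---- phenotype association scans ----
  if ("pheno_assoc" %in% config$stages) {
    results$pheno_assoc <- stage("pheno_assoc", {
      out <- list()
      for (resp in c("WG", "IgG1")) {
        if (!resp %in% names(meta)) next
        scan <- phenotype_association_scan(meta, logab, response = resp)
        emit(scan, sprintf("pheno_association_%s.tsv", resp))
        out[[resp]] <- scan
      }
      out
    })
  }

  # ---- genome scans for selected taxa ----
  if ("gwas" %in% config$stages) {
    results$gwas <- stage("gwas", {
      taxa <- config$gwas_taxa
      if (is.numeric(taxa)) taxa <- colnames(logab)[taxa]
      taxa <- intersect(taxa, colnames(logab))
      Kg <- get_K()
      X <- cbind(1, assoc_design(meta))
      out <- list()
      for (tx in taxa) {
        rec <- gwas_two_step(logab[, tx], X, Kg, geno, fdr = config$gwas_fdr)
        emit(rec[, setdiff(names(rec), "tested")],
             sprintf("gwas_%s.tsv", tx))
        out[[tx]] <- rec
      }
      out
    })
  }

  # ---- microbiability ----
  if ("microbiability" %in% config$stages) {
    results$microbiability <- stage("microbiability", {
      M <- microbial_relationship(logab)
      dat <- meta
      out <- list()
      for (resp in c("WG", "IgG1")) {
        if (!resp %in% names(meta)) next
        dat$y <- meta[[resp]]
        fit <- animal_model(y ~ age + sex, data = dat, K = M)
        out[[resp]] <- fit$varcomp
      }
      tab <- do.call(rbind, lapply(names(out), function(r)
        data.frame(response = r, m2 = out[[r]]$ratio,
                   sigma2_m = out[[r]]$sigma2_u,
                   sigma2_e = out[[r]]$sigma2_e,
                   flat = out[[r]]$flat_likelihood)))
      emit(tab, "microbiability.tsv")
      out
    })
  }

  # ---- co-occurrence network ----
  if ("network" %in% config$stages) {
    results$network <- stage("network", {
      net <- cooccurrence_network(core, min_rho = config$min_rho,
                                  max_q = config$max_q)
      emit(net, "network_edges.tsv", write_network_edges)
      emit(net, "network.graphml", write_network_graphml)
      emit(data.frame(taxon = names(net$degree), degree = net$degree,
                      hub = names(net$degree) %in% net$hub), "network_nodes.tsv")
      net
    })
  }

  # ---- genotype vs breed composition ----
  if ("snp_breed" %in% config$stages) {
    results$snp_breed <- stage("snp_breed", {
      snps <- head(colnames(geno$calls), 50L)
      gb <- genotype_breed_correlation(geno, meta, snps)
      emit(gb$correlations, "snp_breed_correlation.tsv")
      emit(data.frame(snp = rownames(gb$maf_by_group), gb$maf_by_group),
           "snp_breed_maf.tsv")
      gb
    })
  }

  manifest <- list(
    package = "herdscan",
    version = as.character(packageVersion("herdscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(
      qc = config$thresholds,
      core_prevalence = config$core_prevalence,
      half_floor = config$half_floor,
      permanova_n_perm = config$n_perm,
      network_min_rho = config$min_rho,
      network_max_q = config$max_q,
      gwas_fdr = config$gwas_fdr,
      significant_p = 0.05, tendency_p = 0.10),
    design = list(
      grm = "VanRaden method 1, cohort allele frequencies",
      reml = "single-component, ratio-profiled, EMMA-style eigendecomposition",
      genomic_control = "median-based (Devlin-Roeder), lambda clipped at 1",
      outlier_rule = "one-sided z -> BH, FDR < 1%",
      shannon_base = 2,
      fdr_family_network = "upper triangle"),
    outlier_filters = config$outlier_filters,
    files = files)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
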