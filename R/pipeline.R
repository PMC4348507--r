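#' Pipeline configuration
#'
#' Collects every threshold of the pipeline in one place, all defaulting
#' to the method's standard values, plus an artifact directory and a seed.
#'
#' @param out_dir directory for stage artifacts.
#' @param eps HMM per-allele error rate.
#' @param ibd_threshold,ibd_min_markers segment extraction parameters.
#' @param w_min,a_min clique pruning thresholds.
#' @param informative_cut,assign_cut parental-origin thresholds.
#' @param majority_frac imputation majority fraction.
#' @param ld_prob_cut,ld_het_conc_min,ld_maf_min LD-merge thresholds.
#' @param cv_thin cross-validation marker thinning.
#' @param sim a [sim_config()] used by the `simulate` stage.
#' @param seed integer seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir = tempfile("pedimpute_"), eps = 0.005,
                            ibd_threshold = 0.5, ibd_min_markers = 10L,
                            w_min = 0.85, a_min = 0.9,
                            informative_cut = 0.25, assign_cut = 0.75,
                            majority_frac = 2 / 3, ld_prob_cut = 0.99,
                            ld_het_conc_min = 0.99, ld_maf_min = 0.01,
                            cv_thin = 5L, sim = sim_config(), seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

stage_path <- function(config, name) file.path(config$out_dir, paste0(name, ".rds"))

load_stage <- function(config, name, needed_by) {
  p <- stage_path(config, name)
  if (!file.exists(p))
    stop("stage '", needed_by, "' requires artifact of stage '", name,
         "'; run it first")
  readRDS(p)
}

save_stage <- function(config, name, value) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, stage_path(config, name))
  invisible(value)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `qc-framework`, `phase`, `ibd`, `cliques`, `po`,
#' `impute`, `seq-qc`, `cross-validate`. Each stage reads its upstream
#' artifacts from `config$out_dir`, writes its own, and is deterministic
#' given identical inputs; a missing upstream artifact raises an error
#' naming the stage to run.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return The stage's artifact, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  t0 <- Sys.time()
  res <- switch(
    stage,
    "simulate" = {
      study <- simulate_study(config$sim, seed = config$seed)
      save_stage(config, "study", study)
    },
    "qc-framework" = {
      study <- load_stage(config, "study", stage)
      qc <- framework_qc(study$framework, study$ped)
      save_stage(config, "qc", qc)
    },
    "phase" = {
      study <- load_stage(config, "study", stage)
      qc <- load_stage(config, "qc", stage)
      ph <- phase_cohort(study$ped, qc$genotypes, eps = config$eps)
      save_stage(config, "phase", ph)
    },
    "ibd" = {
      study <- load_stage(config, "study", stage)
      ph <- load_stage(config, "phase", stage)
      store <- pairwise_ibd(ph$haplotypes, study$ped, eps = config$eps,
                            threshold = config$ibd_threshold,
                            min_markers = config$ibd_min_markers)
      save_stage(config, "ibd", store)
    },
    "cliques" = {
      study <- load_stage(config, "study", stage)
      store <- load_stage(config, "ibd", stage)
      G <- load_stage(config, "qc", stage)$genotypes
      anchors <- unique(anchor_markers(
        list(markers = seq_len(nrow(G$map)), map = G$map),
        study$variants$chrom, study$variants$bp))
      thinned <- seq(1L, nrow(G$map), by = config$cv_thin)
      D <- build_dictionary(store, sort(unique(c(anchors, thinned))),
                            w_min = config$w_min, a_min = config$a_min)
      save_stage(config, "cliques", D)
    },
    "po" = {
      study <- load_stage(config, "study", stage)
      ph <- load_stage(config, "phase", stage)
      D <- load_stage(config, "cliques", stage)
      po <- assign_parental_origin(study$ped, ph$haplotypes, D,
                                   informative_cut = config$informative_cut,
                                   assign_cut = config$assign_cut)
      save_stage(config, "po", po)
    },
    "impute" = {
      study <- load_stage(config, "study", stage)
      D <- load_stage(config, "cliques", stage)
      panel <- impute_all(study$variants, D, study$seq_geno, study$sequenced,
                          frac = config$majority_frac)
      save_stage(config, "impute", panel)
    },
    "seq-qc" = {
      study <- load_stage(config, "study", stage)
      store <- load_stage(config, "ibd", stage)
      variants <- classify_variants(study$variants, study$seq_geno)
      tab <- ibd2_table(store, study$sequenced)
      rates <- class_discordance_rate(variants, study$seq_geno, tab)
      pass <- apply_class_cutoffs(variants)
      save_stage(config, "seq-qc", list(variants = variants, rates = rates,
                                        pass = pass))
    },
    "cross-validate" = {
      study <- load_stage(config, "study", stage)
      qc <- load_stage(config, "qc", stage)
      D <- load_stage(config, "cliques", stage)
      cv <- cross_validate(qc$genotypes, D, study$sequenced,
                           k = config$cv_thin, frac = config$majority_frac)
      save_stage(config, "cross-validate", cv)
    },
    stop("unknown stage: ", stage))
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param stages stage names in order.
#' @return Named list of stage artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "qc-framework", "phase",
                                    "ibd", "cliques", "po", "impute",
                                    "seq-qc", "cross-validate")) {
  setNames(lapply(stages, run_stage, config = config), stages)
}
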