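# Pipeline orchestration: stages over a single configuration with derived
# per-stage seeds, manifests with input hashes, and atomic writes. Stage
# artifacts live under the configured output directory; a stage whose
# config and inputs are unchanged is a no-op.

.hairqtl_stages <- c("simulate", "preprocess", "grm", "varcomp", "gwas",
                     "pleio", "finemap", "gsea")

#' Assemble (or load) a pipeline run configuration
#'
#' A run configuration holds the output directory, the global seed, the
#' analysis profile, and per-stage parameter blocks. `load_run_config()`
#' reads the same structure from a YAML file.
#'
#' @param out_dir Output directory for stage artifacts and manifests.
#' @param seed Global seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#' @param profile `"desk"` (default) or `"study"` (full protocol); resolves chain lengths.
#' @param params Named list of per-stage overrides, e.g.
#'   `list(preprocess = list(iqr_k = 4.5))`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "hairqtl_run", seed = 20250514L,
                       profile = c("desk", "study"), params = list()) {
  profile <- match.arg(profile)
  defaults <- list(
    simulate = list(),
    preprocess = list(iqr_k = 4.5, cv_flag = 0.15),
    grm = list(ridge = 1e-6),
    varcomp = list(response = "ln_cortisol"),
    gwas = list(response = "ln_cortisol", window_bp = 1e6,
                qtl_threshold = 1),
    pleio = list(traits = c("ln_cortisol", "ln_hormone2"),
                 window_bp = 0.25e6, ad_threshold = 0.02),
    finemap = list(response = "ln_cortisol"),
    gsea = list(bounds = c(11, 8999), n_perm = 500, weight = 1,
                fdr_threshold = 0.25)
  )
  for (nm in names(params)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]] %||% list(),
                                        params[[nm]])
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profile = profile, params = defaults),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_config
#' @param path YAML file with fields `out_dir`, `seed`, `profile`, and
#'   per-stage blocks under `params`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = y$out_dir %||% "hairqtl_run",
             seed = y$seed %||% 20250514L,
             profile = y$profile %||% "desk",
             params = y$params %||% list())
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic splitting rule: `(seed * 97 + stage index) mod (2^31 - 1)`,
#' so stages can be rerun independently yet reproducibly.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  i <- match(stage, .hairqtl_stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 97 + i * 1009) %% (2^31 - 1))
}

.artifact_path <- function(config, name) file.path(config$out_dir, name)

.write_atomic <- function(object, path) {
  tmp <- paste0(path, ".tmp")
  saveRDS(object, tmp)
  file.rename(tmp, path)
  path
}

.manifest_path <- function(config, stage) {
  .artifact_path(config, paste0(stage, ".manifest.json"))
}

.stage_inputs <- function(stage) {
  switch(stage,
         simulate = character(0),
         preprocess = "simulate.rds",
         grm = "simulate.rds",
         varcomp = c("simulate.rds", "grm.rds"),
         gwas = "simulate.rds",
         pleio = "simulate.rds",
         finemap = c("simulate.rds", "grm.rds", "gwas.rds"),
         gsea = c("gwas.rds", "pleio.rds"))
}

.check_inputs <- function(config, stage) {
  for (f in .stage_inputs(stage)) {
    p <- .artifact_path(config, f)
    if (!file.exists(p)) stop("missing upstream artifact: ", p)
    up_stage <- sub("\\.rds$", "", f)
    mp <- .manifest_path(config, up_stage)
    if (file.exists(mp)) {
      man <- jsonlite::read_json(mp)
      h <- unname(tools::md5sum(p))
      if (!identical(man$output_hash, h)) {
        stop("artifact hash mismatch (corrupted or stale): ", p)
      }
    }
  }
}

.config_hash <- function(config, stage) {
  digestable <- list(seed = config$seed, profile = config$profile,
                     params = config$params[[stage]])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(digestable, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run one pipeline stage
#'
#' Checks upstream artifacts against their manifests, runs the stage with
#' its derived seed, writes its artifact atomically, and records a
#' manifest (config hash, seed, input and output hashes, package
#' version). Rerunning with unchanged config and inputs is a no-op.
#'
#' @param stage One of `simulate`, `preprocess`, `grm`, `varcomp`, `gwas`,
#'   `pleio`, `finemap`, `gsea`.
#' @param config A [run_config()].
#' @return The stage artifact, invisibly.
#' @export
run_stage <- function(stage, config = run_config()) {
  stage <- match.arg(stage, .hairqtl_stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .check_inputs(config, stage)
  out_path <- .artifact_path(config, paste0(stage, ".rds"))
  mp <- .manifest_path(config, stage)
  chash <- .config_hash(config, stage)
  in_hashes <- lapply(.stage_inputs(stage), function(f) {
    unname(tools::md5sum(.artifact_path(config, f)))
  })
  if (file.exists(mp) && file.exists(out_path)) {
    man <- jsonlite::read_json(mp)
    if (identical(man$config_hash, unname(chash)) &&
        identical(unlist(man$input_hashes), unlist(in_hashes)) &&
        identical(man$output_hash, unname(tools::md5sum(out_path)))) {
      message("stage '", stage, "' is up to date; skipping")
      return(invisible(readRDS(out_path)))
    }
  }
  seed <- derive_seed(config$seed, stage)
  pars <- config$params[[stage]]
  artifact <- switch(
    stage,
    simulate = simulate_study(sim_params(seed = seed)),
    preprocess = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      set.seed(seed)
      assays <- simulate_assay(setNames(study$phenotypes$cortisol,
                                        study$phenotypes$pig), study$params)
      conc <- summarise_assays(assays, cv_flag = pars$cv_flag)
      qc <- iqr_outlier_filter(conc$concentration, k = pars$iqr_k,
                               ids = conc$pig)
      list(assays = assays, concentrations = conc, qc = qc)
    },
    grm = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      company_grm(study$genotypes, ridge = pars$ridge)
    },
    varcomp = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      grm <- readRDS(.artifact_path(config, "grm.rds"))
      fit_univariate_reml(study$phenotypes, pars$response, grm)
    },
    gwas = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      chain <- run_bayesb(study$phenotypes, pars$response, study$genotypes,
                          bayesb_config(config$profile),
                          window_bp = pars$window_bp, seed = seed)
      list(chain = chain,
           windows = window_egv(chain, qtl_threshold = pars$qtl_threshold))
    },
    pleio = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      chain <- run_bivariate_bayesb(study$phenotypes, pars$traits,
                                    study$genotypes,
                                    bayesb_config(config$profile),
                                    window_bp = pars$window_bp, seed = seed)
      list(chain = chain,
           windows = window_sign_probs(chain,
                                       ad_threshold = pars$ad_threshold))
    },
    finemap = {
      study <- readRDS(.artifact_path(config, "simulate.rds"))
      grm <- readRDS(.artifact_path(config, "grm.rds"))
      gwas <- readRDS(.artifact_path(config, "gwas.rds"))
      lead <- gwas$chain$snps$id[which.max(gwas$chain$snps$pip)]
      fit_snp_covariate(study$phenotypes, config$params$varcomp$response,
                        lead, study$genotypes, grm)
    },
    gsea = {
      gwas <- readRDS(.artifact_path(config, "gwas.rds"))
      pleio <- readRDS(.artifact_path(config, "pleio.rds"))
      ranked <- rank_windows(gwas$windows)
      # a synthetic annotation: random genes per window, random terms
      set.seed(seed)
      windows <- ranked$window
      gene_windows <- tibble::tibble(
        gene = sprintf("gene%04d", seq_along(windows) * 2L),
        window = rep(windows, each = 1))
      gene_terms <- tibble::tibble(
        gene = sample(gene_windows$gene, length(windows) * 3, replace = TRUE),
        term = sample(sprintf("TERM_%02d", 1:12), length(windows) * 3,
                      replace = TRUE))
      lib <- build_window_library(gene_windows, gene_terms,
                                  bounds = pars$bounds)
      gsea_preranked(ranked, lib, p = pars$weight, n_perm = pars$n_perm,
                     seed = seed, fdr_threshold = pars$fdr_threshold)
    })
  .write_atomic(artifact, out_path)
  manifest <- list(stage = stage, seed = seed, config_hash = unname(chash),
                   input_hashes = in_hashes,
                   output_hash = unname(tools::md5sum(out_path)),
                   package_version = as.character(utils::packageVersion("hairqtl")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), mp)
  invisible(artifact)
}

#' Run the full pipeline
#'
#' Runs every stage in order; equivalent to calling [run_stage()] for each.
#'
#' @param config A [run_config()].
#' @param stages Stages to run (default all, in dependency order).
#' @return Named list of stage artifacts, invisibly.
#' @export
run_pipeline <- function(config = run_config(), stages = .hairqtl_stages) {
  out <- list()
  for (s in stages) out[[s]] <- run_stage(s, config)
  invisible(out)
}
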