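## End-to-end orchestration of the subgroup analysis: read or simulate
## inputs, admission filtering, tree building, model fits and LRTs, omega
## profiles, the random-cohort comparison, and diversity statistics, with a
## JSON run manifest tying every reported number to a stage output file.

#' Run the selection-pressure pipeline on one input bundle
#'
#' Stages, in dependency order: load inputs (protein alignment, CDS,
#' position map, subgroup table; or a synthetic bundle), assemble the codon
#' alignment, Nei-Gojobori admission, NJ tree, codon site-model fits with
#' likelihood ratio tests, per-site omega profile, random-cohort comparison
#' of the key positions, and key-position diversity. A failure in one stage
#' is recorded in the manifest without aborting earlier results.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized keys: `protein`, `cds`, `position_map`, `subgroups`
#'   (input paths), `out_dir`, `seed`, `models` (default
#'   `c("M0","M1a","M2a","M3","M7","M8")`), `tests` (default `c(1,2,3,4)`),
#'   `alpha`, `codon_freq`, `n_cohorts`, `cohort_size`, `restarts`.
#' @param force Recompute stages whose outputs already exist?
#' @return The run manifest (named list, also written as `manifest.json` in
#'   `out_dir`): configuration snapshot, seeds, per-stage status, and output
#'   paths.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(seed = 1, tests = c(1, 2, 3, 4), alpha = 0.05,
                   codon_freq = "F3x4", n_cohorts = 200, cohort_size = 10,
                   restarts = 1, out_dir = "siteomega_out",
                   profile_model = "M7")
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("protein", "cds", "position_map", "subgroups")) {
    if (is.null(cfg[[key]]))
      stop("config error: missing input path '", key, "'")
    if (!file.exists(cfg[[key]]))
      stop("config error: input file not found: ", cfg[[key]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, version = as.character(utils::packageVersion("siteomega")),
                   stages = list(), outputs = list())
  out_path <- function(name) file.path(cfg$out_dir, name)
  stage <- function(name, out_file, fun) {
    path <- out_path(out_file)
    if (!force && file.exists(path)) {
      manifest$stages[[name]] <<- "cached"
      return(invisible(TRUE))
    }
    res <- tryCatch({ fun(path); "ok" },
                    error = function(e) paste("error:", conditionMessage(e)))
    manifest$stages[[name]] <<- res
    manifest$outputs[[name]] <<- path
    invisible(identical(res, "ok"))
  }

  ## assemble inputs
  aa <- read_protein_alignment(cfg$protein)
  cds <- read_cds(cfg$cds)
  aln <- build_codon_alignment(aa, cds)
  pm <- read_position_map(cfg$position_map)
  keys <- key_columns(pm)
  state <- new.env()

  ok <- stage("admission", "admission.json", function(path) {
    rt <- pairwise_rate_table(aln)
    adm <- subgroup_admission(rt)
    utils::write.table(round(rt$dN, 4), out_path("dN.tsv"), sep = "\t", quote = FALSE)
    utils::write.table(round(rt$dS, 4), out_path("dS.tsv"), sep = "\t", quote = FALSE)
    state$admission <- adm
    jsonlite::write_json(adm[c("pass", "flags", "members", "removed",
                               "max_dN", "max_dS")],
                         path, auto_unbox = TRUE, digits = NA)
  })

  stage("tree", "tree.nwk", function(path) {
    D <- protein_distance_matrix(aa, model = "JTT-ML")
    state$tree <- neighbor_joining(D)
    ape::write.tree(state$tree, path)
  })
  if (is.null(state$tree) && file.exists(out_path("tree.nwk")))
    state$tree <- ape::read.tree(out_path("tree.nwk"))

  stage("fits", "lrt.json", function(path) {
    res <- site_model_tests(aln, state$tree, tests = cfg$tests,
                            key_columns = keys, codon_freq = cfg$codon_freq,
                            restarts = cfg$restarts, seed = cfg$seed,
                            alpha = cfg$alpha)
    state$fits <- res$fits
    lnls <- lapply(res$fits, function(f)
      list(lnL = f$lnL, np = f$np,
           kappa = if (!is.null(f$mle$kappa)) f$mle$kappa))
    lrts <- lapply(res$lrt, function(x)
      x[c("null", "alt", "Delta", "LR", "df", "p_value", "tenable")])
    jsonlite::write_json(list(seed = cfg$seed, models = lnls, tests = lrts),
                         path, auto_unbox = TRUE, digits = NA)
  })

  stage("profile", "site_report.tsv", function(path) {
    ## the per-site profile comes from M7, or M8 when Test 2 favors it
    use_m8 <- !is.null(state$fits$M8) &&
      !is.null(state$fits$M7) &&
      stats::pchisq(2 * max(state$fits$M8$lnL - state$fits$M7$lnL, 0),
                    df = 2, lower.tail = FALSE) < cfg$alpha
    fit <- if (use_m8) state$fits$M8 else
      if (!is.null(state$fits$M7)) state$fits$M7 else state$fits[[1]]
    state$profile_fit <- fit
    rep <- neb_site_report(fit, position_map = pm)
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("cohorts", "cohorts.json", function(path) {
    prof <- site_omega_profile(state$profile_fit)
    cn <- cohort_null(prof, keys, n_cohorts = cfg$n_cohorts,
                      cohort_size = cfg$cohort_size, seed = cfg$seed)
    state$cohorts <- cn
    jsonlite::write_json(cn[c("omega_key_mean", "random_mean", "random_sd",
                              "z_offset", "outside_2sigma", "ratio",
                              "threshold_flag", "n_cohorts", "cohort_size",
                              "seed")],
                         path, auto_unbox = TRUE, digits = NA)
  })

  stage("diversity", "diversity.json", function(path) {
    dv <- diversity_profile(aa, keys)
    jsonlite::write_json(dv, path, auto_unbox = TRUE, digits = NA)
  })

  manifest$seed <- cfg$seed
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
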