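# Orchestration, configuration and on-disk artifact handling.
#
# Every stage reads only the on-disk outputs of earlier stages, so any
# stage can be re-run in isolation; all randomness flows from one global
# seed through named per-stage substreams (see substream_seed), so
# toggling a stage does not shift other stages' draws.

#' Read a delimited table
#'
#' TSV/CSV chosen by extension; empty fields are missing values;
#' duplicate ids are rejected.
#'
#' @param path file path (`.tsv` or `.csv`).
#' @param id_col column checked for duplicates when present.
#' @return data.frame.
#' @export
read_table <- function(path, id_col = "id") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- as.data.frame(data.table::fread(path, sep = sep, na.strings = "",
                                        header = TRUE, showProgress = FALSE))
  if (id_col %in% names(df) && anyDuplicated(df[[id_col]])) {
    dup <- df[[id_col]][duplicated(df[[id_col]])][1L]
    stop("duplicate ", id_col, " in ", path, ": ", dup)
  }
  df
}

#' Write a delimited table
#'
#' Missing values are written as empty fields; column order preserved.
#'
#' @param table data.frame; `path` destination (`.tsv` or `.csv`).
#' @export
write_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(as.data.frame(table), path, sep = sep, na = "",
                     quote = "auto")
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Produces `participants.tsv`, `metabolites.tsv`, `registry.tsv`,
#' `traits.tsv`, `ground_truth.json` and `config.yaml` (tab-separated,
#' UTF-8, header row, missing values as empty fields).
#'
#' @param bundle a `cohort_bundle`; `dir` output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(bundle$participants, file.path(dir, "participants.tsv"))
  met <- data.frame(id = rownames(bundle$metabolites),
                    bundle$metabolites, check.names = FALSE)
  write_table(met, file.path(dir, "metabolites.tsv"))
  write_table(bundle$registry, file.path(dir, "registry.tsv"))
  if (!is.null(bundle$traits)) write_table(bundle$traits, file.path(dir, "traits.tsv"))
  gt <- serialize_ground_truth(bundle$ground_truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(config_to_list(bundle$ground_truth$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort bundle back from a directory
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_bundle` (ground truth restored from JSON/YAML).
#' @export
read_cohort <- function(dir) {
  participants <- read_table(file.path(dir, "participants.tsv"))
  met <- read_table(file.path(dir, "metabolites.tsv"))
  m <- as.matrix(met[, -1L, drop = FALSE])
  rownames(m) <- met$id
  registry <- read_table(file.path(dir, "registry.tsv"), id_col = "none")
  traits <- if (file.exists(file.path(dir, "traits.tsv")))
    read_table(file.path(dir, "traits.tsv")) else NULL
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth.json")))
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  cfg <- NULL
  if (file.exists(file.path(dir, "config.yaml")))
    cfg <- config_from_list(yaml::read_yaml(file.path(dir, "config.yaml")))
  structure(list(participants = participants, metabolites = m,
                 registry = registry, traits = traits,
                 ground_truth = list(config = cfg, serialized = gt)),
            class = "cohort_bundle")
}

# ---- config (de)serialization ----------------------------------------------

config_to_list <- function(config) {
  if (is.null(config)) return(NULL)
  list(
    n_participants = config$n_participants,
    n_metabolites = config$n_metabolites,
    blocks = lapply(config$blocks, function(b) list(size = b[[1L]], rho = b[[2L]])),
    diseases = lapply(config$diseases, function(d) {
      out <- unclass(d)
      if (!is.null(out$effect_metabolites))
        out$effect_metabolites <- as.list(out$effect_metabolites)
      out
    }),
    traits = lapply(config$traits, function(t) {
      out <- unclass(t)
      if (!is.null(out$effect_metabolites))
        out$effect_metabolites <- as.list(out$effect_metabolites)
      out
    }),
    waves = config$waves,
    age_slopes = config$age_slopes,
    log_scale_sd = config$log_scale_sd,
    follow_up_horizon = config$follow_up_horizon,
    n_centres = config$n_centres,
    missingness = config$missingness,
    include_egfr = config$include_egfr,
    seed = config$seed)
}

config_from_list <- function(lst) {
  diseases <- lapply(lst$diseases, function(d) {
    em <- if (!is.null(d$effect_metabolites))
      data.frame(metabolite = unlist(d$effect_metabolites$metabolite),
                 effect = unlist(d$effect_metabolites$effect)) else NULL
    dv <- d$divergence
    disease_spec(d$disease_id, d$mode, d$prevalence_prevalent,
                 d$incidence_scale, em, dv)
  })
  traits <- lapply(lst$traits, function(t) {
    em <- if (!is.null(t$effect_metabolites))
      data.frame(metabolite = unlist(t$effect_metabolites$metabolite),
                 effect = unlist(t$effect_metabolites$effect)) else NULL
    trait_spec(t$trait_id, t$kind, em, t$n_ordinal_levels %||% 4L,
               t$noise_sd %||% 1, t$intercept %||% 0)
  })
  simulation_config(
    n_participants = lst$n_participants,
    n_metabolites = lst$n_metabolites %||% 313L,
    blocks = lapply(lst$blocks, function(b) c(b$size, b$rho)),
    diseases = diseases, traits = traits,
    waves = lst$waves %||% list(),
    age_slopes = unlist(lst$age_slopes),
    log_scale_sd = lst$log_scale_sd %||% 0.3,
    follow_up_horizon = lst$follow_up_horizon %||% 15,
    n_centres = lst$n_centres %||% 22L,
    missingness = lst$missingness %||% 0.02,
    include_egfr = isTRUE(lst$include_egfr),
    seed = lst$seed %||% 1L)
}

serialize_ground_truth <- function(gt) {
  list(config = config_to_list(gt$config),
       realized = lapply(gt$realized, function(r) {
         if (!is.null(r$spec)) r$spec <- unclass(r$spec)
         r
       }))
}

# ---- pipeline configuration -------------------------------------------------

PIPELINE_KEYS <- c("stages", "out_dir", "seed", "covariates", "include_egfr",
                   "simulate", "scan", "preonset", "ageing", "metrs")

#' Validate a pipeline configuration list
#'
#' Unknown top-level keys are rejected; defaults are resolved so the run
#' log contains the value of every parameter.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]).
#' @return the resolved config.
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    stages = c("simulate", "preprocess", "scan", "preonset", "ageing", "metrs"),
    seed = 1L,
    covariates = DEFAULT_COVARIATES,
    include_egfr = FALSE,
    simulate = list(n_participants = 2000L, n_metabolites = 20L),
    scan = list(alpha = 0.05, min_cases = 300L),
    preonset = list(bins = 15L, ratio = 5L, alpha = 0.05, min_cases_per_bin = 10L),
    ageing = list(width = 3, span = 0.75,
                  q_thresholds = c(1e-4, 1e-3, 1e-2, 5e-2)),
    metrs = list(k = 10L, top_k = 30L, B = 200L))
  for (k in names(defaults)) {
    config[[k]] <- if (is.list(defaults[[k]]) && !is.null(config[[k]]))
      modifyList(defaults[[k]], config[[k]]) else config[[k]] %||% defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  config
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, scan,
#' preonset, ageing, metrs). Each stage consumes only on-disk outputs of
#' prior stages and writes its own artifacts under `out_dir`. A manifest
#' with checksums, the resolved configuration and the run log are stored
#' with the run.
#'
#' @param config pipeline config list (see
#'   [validate_pipeline_config()]); may also be a path to a YAML file.
#' @param quiet suppress progress messages.
#' @return `run_artifacts` list: `manifest` (file, md5), `config`,
#'   `log`, `version`, `seed`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log <- c(sprintf("metaphenome %s", as.character(utils::packageVersion("metaphenome"))),
           sprintf("seed: %d", seed),
           sprintf("resolved config: %s",
                   jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  stage_on <- function(s) s %in% config$stages
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing prerequisite artifact ", path, "; run stage '", stage, "' first")
    path
  }

  if (stage_on("simulate")) {
    say("stage simulate")
    sim <- config$simulate
    cfg <- simulation_config(
      n_participants = sim$n_participants,
      n_metabolites = sim$n_metabolites %||% 20L,
      blocks = lapply(sim$blocks %||% list(), function(b) c(b$size %||% b[[1]], b$rho %||% b[[2]])),
      diseases = if (!is.null(sim$diseases)) sim$diseases else default_demo_diseases(),
      traits = if (!is.null(sim$traits)) sim$traits else default_demo_traits(),
      waves = sim$waves %||% list(),
      follow_up_horizon = sim$follow_up_horizon %||% 15,
      missingness = sim$missingness %||% 0.02,
      include_egfr = isTRUE(config$include_egfr),
      seed = substream_seed(seed, "simulate"))
    bundle <- simulate_cohort(cfg)
    write_cohort(bundle, file.path(out_dir, "cohort"))
  }

  if (stage_on("preprocess")) {
    say("stage preprocess")
    bundle <- read_cohort(need(file.path(out_dir, "cohort"), "simulate"))
    qc <- qc_transform(bundle$metabolites)
    imp <- impute_covariates(bundle$participants)
    zdf <- data.frame(id = rownames(qc$z), qc$z, check.names = FALSE)
    write_table(zdf, file.path(out_dir, "metabolites_z.tsv"))
    write_table(imp$covariates, file.path(out_dir, "covariates_imputed.tsv"))
    corr <- correlation_matrix(qc$z)
    write_table(data.frame(metabolite = rownames(corr), corr, check.names = FALSE),
                file.path(out_dir, "metabolite_correlation.tsv"))
    jsonlite::write_json(
      list(n_outliers = vapply(qc$report$metabolites, function(r) r$n_outliers, numeric(1)),
           imputation = lapply(imp$report$covariates, function(r)
             r[c("covariate", "stratum", "fill", "n_filled")])),
      file.path(out_dir, "transform_report.json"), auto_unbox = TRUE, digits = NA)
  }

  z <- NULL; cov_imp <- NULL; bundle <- NULL
  load_stage_inputs <- function() {
    zdf <- read_table(need(file.path(out_dir, "metabolites_z.tsv"), "preprocess"))
    z <<- as.matrix(zdf[, -1L, drop = FALSE]); rownames(z) <<- zdf$id
    cov_imp <<- read_table(need(file.path(out_dir, "covariates_imputed.tsv"), "preprocess"))
    bundle <<- read_cohort(need(file.path(out_dir, "cohort"), "simulate"))
  }

  if (stage_on("scan")) {
    say("stage scan")
    load_stage_inputs()
    cn <- config$covariates
    if (isTRUE(config$include_egfr)) cn <- union(cn, "egfr")
    all_rec <- list()
    for (kind in c("prevalent", "incident")) {
      sets <- build_analysis_sets(bundle$registry, bundle$participants$id,
                                  kind = kind, min_cases = config$scan$min_cases)
      all_rec[[kind]] <- scan_associations(z, sets, cov_imp,
                                           registry = bundle$registry,
                                           covariate_names = cn,
                                           alpha = config$scan$alpha)
    }
    if (!is.null(bundle$traits) && ncol(bundle$traits) > 1L) {
      tk <- trait_kinds_from_truth(bundle)
      sets <- build_analysis_sets(kind = "traits", traits = bundle$traits,
                                  trait_kinds = tk,
                                  trait_min_n = min(10000L, nrow(bundle$participants)),
                                  binary_min_cell = 50L)
      all_rec$traits <- scan_associations(z, sets, cov_imp, traits = bundle$traits,
                                          covariate_names = cn,
                                          alpha = config$scan$alpha)
    }
    write_table(do.call(rbind, c(all_rec, make.row.names = FALSE)),
                file.path(out_dir, "associations.tsv"))
  }

  if (stage_on("preonset")) {
    say("stage preonset")
    if (is.null(z)) load_stage_inputs()
    pc <- config$preonset
    sets <- build_analysis_sets(bundle$registry, bundle$participants$id,
                                kind = "incident", min_cases = config$scan$min_cases)
    profs <- list(); calls <- list(); msets <- list()
    for (s in Filter(function(s) isTRUE(s$included), sets)) {
      reg <- bundle$registry
      inc <- reg[reg$disease_id == s$id & reg$status == "incident", ]
      cases <- cov_imp[match(inc$id, cov_imp$id), , drop = FALSE]
      cases$time_to_onset <- inc$onset_time
      pool <- cov_imp[match(s$controls, cov_imp$id), , drop = FALSE]
      matched <- propensity_match(cases, pool, ratio = pc$ratio,
                                  seed = substream_seed(seed, paste0("match_", s$id)))
      msets[[s$id]] <- cbind(disease_id = s$id, matched)
      prof <- timeframe_profile(matched, z, cov_imp, disease_id = s$id,
                                bins = pc$bins,
                                min_cases_per_bin = pc$min_cases_per_bin)
      profs[[s$id]] <- prof
      calls[[s$id]] <- do.call(rbind, lapply(split(prof, prof$metabolite_id),
        function(pm) {
          ec <- tryCatch(backward_screen(pm, alpha = pc$alpha),
                         error = function(e) NULL)
          if (is.null(ec)) return(NULL)
          data.frame(disease_id = s$id, metabolite_id = pm$metabolite_id[1L],
                     emergence_bin = ec$emergence_bin %||% NA_integer_,
                     convention = ec$convention)
        }))
    }
    write_table(do.call(rbind, c(msets, make.row.names = FALSE)),
                file.path(out_dir, "matched_sets.tsv"))
    prof_all <- do.call(rbind, c(profs, make.row.names = FALSE))
    write_table(prof_all, file.path(out_dir, "timeframe_profiles.tsv"))
    write_table(do.call(rbind, c(calls, make.row.names = FALSE)),
                file.path(out_dir, "emergence_calls.tsv"))
    if (length(profs) >= 3L) {
      cl <- cluster_trajectories(prof_all)
      write_table(data.frame(disease_id = names(cl$labels), cluster = cl$labels),
                  file.path(out_dir, "clusters.tsv"))
    } else say("preonset clustering skipped: fewer than 3 profiled diseases")
  } else say("stage preonset skipped; emergence tables not produced")

  if (stage_on("ageing")) {
    say("stage ageing")
    if (is.null(z)) load_stage_inputs()
    ac <- age_adjusted_curves(z, cov_imp, span = config$ageing$span)
    write_table(data.frame(metabolite_id = rownames(ac$curves), ac$curves,
                           check.names = FALSE),
                file.path(out_dir, "age_curves.tsv"))
    cl <- cluster_age_curves(ac)
    write_table(data.frame(metabolite_id = names(cl$labels), cluster = cl$labels),
                file.path(out_dir, "age_clusters.tsv"))
    dw <- deswan_scan(z, cov_imp, width = config$ageing$width,
                      q_thresholds = config$ageing$q_thresholds)
    write_table(dw$long, file.path(out_dir, "deswan_long.tsv"))
    write_table(data.frame(centre = dw$centres, dw$counts, check.names = FALSE),
                file.path(out_dir, "deswan_counts.tsv"))
    pk <- detect_wave_peaks(dw)
    jsonlite::write_json(pk, file.path(out_dir, "peaks.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (stage_on("metrs")) {
    say("stage metrs")
    if (is.null(z)) load_stage_inputs()
    mc <- config$metrs
    sets <- build_analysis_sets(bundle$registry, bundle$participants$id,
                                kind = "prevalent", min_cases = config$scan$min_cases)
    evals <- list(); panels <- list()
    for (s in Filter(function(s) isTRUE(s$included), sets)) {
      ids <- intersect(c(s$cases, s$controls), rownames(z))
      y <- as.integer(ids %in% s$cases)
      ctr <- cov_imp$centre[match(ids, cov_imp$id)]
      res <- metrs_cv(z[ids, , drop = FALSE], y, ctr,
                      k = mc$k, top_k = min(mc$top_k, ncol(z)), B = mc$B,
                      seed = substream_seed(seed, paste0("metrs_", s$id)))
      panels[[s$id]] <- data.frame(disease_id = s$id,
                                   metabolite_id = res$panel,
                                   mean_rank = res$mean_rank[res$panel])
      evals[[s$id]] <- data.frame(disease_id = s$id, auc = res$report$auc,
                                  ci_lo = res$report$ci[1L],
                                  ci_hi = res$report$ci[2L])
    }
    if (length(panels)) {
      write_table(do.call(rbind, c(panels, make.row.names = FALSE)),
                  file.path(out_dir, "metrs_panels.tsv"))
      write_table(do.call(rbind, c(evals, make.row.names = FALSE)),
                  file.path(out_dir, "metrs_eval.tsv"))
    } else say("metrs skipped: no disease met the case threshold")
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run\\.log$|manifest\\.json$", files)]
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), digits = NA)
  writeLines(log, file.path(out_dir, "run.log"))
  structure(list(manifest = manifest, config = config, log = log,
                 version = as.character(utils::packageVersion("metaphenome")),
                 seed = seed),
            class = "run_artifacts")
}

trait_kinds_from_truth <- function(bundle) {
  tk <- c()
  cfg <- bundle$ground_truth$config
  if (!is.null(cfg)) {
    for (t in cfg$traits) tk[t$trait_id] <- t$kind
  }
  # fall back to type sniffing for traits without a recorded spec
  for (tr in setdiff(names(bundle$traits), c("id", names(tk)))) {
    x <- bundle$traits[[tr]]
    u <- unique(x[!is.na(x)])
    tk[tr] <- if (length(u) == 2L) "binary"
              else if (length(u) <= 8L && all(u == round(u))) "ordinal"
              else "continuous"
  }
  tk
}

default_demo_diseases <- function() {
  list(
    disease_spec("D_hazard", "hazard_driven", prevalence_prevalent = 0.05,
                 incidence_scale = 0.01,
                 effect_metabolites = data.frame(metabolite = 1:2,
                                                 effect = c(0.4, -0.3))),
    disease_spec("D_diverge", "divergence_driven", prevalence_prevalent = 0.03,
                 incidence_scale = 0.02,
                 divergence = list(metabolite = 3L, emergence_time = 8,
                                   shift = 0.8, ramp = "linear")),
    disease_spec("D_null", "null", prevalence_prevalent = 0.05,
                 incidence_scale = 0.015))
}

default_demo_traits <- function() {
  list(
    trait_spec("trait_cont", "continuous",
               effect_metabolites = data.frame(metabolite = 1L, effect = 0.3)),
    trait_spec("trait_bin", "binary", intercept = qlogis(0.3)),
    trait_spec("trait_ord", "ordinal", n_ordinal_levels = 4L))
}
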