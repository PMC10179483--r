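#' Assemble a full run configuration
#'
#' Bundles every stage's settings behind one global seed. The seed is fanned
#' out to the stochastic stages (simulation, classification folds,
#' regression splits) through [child_seed()] with fixed stage labels, so
#' inserting a stage never reshuffles the randomness of the others.
#'
#' @param out_dir output directory (created by [run_pipeline()]).
#' @param seed global integer seed.
#' @param design a `cc_design`.
#' @param params a `cc_params`; its seed is overridden from `seed`.
#' @param cv classification [cv_protocol()]; seed overridden from `seed`.
#' @param reg [regression_protocol()]; seed overridden from `seed`.
#' @param feature_set `"paper-text"` or `"table-caption"`.
#' @param organs organs to model.
#' @param label_q labelling percentile for classification.
#' @param heatmaps write per-stratum heatmap PNGs (default TRUE).
#' @return a `cc_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 42L, design = default_design(),
                            params = sim_params(), cv = cv_protocol(),
                            reg = regression_protocol(),
                            feature_set = "paper-text",
                            organs = c("liver", "spleen", "heart"),
                            label_q = 70, heatmaps = TRUE) {
  params$seed <- child_seed(seed, "simulate")
  cv$seed <- child_seed(seed, "classify")
  reg$seed <- child_seed(seed, "regress")
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 params = params, cv = cv, reg = reg,
                 feature_set = feature_set, organs = organs,
                 label_q = label_q, heatmaps = heatmaps),
            class = "cc_config")
}

config_echo <- function(config) {
  list(seed = config$seed,
       n_designed = sum(config$design$group_sizes$n),
       lines = config$design$lines,
       weeks = config$design$weeks,
       ipgtt_weeks = config$design$ipgtt_weeks,
       auc_window_min = range(config$design$ipgtt_timepoints_min),
       cv_folds = config$cv$k,
       cv_stratified = config$cv$stratified,
       regression_iterations = config$reg$iterations,
       regression_train_frac = config$reg$train_frac,
       label_percentile = config$label_q,
       feature_set = config$feature_set,
       organs = config$organs,
       sim_seed = config$params$seed,
       cv_seed = config$cv$seed,
       reg_seed = config$reg$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_echo(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full study pipeline on synthetic data
#'
#' One-command replica of the complete analysis: simulate the cohort at the
#' configured design, derive traits, estimate heritability/CVg per stratum,
#' compute correlation matrices (and heatmaps), run all diet contrasts, and
#' fit the per-line classification and regression grids for every organ.
#' All tabular outputs are CSV, model grids JSON, figures PNG; a
#' `manifest.json` records the configuration echo (protocol constants
#' exactly as configured), the config hash, per-stage row counts and the
#' md5 of every output file. Reruns with the same config produce
#' byte-identical numeric outputs.
#'
#' @param config a `cc_config` from [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cc_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package = "ccorganotrait",
                   version = as.character(packageVersion("ccorganotrait")),
                   config = config_echo(config),
                   config_hash = config_hash(config),
                   complete = FALSE, stages = list(), outputs = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  stage <- function(name, expr) {
    log_stage(name, "start")
    tryCatch(expr, error = function(e) {
      manifest$complete <<- FALSE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  done <- function(name, rows, files = character(0)) {
    manifest$stages[[name]] <<- list(status = "ok", rows = rows)
    for (f in files)
      manifest$outputs[[basename(f)]] <<- list(md5 = unname(tools::md5sum(f)),
                                               config_hash = manifest$config_hash)
    log_stage(name, "done (%d rows)", rows)
  }

  cohort <- stage("simulate", {
    co <- generate_cohort(config$design, config$params)
    write_cohort(co, path("cohort.csv"))
    co
  })
  done("simulate", nrow(cohort), path("cohort.csv"))

  traits <- stage("traits", {
    tr <- derive_traits(cohort)
    write.csv(tr, path("traits.csv"), row.names = FALSE, quote = FALSE)
    tr
  })
  done("traits", nrow(traits), path("traits.csv"))

  h2 <- stage("heritability", {
    h <- heritability_table(traits)
    write.csv(h, path("h2_table.csv"), row.names = FALSE, quote = FALSE)
    h
  })
  done("heritability", nrow(h2), path("h2_table.csv"))

  ratios <- stage("delta_ratios", {
    r <- group_delta_ratio_table(traits)
    write.csv(r, path("delta_ratios.csv"), row.names = FALSE, quote = FALSE)
    r
  })
  done("delta_ratios", nrow(ratios), path("delta_ratios.csv"))

  corr_files <- character(0)
  corr <- stage("correlate", {
    rows <- list()
    tcols <- c("bw0_g", "bw_final_g", "dbw_g",
               grep("^auc_wk", names(traits), value = TRUE),
               "liver_g", "spleen_g", "heart_g",
               "pct_liver", "pct_spleen", "pct_heart")
    tcols <- intersect(tcols, names(traits))
    for (sx in sort(unique(traits$sex))) {
      for (dt in sort(unique(traits$diet))) {
        cm <- pearson_matrix(traits, sex = sx, diet = dt, trait_cols = tcols)
        if (isTRUE(config$heatmaps) && capabilities("png")) {
          f <- path(sprintf("heatmap_%s_%s.png", sx, dt))
          render_heatmap(cm, f)
          corr_files <- c(corr_files, f)
        }
        k <- length(tcols)
        idx <- which(upper.tri(cm$r, diag = TRUE), arr.ind = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, diet = dt,
          trait_i = tcols[idx[, 1L]], trait_j = tcols[idx[, 2L]],
          r = cm$r[idx], n = cm$n[idx], flag = cm$flags[idx],
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, path("correlations.csv"), row.names = FALSE, quote = FALSE)
    tab
  })
  done("correlate", nrow(corr), c(path("correlations.csv"), corr_files))

  contrasts <- stage("contrast", {
    ct <- contrast_table(traits)
    write.csv(ct, path("contrasts.csv"), row.names = FALSE, quote = FALSE)
    ct
  })
  done("contrast", nrow(contrasts), path("contrasts.csv"))

  for (organ in config$organs) {
    for (task in c("classify", "regress")) {
      nm <- sprintf("%s_%s", task, organ)
      grid <- stage(nm, {
        g <- model_grid(traits, organ, task, cv = config$cv, reg = config$reg,
                        feature_set = config$feature_set,
                        label_q = config$label_q)
        f <- path(sprintf("%s.json", nm))
        jsonlite::write_json(
          list(organ = organ, task = task,
               protocol = if (task == "classify") unclass(config$cv) else unclass(config$reg),
               feature_set = config$feature_set,
               label_percentile = config$label_q,
               config_hash = manifest$config_hash,
               grid = as.data.frame(g)),
          f, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
        g
      })
      done(nm, nrow(grid), path(sprintf("%s.json", nm)))
    }
  }

  manifest$complete <- TRUE
  flush_manifest()
  log_stage("pipeline", "complete: %s", config$out_dir)
  invisible(manifest)
}
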