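#' Pipeline configuration
#'
#' Describes a full synthetic run: which stages to execute and the
#' per-module parameters. Stages run in dependency order:
#' `simulate` -> `train` -> `predict` -> `gompertz` / `resilience` /
#' `stats`. All randomness derives from `seed`.
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param stages Character vector of stages to run.
#' @param seed Global integer seed.
#' @param n_subjects,n_days Cohort size and series length for `simulate`.
#' @param sim Optional list of [sim_config()] overrides.
#' @param encoder_profile `"test"` or `"full"` encoder size.
#' @param train Optional list of [train_config()] overrides.
#' @param resilience_n_subjects,resilience_n_days Size of the longitudinal
#'   resilience cohort.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "actiage_run",
                            stages = c("simulate", "train", "predict",
                                       "gompertz", "resilience", "stats"),
                            seed = 1L,
                            n_subjects = 300, n_days = 7,
                            sim = list(),
                            encoder_profile = "test",
                            train = list(),
                            resilience_n_subjects = 400,
                            resilience_n_days = 365) {
  known <- c("simulate", "train", "predict", "gompertz", "resilience", "stats")
  stopifnot(all(stages %in% known))
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
                 sim = sim, encoder_profile = encoder_profile, train = train,
                 resilience_n_subjects = as.integer(resilience_n_subjects),
                 resilience_n_days = as.integer(resilience_n_days)),
            class = "pipeline_config")
}

#' Run the synthetic pipeline
#'
#' Executes the requested stages in dependency order, writing artifacts as
#' CSV under `config$out_dir` and a JSON manifest recording package version,
#' seeds, parameter hashes, and per-stage wall time. Reruns with an
#' identical config reproduce stochastic stages bit-identically. A stage
#' failure halts downstream stages; partial outputs keep a `.partial`
#' suffix.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return The manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(
    package = "actiage",
    version = as.character(utils::packageVersion("actiage")),
    seed = config$seed,
    stages = list()
  )
  art <- function(name) file.path(config$out_dir, name)
  scfg <- do.call(sim_config, utils::modifyList(
    list(n_subjects = config$n_subjects, seed = config$seed), config$sim))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              "; downstream stages skipped")
      # all writes are atomic (temp + rename), so on-disk artifacts from
      # completed stages remain intact; leftover temp files mark partials
      for (f in list.files(config$out_dir, pattern = "\\.tmp$",
                           full.names = TRUE)) {
        file.rename(f, sub("\\.tmp$", ".partial", f))
      }
      FALSE
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      ok = ok)
    if (!ok) stop("pipeline halted at stage '", name, "'", call. = FALSE)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    cohort <- simulate_cohort(scfg)
    series <- lapply(seq_len(nrow(cohort)), function(i)
      simulate_step_series(cohort[i, ], config$n_days, scfg,
                           seed = scfg$seed + 1000L + i))
    names(series) <- cohort$id
    write_cohort(cohort, art("cohort.csv"))
    write_step_series(series, art("steps.csv"))
    state$cohort <- cohort
    state$series <- series
  })

  load_inputs <- function() {
    if (is.null(state$cohort)) state$cohort <- read_cohort(art("cohort.csv"))
    if (is.null(state$series)) state$series <- read_step_series(art("steps.csv"))
  }

  run_stage("train", function() {
    load_inputs()
    ecfg <- encoder_config(profile = config$encoder_profile)
    tcfg <- do.call(train_config, utils::modifyList(
      list(seed = config$seed,
           iterations = if (config$encoder_profile == "test") 200L else 2000L,
           batch_size = if (config$encoder_profile == "test") 64L else 256L,
           learning_rate = if (config$encoder_profile == "test") 1e-2 else 1e-3,
           adapt_batch = if (config$encoder_profile == "test") 12L else 32L),
      config$train))
    model <- baa_model_init(ecfg, seed = config$seed)
    model <- train_baa_model(state$cohort, state$series, model, tcfg)
    state$model <- model
    atomic_write(function(p) saveRDS(model, p), art("model.rds"))
    atomic_write(function(p)
      utils::write.csv(model$training_log, p, row.names = FALSE),
      art("training_log.csv"))
  })

  run_stage("predict", function() {
    load_inputs()
    if (is.null(state$model)) state$model <- readRDS(art("model.rds"))
    pred <- predict_cohort(state$cohort, state$series, state$model)
    state$pred <- pred
    atomic_write(function(p) utils::write.csv(pred, p, row.names = FALSE),
                 art("predictions.csv"))
  })

  run_stage("gompertz", function() {
    load_inputs()
    tab <- group_life_expectancy(state$cohort, "occupation")
    atomic_write(function(p) utils::write.csv(tab, p, row.names = FALSE),
                 art("life_expectancy.csv"))
  })

  run_stage("resilience", function() {
    n <- config$resilience_n_subjects
    set.seed(config$seed + 7L)
    ages <- stats::runif(n, scfg$age_range[1], scfg$age_range[2])
    est <- do.call(rbind, lapply(seq_len(n), function(i) {
      tau <- draw_relaxation_time(ages[i], scfg, seed = config$seed + 10L + i)
      tr <- simulate_baa_track(ages[i], config$resilience_n_days, tau,
                               seed = config$seed + 20000L + i)
      r <- tryCatch(estimate_resilience(tr), error = function(e) NULL)
      data.frame(age = ages[i], tau_true = tau,
                 tau = if (is.null(r)) 0 else r$tau,
                 rate = if (is.null(r)) NA_real_ else r$rate,
                 unresolved = is.null(r))
    }))
    ok <- est[!est$unresolved & is.finite(est$rate), ]
    mpb <- max(5L, n %/% 20L)    # scale the per-bin minimum with cohort size
    trend <- cohort_recovery_trend(ok, n_boot = 100, min_per_bin = mpb)
    # small cohorts may legitimately contain no non-resilient subjects;
    # report the fractions as absent rather than failing the stage
    frac <- tryCatch(nonresilient_fraction(est, min_per_bin = mpb),
                     error = function(e) NULL)
    atomic_write(function(p) utils::write.csv(est, p, row.names = FALSE),
                 art("resilience_subjects.csv"))
    if (is.null(frac)) {
      summary_df <- trend$bins
      summary_df$fraction <- NA_real_
      summary_df$alpha <- NA_real_
    } else {
      summary_df <- merge(trend$bins, frac$bins, by = "age", all = TRUE)
      summary_df$alpha <- frac$alpha
    }
    summary_df$zero_crossing_age <- trend$zero_crossing_age
    atomic_write(function(p) utils::write.csv(summary_df, p, row.names = FALSE),
                 art("resilience_summary.csv"))
  })

  run_stage("stats", function() {
    load_inputs()
    if (is.null(state$pred)) {
      if (file.exists(art("predictions.csv"))) {
        state$pred <- utils::read.csv(art("predictions.csv"))
      } else {
        stop("stats stage needs predictions; enable the predict stage")
      }
    }
    df <- merge(state$cohort, state$pred, by = "id")
    cmp <- suppressWarnings(mannwhitney_fisher(
      df$baa[df$morbid], df$baa[!df$morbid], seed = config$seed))
    report <- list(metric = "baa", by = "morbid",
                   p_combined = cmp$p_combined,
                   p_quantiles = as.list(stats::quantile(cmp$p_values,
                                                         c(0.25, 0.5, 0.75))),
                   n_a = cmp$n_a, n_b = cmp$n_b,
                   degenerate = cmp$degenerate, seed = cmp$seed)
    atomic_write(function(p)
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA),
      art("group_comparison.json"))
  })

  manifest$config_hash <- config_hash(config)
  atomic_write(function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE),
    art("manifest.json"))
  say("pipeline complete: ", config$out_dir)
  invisible(manifest)
}

# stable hash of the configuration (md5 of its serialized form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
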