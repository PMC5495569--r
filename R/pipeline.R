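#' Default run configuration
#'
#' @param ... Overrides of the default fields.
#' @return Named list: `preset`, `alignment`, `n_rats`, `phenotypes` (named
#'   counts summing to `n_units`), `baseline_rate_hz`, `modulation`,
#'   `alpha`, `latency_z`, `r_threshold`, `unstable_frac` (fraction of units
#'   given template drift below the stability gate), `seed`, `out_dir`.
#' @export
default_config <- function(...) {
  cfg <- list(preset = "recording", alignment = "pip", n_rats = 4,
              phenotypes = c(fear = 2, extinction = 2, session_selective = 1,
                             non_responsive = 5),
              baseline_rate_hz = 5, modulation = 10, alpha = 0.05,
              latency_z = 3, r_threshold = 0.97, unstable_frac = 0,
              seed = 1, out_dir = NULL)
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite).
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$phenotypes)) raw$phenotypes <- unlist(raw$phenotypes)
  do.call(default_config, raw)
}

#' Run a complete simulated experiment end to end
#'
#' Simulate -> score freezing -> recall groups -> unit QC -> z-PETH ->
#' responsiveness profiles -> neuron typing -> composition -> statistics,
#' with planted ground truth carried through for validation.  The bundle is
#' a pure function of `(config, seed)`; every unit dropped by the stability
#' gate is logged with a reason code, and per-stage in/out counts are
#' recorded.
#'
#' @param config From [default_config()] / [read_config()].
#' @param verbose Emit per-stage progress on stderr (default FALSE).
#' @return List of class `run_bundle`: `plan`, `freezing`, `groups`,
#'   `unit_qc`, `profiles`, `types` (data frame with planted and recovered
#'   labels), `composition`, `stats`, `stage_log`.  When `config$out_dir` is
#'   set the tables are also written there as TSV/JSON.
#' @export
run_experiment <- function(config = default_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(sum(config$phenotypes) >= 1, config$n_rats >= 1)
  seed <- config$seed
  plan <- make_session_plan(config$preset, list(alignment = config$alignment))
  stage_log <- list()
  log_stage <- function(stage, n_in, n_out, note = "") {
    stage_log[[length(stage_log) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, note = note,
      stringsAsFactors = FALSE)
  }

  ## rats: shared event schedules and freezing traces
  say("simulating %d rats", config$n_rats)
  rat_ids <- sprintf("rat%02d", seq_len(config$n_rats))
  events_by_rat <- lapply(rat_ids, function(rid) {
    generate_events(plan, substream_seed(seed, "rat", rid))
  })
  names(events_by_rat) <- rat_ids
  movement <- do.call(rbind, lapply(seq_along(rat_ids), function(i) {
    grp <- if (i <= ceiling(config$n_rats * 0.75)) "successful" else "poor"
    simulate_freezing(default_rat_params(rat_ids[i], grp), plan,
                      substream_seed(seed, "freeze", rat_ids[i]))
  }))
  freezing <- score_freezing_table(movement, plan)
  groups <- assign_recall_groups(post_ext1_freezing(freezing, plan))
  log_stage("freezing", nrow(movement), nrow(freezing))

  ## units: simulate, QC, profile, classify
  pheno <- rep(names(config$phenotypes), config$phenotypes)
  n_units <- length(pheno)
  say("simulating %d units", n_units)
  unit_ids <- sprintf("unit%03d", seq_len(n_units))
  unit_rat <- rat_ids[(seq_len(n_units) - 1) %% config$n_rats + 1]
  n_unstable <- round(config$unstable_frac * n_units)
  qc_rows <- list(); prof_rows <- list(); type_rows <- list()
  for (i in seq_len(n_units)) {
    uid <- unit_ids[i]
    spec <- make_neuron_spec(uid, pheno[i], plan,
                             baseline_rate_hz = config$baseline_rate_hz,
                             modulation = config$modulation,
                             target_session = if (pheno[i] == "session_selective") "Ext3")
    drift <- if (i <= n_unstable) 0.6 else 0.01
    sim <- simulate_unit(spec, plan, substream_seed(seed, "unit", uid),
                         events = events_by_rat[[unit_rat[i]]],
                         wf_drift = drift)
    st <- template_stability(sim$waveforms, config$r_threshold)
    qc_rows[[i]] <- data.frame(unit_id = uid, rat_id = unit_rat[i],
                               min_r = st$min_r, stable = st$stable,
                               reason = st$reason %||%
                                 if (st$stable) "" else "template_drift",
                               stringsAsFactors = FALSE)
    if (!st$stable) next
    prof <- build_profile(sim$spikes, events_by_rat[[unit_rat[i]]], plan,
                          alpha = config$alpha, unit_id = uid)
    cls <- classify_neuron(prof)
    prof_rows[[i]] <- prof
    type_rows[[i]] <- data.frame(unit_id = uid, planted = pheno[i],
                                 label = cls$label,
                                 selective_epoch = cls$selective_epoch %||% NA,
                                 stringsAsFactors = FALSE)
  }
  unit_qc <- do.call(rbind, qc_rows)
  profiles <- do.call(rbind, prof_rows)
  types <- do.call(rbind, type_rows)
  log_stage("stability_gate", n_units, sum(unit_qc$stable),
            sprintf("%d dropped (r <= %g)", n_units - sum(unit_qc$stable),
                    config$r_threshold))
  composition <- cohort_summary(types$label, n_recorded = n_units)

  ## statistics over the surviving population
  stats_out <- list()
  ep_names <- recall_epochs(plan)$epoch
  zmat <- if (!is.null(profiles)) {
    m <- matrix(profiles$mean_window_z,
                ncol = length(ep_names), byrow = TRUE,
                dimnames = list(unique(profiles$unit_id), ep_names))
    m[stats::complete.cases(m), , drop = FALSE]
  }
  for (lab in c("fear", "extinction")) {
    u <- types$unit_id[types$label == lab]
    if (length(u) >= 2) {
      sub <- zmat[rownames(zmat) %in% u, , drop = FALSE]
      stats_out[[paste0(lab, "_friedman")]] <- friedman_test(sub)
      stats_out[[paste0(lab, "_dunn")]] <- dunn_bky(sub, "repeated")
    }
  }
  fz <- tapply(freezing$freezing_pct,
               list(freezing$rat_id, freezing$session), mean)
  stats_out$freezing_friedman <- friedman_test(fz)
  if (!is.null(zmat) && nrow(zmat) >= 2) {
    stats_out$population_rm_anova <- rm_anova1(zmat)
  }
  log_stage("stats", length(stats_out), length(stats_out))

  bundle <- structure(list(plan = plan, freezing = freezing, groups = groups,
                           unit_qc = unit_qc, profiles = profiles,
                           types = types, composition = composition,
                           stats = stats_out,
                           stage_log = do.call(rbind, stage_log),
                           config = config),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a run bundle as TSV/JSON files
#'
#' @param bundle A `run_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$freezing, file.path(dir, "freezing.tsv"))
  write_tsv(bundle$groups, file.path(dir, "groups.tsv"))
  write_tsv(bundle$unit_qc, file.path(dir, "unit_qc.tsv"))
  if (!is.null(bundle$profiles)) {
    write_tsv(bundle$profiles, file.path(dir, "profiles.tsv"))
  }
  if (!is.null(bundle$types)) {
    write_tsv(bundle$types, file.path(dir, "types.tsv"))
  }
  write_tsv(bundle$stage_log, file.path(dir, "stage_log.tsv"))
  jsonlite::write_json(bundle$composition, file.path(dir, "composition.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  stats_flat <- lapply(bundle$stats, function(s) {
    if (inherits(s, "test_result")) {
      list(method = s$method, statistic = s$statistic, df = s$df,
           p_value = s$p_value, n = s$n)
    } else s
  })
  jsonlite::write_json(stats_flat, file.path(dir, "stats.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
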