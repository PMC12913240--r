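#' Study configuration
#'
#' Bundles every stage's settings for a full synthetic study (generate ->
#' simulate -> preprocess -> cluster statistics -> individual sensitivity ->
#' sensor x epoch sweep). A single `master_seed` is fanned out
#' deterministically to per-stage, per-participant streams, so re-running
#' the same configuration reproduces every number exactly.
#'
#' @param paradigm A [paradigm_config()].
#' @param n_participants Cohort size (30 in the published study).
#' @param between_subject_sd Between-participant amplitude SD (fraction).
#' @param noise An [noise_spec()].
#' @param alpha,n_perm Cluster-test level and permutation count.
#' @param cluster_hat Variance-regularization fraction for the cluster t
#'   maps (see [paired_t_map()]); 0 = plain paired t.
#' @param n_blocks,n_iter Block count and permutation-framework iterations
#'   for the sensitivity analysis.
#' @param sweep_n_repeats,sweep_n_boot Sweep CV repetitions and bootstrap
#'   replicates.
#' @param contrasts Contrast names to analyze.
#' @param components_active,components_passive Optional component-table
#'   overrides (defaults: [build_default_components()] per condition).
#' @param master_seed Integer master seed.
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @return An `lg_study_config` list.
#' @export
study_config <- function(paradigm = paradigm_config(),
                         n_participants = 30,
                         between_subject_sd = 0.2,
                         noise = noise_spec(),
                         alpha = 0.05, n_perm = 1000, cluster_hat = 0,
                         n_blocks = 50, n_iter = 1000,
                         sweep_n_repeats = 500, sweep_n_boot = 1000,
                         contrasts = c("P1N1P2", "Local_SF", "Local_ST",
                                       "Global_SS_ST1", "Global_SF_ST2"),
                         components_active = NULL,
                         components_passive = NULL,
                         master_seed = 1,
                         output_dir = NULL) {
  validate_paradigm_config(paradigm)
  stopifnot(n_participants >= 1, alpha > 0, alpha < 1, n_perm >= 2,
            n_blocks >= 1, n_iter >= 1)
  structure(list(paradigm = paradigm, n_participants = n_participants,
                 between_subject_sd = between_subject_sd, noise = noise,
                 alpha = alpha, n_perm = n_perm, cluster_hat = cluster_hat,
                 n_blocks = n_blocks,
                 n_iter = n_iter, sweep_n_repeats = sweep_n_repeats,
                 sweep_n_boot = sweep_n_boot, contrasts = contrasts,
                 components_active = components_active,
                 components_passive = components_passive,
                 master_seed = master_seed, output_dir = output_dir),
            class = "lg_study_config")
}

#' Miniature study configurations for fast runs
#'
#' `"unit"` (2 participants, 60 analyzed pairs, reduced permutation and
#' iteration counts) exercises every stage in seconds; `"smoke"`
#' (6 participants, 300 analyzed pairs) is large enough for component
#' recovery while staying desk-scale.
#'
#' @param scale `"unit"` or `"smoke"`.
#' @param master_seed Integer master seed recorded in the configuration.
#' @return An `lg_study_config`.
#' @export
make_fixtures <- function(scale = c("unit", "smoke"), master_seed = 1) {
  scale <- match.arg(scale)
  if (scale == "unit") {
    study_config(
      paradigm = paradigm_config(n_total_pairs = 64, n_regularity_pairs = 4,
                                 n_ss = 25, n_sf = 23, n_st = 12,
                                 n_st_context_ss = 6, n_st_context_sf = 6),
      n_participants = 2, n_perm = 100, n_iter = 30, n_blocks = 10,
      sweep_n_repeats = 10, sweep_n_boot = 100, master_seed = master_seed)
  } else {
    study_config(
      paradigm = paradigm_config(n_total_pairs = 306, n_regularity_pairs = 6,
                                 n_ss = 123, n_sf = 120, n_st = 57,
                                 n_st_context_ss = 27, n_st_context_sf = 30),
      n_participants = 6, n_perm = 200, n_iter = 100, n_blocks = 25,
      sweep_n_repeats = 50, sweep_n_boot = 200, master_seed = master_seed)
  }
}

#' Run a full synthetic study
#'
#' Simulates the cohort participant by participant (recordings are released
#' after epoching, so memory stays bounded), runs the group-level cluster
#' statistics per contrast and condition plus the active-vs-passive task
#' contrast on the local/global effects, the individual sensitivity analysis
#' for every contrast and condition plus the active-vs-passive global
#' comparisons, and the sensor x epoch sweep for both global contrasts.
#'
#' @param config An [study_config()].
#' @param run_sweep_stage Set `FALSE` to skip the (slowest) sweep stage.
#' @param run_decoding_stage Set `FALSE` to skip the individual-sensitivity
#'   stage (group cluster statistics only).
#' @param sweep_contrasts Global contrasts to sweep (default: all configured
#'   global contrasts).
#' @param montage Montage; defaults to [montage_ant64()].
#' @return An `lg_study` list: `clusters` (named list of `lg_clusters`),
#'   `sensitivity` (list of `lg_sensitivity`), `detection` (Table-1-style
#'   tibble), `sweeps` (per global contrast: grid + correlations),
#'   `trial_counts` tibble, and the `config`/`manifest`.
#' @export
run_study <- function(config, run_sweep_stage = TRUE,
                      run_decoding_stage = TRUE, sweep_contrasts = NULL,
                      montage = montage_ant64()) {
  seed <- config$master_seed
  conds <- c("active", "passive")
  globals <- intersect(config$contrasts, c("Global_SS_ST1", "Global_SF_ST2"))
  avg <- list()        # avg[[contrast]][[cond]][[A|B]][[p]]
  t_epochs <- list()   # t_epochs[[contrast]][[cond]][[p]]: global T epochs
  sens <- list()
  counts <- list()
  times_by_contrast <- list()

  for (p in seq_len(config$n_participants)) {
    part <- simulate_participant(
      config$paradigm, config$noise, montage, participant_id = p, seed = seed,
      between_subject_sd = config$between_subject_sd,
      components_active = config$components_active %||%
        build_default_components("active"),
      components_passive = config$components_passive %||%
        build_default_components("passive"))
    for (cond in conds) {
      rec <- filter_chain(part[[cond]])
      part[[cond]] <- NULL   # release the raw recording
      for (cn in config$contrasts) {
        eps <- extract_epochs(rec, cn, participant_id = p)
        rej <- reject_amplitude(eps$A, eps$B)
        counts[[length(counts) + 1]] <- tibble(
          participant = p, condition = cond, contrast = cn,
          n_trials = n_trials(rej$A), n_rejected = unname(rej$n_rejected["A"]))
        avg[[cn]][[cond]][["A"]][[p]] <- epochs_average(rej$A)
        avg[[cn]][[cond]][["B"]][[p]] <- epochs_average(rej$B)
        times_by_contrast[[cn]] <- rej$A$times
        if (run_decoding_stage)
          sens[[paste(cn, cond, p, sep = "/")]] <- sensitivity_from_epochs(
            rej$A, rej$B, contrast = cn, n_blocks = config$n_blocks,
            n_iter = config$n_iter,
            seed = derive_seed(seed, "sens", cn, cond, p))
        if (cn %in% globals) t_epochs[[cn]][[cond]][[p]] <- rej$A
      }
      rm(rec)
      gc(verbose = FALSE)
    }
    if (run_decoding_stage) for (cn in globals) {
      sens[[paste(cn, "active_vs_passive", p, sep = "/")]] <-
        active_passive_contrast(
          t_epochs[[cn]][["active"]][[p]], t_epochs[[cn]][["passive"]][[p]],
          contrast = cn, n_blocks = config$n_blocks, n_iter = config$n_iter,
          seed = derive_seed(seed, "sens-ap", cn, p))
    }
  }

  clusters <- list()
  for (cn in config$contrasts) {
    tms <- times_by_contrast[[cn]]
    for (cond in conds) {
      g <- group_data(avg[[cn]][[cond]][["A"]], avg[[cn]][[cond]][["B"]],
                      tms, montage)
      clusters[[paste(cn, cond, sep = "/")]] <- permutation_test(
        g, n_perm = config$n_perm, alpha = config$alpha,
        hat = config$cluster_hat %||% 0,
        seed = derive_seed(seed, "clust", cn, cond))
    }
    if (cn != "P1N1P2") {
      # Task contrast: active vs passive difference (deviant - standard) waves.
      dif <- function(cond) purrr::map2(avg[[cn]][[cond]][["A"]],
                                        avg[[cn]][[cond]][["B"]], `-`)
      g <- group_data(dif("active"), dif("passive"), tms, montage)
      clusters[[paste(cn, "active_vs_passive", sep = "/")]] <- permutation_test(
        g, n_perm = config$n_perm, alpha = config$alpha,
        hat = config$cluster_hat %||% 0,
        seed = derive_seed(seed, "clust-ap", cn))
    }
  }

  sweeps <- list()
  if (run_sweep_stage && length(globals) > 0) {
    for (cn in intersect(sweep_contrasts %||% globals, globals)) {
      parts <- lapply(seq_len(config$n_participants), function(p)
        list(active = t_epochs[[cn]][["active"]][[p]],
             passive = t_epochs[[cn]][["passive"]][[p]]))
      grid <- run_sweep(parts, montage, n_repeats = config$sweep_n_repeats,
                        n_blocks = config$n_blocks,
                        seed = derive_seed(seed, "sweep", cn))
      sweeps[[cn]] <- list(
        grid = grid,
        correlations = correlate_performance(
          grid, n_boot = config$sweep_n_boot,
          seed = derive_seed(seed, "boot", cn)))
    }
  }

  study <- structure(list(
    clusters = clusters,
    sensitivity = sens,
    detection = if (length(sens)) detection_table(sens) else tibble(),
    sweeps = sweeps,
    trial_counts = bind_rows(counts),
    config = config,
    manifest = list(master_seed = seed,
                    n_participants = config$n_participants,
                    contrasts = config$contrasts,
                    package_version = as.character(utils::packageVersion("lgerp")),
                    r_version = R.version.string)),
    class = "lg_study")
  if (!is.null(config$output_dir)) write_study_results(study, config$output_dir)
  study
}

#' Detection-count table across contrasts and conditions
#'
#' Summarizes a set of sensitivity results into the published table layout:
#' detected / total per contrast and condition (plus the active-vs-passive
#' rows for the global contrasts).
#'
#' @param sens Named list of `lg_sensitivity` results with names
#'   `"contrast/condition/participant"`.
#' @return Tibble with `contrast`, `condition`, `n_detected`,
#'   `n_participants`, `mean_accuracy`, `sd_accuracy`.
#' @export
detection_table <- function(sens) {
  info <- purrr::map(names(sens), function(nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    s <- sens[[nm]]
    tibble(contrast = parts[1], condition = parts[2],
           participant = parts[3], detected = s$detected,
           accuracy = s$mean_accuracy)
  }) |> bind_rows()
  info |>
    group_by(.data$contrast, .data$condition) |>
    summarise(n_detected = sum(.data$detected),
              n_participants = n(),
              mean_accuracy = mean(.data$accuracy),
              sd_accuracy = sd(.data$accuracy), .groups = "drop")
}
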