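#' Run an analysis pipeline from a configuration list
#'
#' Dispatches one analysis stage from a configuration (typically parsed from
#' a JSON file) and writes its outputs, a provenance record (configuration
#' echo, hash and package version) included. Given the same configuration
#' and seed the outputs are deterministic.
#'
#' Subcommands and their required config fields:
#' \describe{
#'   \item{`simulate`}{`what` in `kymograph`/`distance`/`decay`/`fret`/
#'     `fd`/`reads` plus the matching generator arguments (`args` list);
#'     writes the dataset and its ground-truth sidecar.}
#'   \item{`track`}{`input` (TIFF kymograph); localizes and links, writes
#'     `localizations.csv` and `tracks.csv`.}
#'   \item{`motion`}{`input` (tracks CSV); MSD power-law fit, velocity and
#'     classification per track, written to `motion.csv` /
#'     `motion_summary.json`.}
#'   \item{`kinetics`}{`input` (dwell CSV with `duration_s`, `censored`);
#'     censored-MLE exponential fit to `kinetics.json`.}
#'   \item{`decay`}{`input` (decay CSV with `time_min`, `intensity`);
#'     stripping-rate fit to `decay.json`.}
#'   \item{`fret`}{`input` (trace CSV with `frame`, `I_D`, `I_A`);
#'     efficiency, segmentation and dwell tables.}
#'   \item{`polymer`}{`input` (CSV `extension_nm`, `force_pN`) plus `Lp`;
#'     event detection, per-branch contour lengths and loop sizes.}
#'   \item{`classify`}{`reference` and `reads` FASTA paths, optional
#'     `donor_subs`; per-read calls CSV and class-fraction JSON.}
#' }
#'
#' @param config Named list with at least `subcommand` and `out_dir`;
#'   stage parameters as described above. Unknown top-level keys are
#'   rejected.
#' @return Invisibly, a list of the stage's in-memory results.
#' @export
run_pipeline <- function(config) {
  allowed <- c("subcommand", "out_dir", "seed", "what", "args", "input",
               "reference", "reads", "donor_subs", "Lp", "kT",
               "threshold", "max_step", "max_gap", "min_duration",
               "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(config$subcommand) || is.null(config$out_dir)) {
    stop("config needs 'subcommand' and 'out_dir'", call. = FALSE)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  result <- switch(config$subcommand,
    simulate = pipeline_simulate(config, out),
    track = pipeline_track(config, out),
    motion = pipeline_motion(config, out),
    kinetics = {
      dw <- read_table_csv(config$input)
      fit <- fit_dwell_exponential(dw$duration_s, dw$censored)
      write_json_record(list(tau_s = fit$tau, se = fit$se, n = fit$n,
                             n_censored = fit$n_censored,
                             method = fit$method),
                        file.path(out, "kinetics.json"))
      list(fit = fit)
    },
    decay = {
      tr <- read_table_csv(config$input)
      fit <- fit_decay_rate(tr)
      write_json_record(list(k_per_min = fit$k, se = fit$se, A = fit$A,
                             C = fit$C, no_decay = fit$no_decay),
                        file.path(out, "decay.json"))
      list(fit = fit)
    },
    fret = pipeline_fret(config, out),
    polymer = {
      cur <- read_table_csv(config$input)
      p <- polymer_params(Lp = config$Lp %||% 50,
                          Lc = max(cur$extension_nm) * 2,
                          kT = config$kT %||% 4.114)
      res <- analyze_fd_curve(cur$extension_nm, cur$force_pN, p)
      write_table_csv(res$branches, file.path(out, "branches.csv"))
      write_json_record(list(loops_nm = res$loops,
                             n_events = length(res$boundaries)),
                        file.path(out, "polymer.json"))
      res
    },
    classify = {
      ref <- read_reads_fasta(config$reference)[[1]]
      reads <- read_reads_fasta(config$reads)
      donor <- config$donor_subs
      if (!is.null(donor)) donor <- as.data.frame(donor)
      res <- classify_reads(ref, reads, donor)
      write_table_csv(res$calls, file.path(out, "calls.csv"))
      write_json_record(as.list(res$fractions),
                        file.path(out, "class_fractions.json"))
      res
    },
    stop(sprintf("unknown subcommand '%s'", config$subcommand), call. = FALSE)
  )

  provenance <- list(
    config = config[!vapply(config, is.null, logical(1))],
    config_hash = fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)),
    package = "helitrax",
    version = as.character(utils::packageVersion("helitrax"))
  )
  write_json_record(provenance, file.path(out, "provenance.json"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_simulate <- function(config, out) {
  what <- config$what %||% "kymograph"
  args <- config$args %||% list()
  if (!is.null(config$seed)) args$seed <- config$seed
  switch(what,
    kymograph = {
      cfg_args <- args[setdiff(names(args), "particles")]
      cfg <- do.call(sim_config, cfg_args)
      parts <- lapply(args$particles, function(p) {
        do.call(match.fun(paste0("particle_", p$type)),
                p[setdiff(names(p), "type")])
      })
      sim <- simulate_kymograph(cfg, parts)
      write_kymograph(sim$kymograph, file.path(out, "kymograph.tif"))
      write_json_record(sim$truth["particles"],
                        file.path(out, "ground_truth.json"))
      sim
    },
    distance = {
      sim <- do.call(simulate_distance_trace, args)
      write_table_csv(sim$trace, file.path(out, "distance_trace.csv"))
      write_json_record(list(segments = sim$truth),
                        file.path(out, "ground_truth.json"))
      sim
    },
    decay = {
      tr <- do.call(simulate_decay_trace, args)
      write_table_csv(tr, file.path(out, "decay_trace.csv"))
      list(trace = tr)
    },
    fret = {
      sim <- do.call(simulate_fret_trace, args)
      write_table_csv(sim$trace, file.path(out, "fret_trace.csv"))
      write_json_record(list(dwells = sim$truth$dwells),
                        file.path(out, "ground_truth.json"))
      sim
    },
    fd = {
      pol_args <- args$polymer %||% list()
      args$polymer <- do.call(polymer_params, pol_args)
      if (!is.null(args$events)) args$events <- as.data.frame(args$events)
      sim <- do.call(simulate_fd_curve, args)
      write_table_csv(sim$curve, file.path(out, "fd_curve.csv"))
      write_json_record(list(Lc_sequence = sim$truth$Lc_sequence),
                        file.path(out, "ground_truth.json"))
      sim
    },
    reads = {
      if (!is.null(args$donor_subs)) args$donor_subs <- as.data.frame(args$donor_subs)
      args$mix <- unlist(args$mix)
      sim <- do.call(simulate_repair_reads, args)
      write_reads_fasta(sim$reads, file.path(out, "reads.fasta"))
      write_reads_fasta(c(reference = args$reference),
                        file.path(out, "reference.fasta"))
      write_json_record(list(truth = sim$truth),
                        file.path(out, "ground_truth.json"))
      sim
    },
    stop(sprintf("unknown simulation target '%s'", what), call. = FALSE))
}

pipeline_track <- function(config, out) {
  kymo <- read_kymograph(config$input)
  locs <- localize_kymograph(kymo)
  tracks <- link_trajectories(locs,
                              max_step = config$max_step %||% 300,
                              max_gap = config$max_gap %||% 1)
  write_table_csv(locs, file.path(out, "localizations.csv"))
  track_df <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(frame = integer(), time_s = numeric(),
               position_nm = numeric(), amplitude = numeric(),
               width_nm = numeric(), rss = numeric(), track_id = integer())
  write_table_csv(track_df, file.path(out, "tracks.csv"))
  list(localizations = locs, tracks = tracks)
}

pipeline_motion <- function(config, out) {
  df <- read_table_csv(config$input)
  # tracks too short for a meaningful MSD power-law fit are skipped
  keep <- names(which(table(df$track_id) >= 8))
  df <- df[df$track_id %in% keep, ]
  res <- lapply(split(df, df$track_id), function(tr) {
    fit <- fit_msd(compute_msd(tr))
    v <- estimate_velocity(tr)
    data.frame(track_id = tr$track_id[1], n = nrow(tr),
               alpha = if (fit$static) NA_real_ else fit$alpha,
               D = fit$D, label = fit$label, velocity_nm_s = v)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  write_table_csv(tab, file.path(out, "motion.csv"))
  write_json_record(list(
    n_tracks = nrow(tab),
    labels = as.list(table(tab$label)),
    mean_velocity_nm_s = mean(tab$velocity_nm_s)),
    file.path(out, "motion_summary.json"))
  list(table = tab)
}

pipeline_fret <- function(config, out) {
  tr <- read_table_csv(config$input)
  E <- compute_fret(tr$I_D, tr$I_A)
  thr <- config$threshold %||% fret_threshold(E)
  seg <- segment_states(E, threshold = thr)
  write_table_csv(data.frame(frame = tr$frame, E = E),
                  file.path(out, "fret_efficiency.csv"))
  write_table_csv(as.data.frame(seg), file.path(out, "segmentation.csv"))
  t_on <- state_dwells(seg, "free")
  fit <- if (nrow(t_on) >= 5) fit_dwell_exponential(t_on$duration_s) else NULL
  write_json_record(list(threshold = thr,
                         n_free = sum(seg$state == "free"),
                         n_bound = sum(seg$state == "bound"),
                         t_on_tau_s = if (!is.null(fit)) fit$tau else NA),
                    file.path(out, "fret_summary.json"))
  list(E = E, segmentation = seg, t_on_fit = fit)
}
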