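# End-to-end orchestration: recording -> phases -> coupling -> HFNs ->
# metrics -> dynamics -> (optional) stimulus classification, with file output.

#' Pipeline configuration
#'
#' Defaults mirror the method's stated operating point: frequencies of
#' interest 2--20 Hz in 2-Hz steps, 2000/100-ms sliding windows on a 20-ms
#' phase grid, connectivity threshold 0.26, 10 reference-network
#' realizations, and a 58-8-6 tanh classifier averaged over 100 repetitions.
#'
#' @param input Path to a recording written by [write_recording()], or a
#'   [segmented_recording()] object.
#' @param out_dir Output directory (created if missing).
#' @param fois Frequencies of interest in Hz.
#' @param n_cycles Morlet constant-cycles parameter.
#' @param time_step Wavelet decimation step in samples.
#' @param window_ms,step_ms Sliding-window width and step.
#' @param threshold Connectivity threshold for [apply_threshold()].
#' @param surrogates Compute a surrogate critical value? (slowest stage)
#' @param surrogate_method,n_boot,alpha,n_surrogates Surrogate settings.
#' @param n_reference Reference-network realizations for small-world metrics.
#' @param small_world_window Window index to run the small-world analysis on
#'   (`NULL` skips it).
#' @param modularity_restarts Louvain restarts.
#' @param classify Run the stimulus classifier when a schedule is present?
#' @param fnn An [fnn_config()].
#' @param write_graphs Write per-window edge lists?
#' @param seed Global seed, fanned out to the stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, fois = seq(2, 20, by = 2),
                            n_cycles = 5, time_step = 5L,
                            window_ms = 2000, step_ms = 100, threshold = 0.26,
                            surrogates = FALSE,
                            surrogate_method = "phase-shuffle",
                            n_boot = 1000, alpha = 1e-4, n_surrogates = 10,
                            n_reference = 10, small_world_window = NULL,
                            modularity_restarts = 10,
                            classify = TRUE, fnn = fnn_config(),
                            write_graphs = FALSE, seed = 1L) {
  structure(list(input = input, out_dir = out_dir, fois = fois,
                 n_cycles = n_cycles, time_step = as.integer(time_step),
                 window_ms = window_ms, step_ms = step_ms,
                 threshold = threshold, surrogates = surrogates,
                 surrogate_method = surrogate_method, n_boot = n_boot,
                 alpha = alpha, n_surrogates = n_surrogates,
                 n_reference = n_reference,
                 small_world_window = small_world_window,
                 modularity_restarts = modularity_restarts,
                 classify = classify, fnn = fnn,
                 write_graphs = write_graphs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full HFN pipeline
#'
#' Executes phase extraction, sliding-window coupling, HFN construction and
#' thresholding, nodal metric dynamics, temporal/nodal similarity and
#' modularity, optional surrogate thresholding and small-world analysis, and
#' optional stimulus classification; writes delimited tables and JSON
#' summaries plus a manifest into `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`recording`,
#'   `coupling`, `graphs`, `dynamics`, `summaries`, `partitions`,
#'   `classification`, ...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  rec <- if (inherits(cfg$input, "segmented_recording")) cfg$input
         else read_recording(cfg$input)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  params <- morlet_params(freqs = cfg$fois, n_cycles = cfg$n_cycles,
                          time_step = cfg$time_step)
  phases <- extract_phases(rec, params)
  nodes <- hfn_nodes(rec$labels, cfg$fois)
  pairs <- hfn_pairs(nodes)
  coupling <- sliding_window_coupling(phases, pairs, window_ms = cfg$window_ms,
                                      step_ms = cfg$step_ms)
  write.table(as.data.frame(coupling), out("coupling.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  graphs <- hfn_series(coupling, nodes, threshold = cfg$threshold)
  if (cfg$write_graphs) {
    dir.create(out("graphs"), showWarnings = FALSE)
    for (w in seq_along(graphs)) {
      write_hfn(graphs[[w]], out("graphs", sprintf("window_%03d", w)))
    }
  }

  dynamics <- metric_dynamics_set(graphs)
  summaries <- list()
  partitions <- list()
  for (mt in names(dynamics)) {
    m <- dynamics[[mt]]
    write.table(m, out(sprintf("dynamics_%s.tsv", mt)), sep = "\t",
                row.names = FALSE, col.names = FALSE)
    s_t <- similarity(m, "temporal")
    s_n <- similarity(m, "nodal")
    write.table(unclass(s_t), out(sprintf("similarity_temporal_%s.tsv", mt)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    p_t <- suppressMessages(modularity_partition(
      s_t, seed = cfg$seed + 1L, n_restarts = cfg$modularity_restarts))
    p_n <- louvain_signed_partition(s_n, seed = cfg$seed + 2L,
                                    n_restarts = cfg$modularity_restarts)
    partitions[[mt]] <- list(temporal = p_t, nodal = p_n)
    write.table(data.frame(element = seq_along(p_t$assignment),
                           module = p_t$assignment),
                out(sprintf("states_%s.tsv", mt)), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(data.frame(element = seq_along(p_n$assignment),
                           module = p_n$assignment),
                out(sprintf("communities_%s.tsv", mt)), sep = "\t",
                row.names = FALSE, quote = FALSE)
    summaries[[mt]] <- c(summarize_dynamics(m),
                         list(states = state_statistics(p_t,
                                step_s = cfg$step_ms / 1000),
                              communities = state_statistics(p_n)))
  }

  result <- list(recording = rec, phases = NULL, coupling = coupling,
                 nodes = nodes, graphs = graphs, dynamics = dynamics,
                 partitions = partitions, summaries = summaries)

  if (cfg$surrogates) {
    sn <- surrogate_critical_value(rec, cfg$surrogate_method,
                                   n_boot = cfg$n_boot, alpha = cfg$alpha,
                                   seed = cfg$seed + 3L,
                                   n_surrogates = cfg$n_surrogates,
                                   fois = cfg$fois,
                                   window_ms = cfg$window_ms,
                                   step_ms = cfg$step_ms, params = params)
    result$surrogate_null <- sn
    summaries$surrogate <- list(method = sn$method,
                                critical_value = sn$critical_value,
                                alpha = sn$alpha,
                                threshold_exceeds = cfg$threshold > sn$critical_value)
  }

  if (!is.null(cfg$small_world_window)) {
    g <- graphs[[cfg$small_world_window]]
    rand <- random_reference(g, cfg$n_reference, seed = cfg$seed + 4L)
    latt <- lattice_reference(g, cfg$n_reference, seed = cfg$seed + 5L)
    sw <- small_world_coefficients(g, rand, latt)
    result$small_world <- sw
    summaries$small_world <- sw[c("gamma", "lambda", "sigma", "omega",
                                  "gammaE", "lambdaE", "sigmaE", "omegaE")]
  }

  if (cfg$classify && !is.null(rec$schedule)) {
    ca <- run_stimulus_ntd(dynamics, rec$schedule, nodes, cfg$fnn,
                           window_step_ms = cfg$step_ms)
    write.table(ca, out("classification.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    result$classification <- ca
  }

  jsonlite::write_json(summaries, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  cfg_out <- cfg
  cfg_out$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
  cfg_out$fnn <- unclass(cfg_out$fnn)
  jsonlite::write_json(unclass(cfg_out), out("config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(config_md5 = unname(tools::md5sum(out("config.json"))),
                   seed = cfg$seed,
                   n_channels = length(rec$labels), fs = rec$fs,
                   n_nodes = nrow(nodes), n_windows = coupling$n_windows,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(result)
}
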