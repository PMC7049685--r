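#' Built-in simulation scenarios
#'
#' Named conditions matching the experimental designs the simulator
#' emulates: `dna_only` (free DNA, single low-FRET state), `wt_pos2`
#' (wild-type +2 initiation complex: three states with scrunching favored,
#' Keq = 6) and `d12_pos2` (C-tail-truncated factor at +2: destabilized
#' scrunching, Keq = 1.5). Each returns a config list accepted by
#' [run_pipeline()].
#'
#' @param scenario scenario name.
#' @param seed master seed.
#' @param n_traces,n_frames simulation size.
#' @return a config list.
#' @export
scenario_config <- function(scenario = c("dna_only", "wt_pos2", "d12_pos2"),
                            seed = 1L, n_traces = 50L, n_frames = 400L) {
  scenario <- match.arg(scenario)
  model <- switch(scenario,
    dna_only = kinetic_model(matrix(0, 1, 1), fret_means = 0.14,
                             fret_sd = 0.06, states = "closed"),
    wt_pos2 = three_state_model(k_open = 0.2, k_close = 0.4,
                                k_scrunch = 0.6, k_unscrunch = 0.1),
    d12_pos2 = three_state_model(k_open = 0.2, k_close = 0.4,
                                 k_scrunch = 0.6, k_unscrunch = 0.4))
  list(scenario = scenario, seed = as.integer(seed),
       n_traces = as.integer(n_traces), n_frames = as.integer(n_frames),
       kinetic_model = model,
       photophysics = photophysics(),
       fit = list(window = 5L,
                  n_components = length(model$states),
                  n_states = length(model$states)))
}

.validate_config <- function(config) {
  required <- c("scenario", "seed", "n_traces", "n_frames",
                "kinetic_model", "photophysics", "fit")
  missing_blocks <- setdiff(required, names(config))
  if (length(missing_blocks))
    stop("config is missing block(s): ",
         paste(missing_blocks, collapse = ", "))
  if (!inherits(config$kinetic_model, "kinetic_model"))
    stop("config block `kinetic_model` must be a kinetic_model object")
  if (!inherits(config$photophysics, "photophysics"))
    stop("config block `photophysics` must be a photophysics object")
  invisible(config)
}

#' Run the smFRET analysis pipeline end to end
#'
#' Composes simulate -> QC selection -> FRET correction -> five-frame
#' histogram -> mixture fit, and (for multi-state models) the three-state
#' HMM -> Viterbi idealization -> transition density -> rate conversion.
#' Every stochastic stage derives its seed from the config's master seed,
#' so identical configs give identical reports.
#'
#' @param config a config list, typically from [scenario_config()].
#' @param out_dir optional directory; when given, traces, the FRET
#'   histogram, mixture table and rate tables are written as delimited
#'   text.
#' @return a `run_report` list: `config`, `n_traces_accepted`,
#'   `rejections`, `histogram`, `mixture`, and for multi-state models
#'   `hmm`, `rates`, `tdp`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  .validate_config(config)
  model <- config$kinetic_model
  phys <- config$photophysics
  seeds <- derive_seeds(config$seed, 3L)

  traces <- simulate_trace_set(model, phys, config$n_traces,
                               config$n_frames, seed = seeds[1])
  kept <- select_traces(traces,
                        acceptor_check = phys$n_check_frames > 0,
                        single_pair = TRUE,
                        acceptor_min = phys$total_intensity / 4,
                        leakage = phys$leakage,
                        background_d = phys$background_d,
                        background_a = phys$background_a)
  if (length(kept) == 0L) stop("pipeline: QC rejected every trace")
  fret <- lapply(kept, compute_fret, leakage = phys$leakage,
                 background_d = phys$background_d,
                 background_a = phys$background_a)
  hist_obj <- build_histogram(fret, window = config$fit$window)
  mix <- fit_gaussian_mixture(hist_obj,
                              n_components = config$fit$n_components,
                              seed = seeds[2])
  report <- list(config = config,
                 n_traces_accepted = length(kept),
                 rejections = attr(kept, "rejections"),
                 histogram = hist_obj,
                 mixture = mix)
  if (length(model$states) > 1L) {
    fit <- fit_hmm(fret, n_states = config$fit$n_states, seed = seeds[3])
    paths <- lapply(fret, function(f) viterbi_path(fit, f))
    report$hmm <- fit
    report$tdp <- transition_density(paths, fit)
    report$rates <- rates_from_hmm(fit, phys$frame_interval)
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir, traces)
  report
}

#' Write a pipeline report's tables to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @param traces optional trace set to write alongside the results.
#' @export
write_report <- function(report, dir, traces = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- report$config$seed
  if (!is.null(traces)) write_trace_set(traces, file.path(dir, "traces"))
  h <- report$histogram
  .write_tsv(data.frame(bin_left = head(h$bin_edges, -1),
                        bin_right = tail(h$bin_edges, -1),
                        density = h$density, counts = h$counts),
             file.path(dir, "fret_histogram.tsv"),
             .provenance_header("histogram", seed))
  write_mixture_fit(report$mixture, file.path(dir, "mixture_fit.tsv"))
  if (!is.null(report$rejections) && nrow(report$rejections))
    .write_tsv(report$rejections, file.path(dir, "qc_rejections.tsv"),
               .provenance_header("qc", seed))
  if (!is.null(report$hmm)) {
    fit <- report$hmm
    .write_tsv(data.frame(state = seq_len(fit$n_states),
                          mean = fit$emission_means,
                          sigma = fit$emission_sds,
                          initial_prob = fit$initial_probs),
               file.path(dir, "hmm_emissions.tsv"),
               .provenance_header("hmm", seed))
    .write_tsv(as.data.frame(fit$transition_matrix),
               file.path(dir, "hmm_transition_matrix.tsv"),
               .provenance_header("hmm", seed))
    .write_tsv(as.data.frame(report$rates$k),
               file.path(dir, "rate_matrix.tsv"),
               .provenance_header("rates", seed))
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report: scenario", x$config$scenario,
      "(seed", x$config$seed, ")\n")
  cat(" ", x$n_traces_accepted, "of", x$config$n_traces,
      "traces passed QC;", x$histogram$n_points, "window means\n")
  cat("  mixture means:", paste(round(x$mixture$means, 3),
                                collapse = ", "), "\n")
  if (!is.null(x$rates))
    cat("  Keq (scrunch):", format(x$rates$keq_scrunch, digits = 3), "\n")
  invisible(x)
}
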