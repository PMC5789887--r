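# End-to-end orchestration: a single configuration drives generation,
# reduction, FEWS analysis, QENS fitting and trajectory analysis; the run
# report is a pure function of config + inputs + seed.

.pipeline_stages <- c("synth_spectra", "synth_scan", "synth_traj",
                      "reduce", "fews", "fit_qens", "traj")

#' Run a configured analysis pipeline
#'
#' `config` is a list (or path to a YAML file) with fields `seed`
#' (integer), optional `outdir` (report written as JSON there) and
#' `stages`, a list of stage specs executed in order.  Each stage is a
#' list with `name` in `synth_spectra`, `synth_scan`, `synth_traj`,
#' `reduce`, `fews`, `fit_qens`, `traj`, plus
#' stage parameters; stages exchange artifacts by name (e.g. `fit_qens`
#' consumes the spectra produced by `synth_spectra`, or reads them from a
#' `spectra`/`resolution` file pair).  The report records every stage's
#' parameters and scalar outputs; for a fixed config and seed the report
#' is identical across runs.
#'
#' @param config list or YAML file path.
#' @return List of class `pipeline_report` with `seed` and one entry per
#'   stage (`name`, `params`, `outputs`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  for (st in stages) {
    if (is.null(st$name) || !st$name %in% .pipeline_stages)
      stop("unknown pipeline stage: ",
           if (is.null(st$name)) "<unnamed>" else st$name)
    for (f in intersect(c("spectra_file", "resolution_file", "scan_file"),
                        names(st)))
      if (!file.exists(st[[f]]))
        stop(sprintf("stage '%s': input file not found: %s", st$name, st[[f]]))
  }
  art <- new.env(parent = emptyenv())
  report <- list(seed = seed, stages = list())
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    st_seed <- seed + 101L * k
    out <- switch(
      st$name,
      synth_spectra = {
        params <- if (identical(st$phase, "fluid"))
          do.call(fluid_params, st$params) else do.call(gel_coagel_params,
                                                        st$params)
        lat <- if (!is.null(st$D_lat_cm2s)) lateral_model(st$D_lat_cm2s)
        ds <- generate_qens_dataset(
          phase = st$phase, params = params, lateral = lat,
          q = if (is.null(st$q)) seq(0.5, 1.8, length.out = 8) else st$q,
          peak_counts = if (is.null(st$peak_counts)) 1e4 else st$peak_counts,
          noise = if (is.null(st$noise)) "poisson" else st$noise,
          seed = st_seed)
        art$spectra <- ds$spectra; art$resolution <- ds$resolution
        art$phase <- st$phase
        list(n_spectra = length(ds$spectra),
             peak_counts = ds$truth$peak_counts)
      },
      synth_scan = {
        sc <- generate_elastic_scan(
          schedule = as.data.frame(st$schedule), q = st$q,
          cycle = if (is.null(st$cycle)) "heating" else st$cycle,
          steps = if (is.null(st$steps)) NULL else as.data.frame(st$steps),
          noise_frac = if (is.null(st$noise_frac)) 0 else st$noise_frac,
          seed = st_seed)
        art$scan <- sc
        list(n_rows = nrow(sc))
      },
      synth_traj = {
        tr <- do.call(generate_trajectory,
                      c(st[setdiff(names(st), "name")], list(seed = st_seed)))
        art$traj <- tr
        list(n_frames = dim(tr$positions)[1],
             n_particles = dim(tr$positions)[2])
      },
      reduce = {
        sol <- if (!is.null(st$spectra_file))
          read_grouped_spectra(st$spectra_file) else art$spectra
        sov <- read_grouped_spectra(st$solvent_file)
        phi <- if (is.null(st$phi)) default_solvent_fraction() else st$phi
        red <- mapply(subtract_solvent, sol, sov,
                      MoreArgs = list(phi = phi), SIMPLIFY = FALSE)
        art$spectra <- red
        list(phi = phi,
             n_negative = sum(vapply(red, function(s)
               attr(s, "n_negative"), integer(1))))
      },
      fews = {
        sc <- if (!is.null(st$scan_file)) read_elastic_scan(st$scan_file)
        else art$scan
        cyc <- if (is.null(st$cycle)) "heating" else st$cycle
        qa <- q_average_elastic(sc, cycle = cyc)
        tr <- detect_transitions(qa$T_K, qa$I_el)
        msd <- try(fit_msd(sc, cycle = cyc), silent = TRUE)
        list(transitions_K = as.numeric(tr),
             u2_max = if (inherits(msd, "try-error")) NA_real_
             else max(msd$u2))
      },
      fit_qens = {
        sp <- if (!is.null(st$spectra_file))
          read_grouped_spectra(st$spectra_file) else art$spectra
        kern <- if (!is.null(st$resolution_file)) {
          rs <- read_grouped_spectra(st$resolution_file)[[1]]
          resolution_kernel(rs$energies, rs$intensity)
        } else art$resolution
        phase <- if (is.null(st$phase)) art$phase else st$phase
        ch <- qens_inference_chain(
          sp, kern, phase,
          n_starts = if (is.null(st$n_starts)) 8L else st$n_starts,
          seed = st_seed)
        out <- list(phase = phase)
        if (phase == "fluid") {
          out$R_max <- ch$eisf$R_max
          out$D_max_cm2s <- ch$hwhm$D_max_cm2s
          out$tau_MG <- ch$hwhm$tau_MG
        } else {
          out$p_x <- ch$eisf$p_x; out$a <- ch$eisf$a
          out$tau_MG <- ch$hwhm$tau_MG
          out$D_r_per_s <- ch$hwhm$D_r_per_s
        }
        if (!is.null(ch$fickian)) out$D_lat_cm2s <- ch$fickian$D_lat_cm2s
        out
      },
      traj = {
        tr <- art$traj
        if (is.null(tr)) stop("stage 'traj': no trajectory artifact available")
        qv <- if (is.null(st$q)) c(0.7, 1.0, 1.4) else st$q
        isf <- compute_isf(tr, qv,
                           max_lag = if (is.null(st$max_lag)) NULL
                           else st$max_lag,
                           orientation = if (is.null(st$orientation))
                             "powder" else st$orientation)
        rates <- vapply(qv, function(qq) {
          sub <- isf[isf$q == qq, ]
          fit_isf_three_process(sub$t_ps, sub$isf, seed = st_seed)$Gamma_lat
        }, numeric(1))
        dl <- try(lateral_diffusivity_from_isf(qv, rates), silent = TRUE)
        list(Gamma_lat_per_ps = rates,
             D_lat_cm2s = if (inherits(dl, "try-error")) NA_real_
             else dl$D_lat_cm2s)
      })
    report$stages[[k]] <- list(name = st$name,
                               params = st[setdiff(names(st), "name")],
                               outputs = out)
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$outdir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}
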