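# End-to-end driver: simulate (or load) raw datasets, reduce, fit the
# elastic and/or quasi-elastic branch, and assemble a machine-readable
# report with a resilience/MSD summary block and an immobile-fraction
# block. All stages are pure functions of (inputs, config, seed).

#' Build a run configuration
#'
#' @param samples Character vector of fixture names (see
#'   \code{\link{fixture_catalog}}) or a named list of
#'   \code{\link{sample_model}} objects.
#' @param elastic_instrument,qens_instrument Instrument preset names or
#'   \code{\link{instrument_config}} objects.
#' @param temperatures Elastic-scan temperatures (K).
#' @param qens_temperature QENS temperature (K).
#' @param q_window Q window (1/A) for the MSD extraction.
#' @param t_min Lower bound (K) of the force-constant fit.
#' @param counts_scale Expected peak counts for Poisson noise;
#'   \code{NULL} for noiseless runs.
#' @param seed Base seed; per-sample seeds are derived deterministically.
#' @param transmission Sample transmission.
#' @param empty_level Empty-cell background level.
#' @param do_elastic,do_qens Which branches to run.
#' @return A \code{run_config} list.
#' @export
run_config <- function(samples = c("h30s_nacl", "h30s_kcl", "h50s_nacl"),
                       elastic_instrument = "IN16",
                       qens_instrument = "IN5_5.1A",
                       temperatures = seq(250, 310, by = 5),
                       qens_temperature = 298,
                       q_window = c(0.34, 0.85), t_min = 270,
                       counts_scale = 1e5, seed = 1L,
                       transmission = 0.93, empty_level = 0.05,
                       do_elastic = TRUE, do_qens = TRUE) {
  models <- if (is.character(samples)) {
    cat_models <- fixture_catalog()
    missing <- setdiff(samples, names(cat_models))
    if (length(missing))
      stop("unknown fixture sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    cat_models[samples]
  } else samples
  resolve <- function(x) if (is.character(x)) instrument_preset(x) else x
  ei <- resolve(elastic_instrument); qi <- resolve(qens_instrument)
  if (q_window[1] < ei$q_min - 1e-9 || q_window[2] > ei$q_max + 1e-9)
    stop("q_window outside the elastic instrument's Q range", call. = FALSE)
  structure(list(models = models, elastic_instrument = ei,
                 qens_instrument = qi, temperatures = temperatures,
                 qens_temperature = qens_temperature,
                 q_window = q_window, t_min = t_min,
                 counts_scale = counts_scale, seed = as.integer(seed),
                 transmission = transmission, empty_level = empty_level,
                 do_elastic = do_elastic, do_qens = do_qens),
            class = "run_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

run_noise <- function(config, offset) {
  if (is.null(config$counts_scale)) noise_spec("none")
  else noise_spec("poisson", counts_scale = config$counts_scale,
                  seed = derive_seed(config$seed, offset))
}

#' Run the elastic branch for one sample model
#'
#' Simulates the raw scan + empty cell + vanadium, reduces, extracts the
#' MSD series and fits the force constant.
#'
#' @param model A \code{\link{sample_model}}.
#' @param config A \code{\link{run_config}}.
#' @param seed_offset Offset added to the derived seed (so samples get
#'   independent noise streams).
#' @return List with \code{series} (\code{msd_series}) and \code{fc}
#'   (\code{force_constant_result}).
#' @export
run_elastic_sample <- function(model, config, seed_offset = 0L) {
  raw <- simulate_experiment(model, config$elastic_instrument, "elastic",
                             noise = run_noise(config, seed_offset),
                             temperatures = config$temperatures,
                             empty_level = config$empty_level,
                             transmission = config$transmission)
  red <- reduce_chain(raw$sample, raw$empty, raw$vanadium,
                      transmission = config$transmission)
  series <- fit_msd(red, config$q_window)
  fc <- fit_force_constant(series, config$t_min)
  list(series = series, fc = fc)
}

#' Run the quasi-elastic branch for one sample model
#'
#' @inheritParams run_elastic_sample
#' @return A \code{\link{fit_qens}} result.
#' @export
run_qens_sample <- function(model, config, seed_offset = 0L) {
  raw <- simulate_experiment(model, config$qens_instrument, "qens",
                             noise = run_noise(config, seed_offset),
                             temperature = config$qens_temperature,
                             empty_level = config$empty_level,
                             transmission = config$transmission)
  red <- reduce_chain(raw$sample, raw$empty, raw$vanadium,
                      transmission = config$transmission)
  fit_qens(red, instrument = config$qens_instrument)
}

#' Run the full pipeline over the configured samples
#'
#' simulate -> reduce -> fit-elastic and/or fit-qens -> report. The report
#' contains a resilience table (\code{<k>} and MSD at 37 C with
#' uncertainties per sample) and an immobile-fraction block, plus the run
#' metadata (seed, windows, convention constant, package version) needed
#' to reproduce it. Identical configurations produce identical reports.
#'
#' @param config A \code{\link{run_config}}.
#' @param out Optional path; when given, the report is also written as JSON.
#' @return A \code{ribodyn_report} list.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  table1 <- NULL; immobile <- NULL; details <- list()
  for (k in seq_along(config$models)) {
    model <- config$models[[k]]
    det <- list()
    if (config$do_elastic) {
      el <- run_elastic_sample(model, config, seed_offset = 10L * k)
      table1 <- rbind(table1, data.frame(
        sample = model$name,
        k_eff = el$fc$k_eff, k_sigma = el$fc$k_sigma,
        msd_at_37C = el$fc$msd_at_ref, msd_sigma = el$fc$msd_at_ref_sigma))
      det$elastic <- el
    }
    if (config$do_qens) {
      qf <- run_qens_sample(model, config, seed_offset = 10L * k + 5L)
      immobile <- rbind(immobile, data.frame(
        sample = model$name,
        fraction = qf$immobile$fraction, sigma = qf$immobile$sigma))
      det$qens <- qf
    }
    details[[model$name]] <- det
  }
  report <- structure(list(
    table1 = table1, immobile = immobile, details = details,
    meta = list(seed = config$seed, q_window = config$q_window,
                t_min = config$t_min, counts_scale = config$counts_scale,
                gauss_constant = gauss_constant(),
                qh_constant = QH_CONST,
                package_version = as.character(utils::packageVersion("ribodyn")))),
    class = "ribodyn_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Serialize a report to JSON
#'
#' Machine-readable rendering of the summary blocks and metadata
#' (per-sample fit details are omitted); deterministic for a given report.
#'
#' @param report A \code{ribodyn_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(table1 = report$table1, immobile = report$immobile,
              meta = report$meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.ribodyn_report <- function(x, ...) {
  cat("<ribodyn_report>\n")
  if (!is.null(x$table1)) {
    cat("  Resilience and MSD at 37 C:\n")
    for (i in seq_len(nrow(x$table1)))
      cat(sprintf("    %-10s <k> = %.3f +/- %.3f N/m   MSD = %.1f +/- %.1f A^2\n",
                  x$table1$sample[i], x$table1$k_eff[i], x$table1$k_sigma[i],
                  x$table1$msd_at_37C[i], x$table1$msd_sigma[i]))
  }
  if (!is.null(x$immobile)) {
    cat("  Immobile H fraction (10 ps timescale):\n")
    for (i in seq_len(nrow(x$immobile)))
      cat(sprintf("    %-10s %.1f +/- %.1f %%\n", x$immobile$sample[i],
                  100 * x$immobile$fraction[i], 100 * x$immobile$sigma[i]))
  }
  invisible(x)
}

#' Compare resilience and MSD between two samples
#'
#' Ratios of force constants and of MSD at 37 C between the (first) sample
#' of two reports, with uncertainties propagated for independent
#' measurements, plus integer-rounded and one-decimal-rounded forms for
#' headline statements like "a factor of 2 stiffer".
#'
#' @param report_a,report_b \code{ribodyn_report} objects (or single rows
#'   of a resilience table); both must contain force-constant blocks.
#' @param sample_a,sample_b Sample names to compare; default the first row
#'   of each report.
#' @return List with \code{k_ratio}, \code{k_ratio_sigma},
#'   \code{msd_ratio}, \code{msd_ratio_sigma} and their rounded forms.
#' @export
compare_samples <- function(report_a, report_b, sample_a = NULL,
                            sample_b = NULL) {
  get_row <- function(rep, sample) {
    tab <- if (inherits(rep, "ribodyn_report")) rep$table1
           else if (is.data.frame(rep)) rep else rep$table1
    if (!is.data.frame(tab) || is.null(tab$k_eff))
      stop("report lacks a force-constant block", call. = FALSE)
    if (!is.null(sample)) tab <- tab[tab$sample == sample, , drop = FALSE]
    if (nrow(tab) < 1) stop("sample not found in report", call. = FALSE)
    tab[1, ]
  }
  a <- get_row(report_a, sample_a); b <- get_row(report_b, sample_b)
  ratio <- function(x, sx, y, sy) {
    r <- x / y
    list(value = r, sigma = abs(r) * sqrt((sx / x)^2 + (sy / y)^2))
  }
  kr <- ratio(a$k_eff, a$k_sigma, b$k_eff, b$k_sigma)
  mr <- ratio(a$msd_at_37C, a$msd_sigma, b$msd_at_37C, b$msd_sigma)
  list(k_ratio = kr$value, k_ratio_sigma = kr$sigma,
       k_ratio_rounded = round(kr$value),
       k_ratio_one_decimal = round(kr$value, 1),
       msd_ratio = mr$value, msd_ratio_sigma = mr$sigma,
       msd_ratio_rounded = round(mr$value),
       msd_ratio_one_decimal = round(mr$value, 1))
}
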