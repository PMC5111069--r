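# NSTSV: a self-describing tab-separated dialect for reduced neutron
# spectra. '#'-prefixed 'key<TAB>value' header lines, then a column header
# row and long-format data rows. UTF-8, LF, '.' decimal separator.
#
#   qens:     q  omega        intensity  sigma
#   elastic:  q  temperature  intensity  sigma
#   vanadium: q  intensity    sigma
#
# Required header keys: kind, instrument, sample, temperature_K or
# temperature_column, monitor, transmission, reduction_state, q_units,
# omega_units. Numeric output uses %.15g so a load/write cycle is a fixed
# point and every field survives to >= 12 significant digits.

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a dataset to an NSTSV file
#'
#' Output is deterministic: fixed key order, fixed column order, fixed
#' numeric formatting, no timestamps — identical objects produce identical
#' bytes.
#'
#' @param obj A \code{spectrum_set}, \code{elastic_scan} or \code{vanadium_ref}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(obj, path) {
  validate_dataset(obj)
  md <- obj$metadata
  red <- if (length(md$reduction_state)) paste(md$reduction_state, collapse = ",")
         else "raw"
  hdr <- c("# nstsv\t1")
  add <- function(key, value) hdr <<- c(hdr, paste0("# ", key, "\t", value))
  if (inherits(obj, "spectrum_set")) {
    add("kind", "qens")
    add("instrument", md$instrument); add("sample", md$sample)
    add("temperature_K", fmt_num(obj$temperature))
    add("monitor", fmt_num(obj$monitor))
    add("transmission", fmt_num(obj$transmission))
  } else if (inherits(obj, "elastic_scan")) {
    add("kind", "elastic")
    add("instrument", md$instrument); add("sample", md$sample)
    add("temperature_column", "true")
    add("monitor", paste(fmt_num(obj$monitor), collapse = ","))
    add("transmission", fmt_num(obj$transmission))
  } else {
    add("kind", "vanadium")
    add("instrument", md$instrument); add("sample", md$sample)
    add("temperature_K", fmt_num(md$temperature %||% 295))
    add("monitor", "1")
    add("transmission", "1")
  }
  add("reduction_state", red)
  add("q_units", "inv_angstrom")
  add("omega_units", "ueV")
  if (!is.null(md$q_window))
    add("q_window", paste(fmt_num(md$q_window), collapse = ","))

  if (inherits(obj, "spectrum_set")) {
    cols <- "q\tomega\tintensity\tsigma"
    rows <- character(length(obj$q) * length(obj$omega))
    r <- 0L
    for (i in seq_along(obj$q)) for (j in seq_along(obj$omega)) {
      r <- r + 1L
      rows[r] <- paste(fmt_num(obj$q[i]), fmt_num(obj$omega[j]),
                       fmt_num(obj$intensity[i, j]), fmt_num(obj$sigma[i, j]),
                       sep = "\t")
    }
  } else if (inherits(obj, "elastic_scan")) {
    cols <- "q\ttemperature\tintensity\tsigma"
    rows <- character(length(obj$q) * length(obj$temperatures))
    r <- 0L
    for (i in seq_along(obj$q)) for (j in seq_along(obj$temperatures)) {
      r <- r + 1L
      rows[r] <- paste(fmt_num(obj$q[i]), fmt_num(obj$temperatures[j]),
                       fmt_num(obj$intensity[i, j]), fmt_num(obj$sigma[i, j]),
                       sep = "\t")
    }
  } else {
    cols <- "q\tintensity\tsigma"
    rows <- paste(fmt_num(obj$q), fmt_num(obj$intensity), fmt_num(obj$sigma),
                  sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, cols, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_header <- function(lines) {
  keys <- list(); n <- 0L
  for (ln in lines) {
    n <- n + 1L
    if (!startsWith(ln, "#")) break
    body <- sub("^#[ ]?", "", ln)
    parts <- strsplit(body, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed NSTSV header at line ", n, ": '", ln, "'", call. = FALSE)
    keys[[parts[1]]] <- parts[2]
  }
  list(keys = keys, data_start = n)
}

#' Load a dataset from an NSTSV file
#'
#' @param path File path.
#' @param kind Optional expected kind (\code{"qens"}, \code{"elastic"},
#'   \code{"vanadium"}); an error is raised if the file declares another.
#' @return A \code{spectrum_set}, \code{elastic_scan} or \code{vanadium_ref},
#'   fully validated (ascending grids, consistent shapes, non-negative sigma).
#' @export
load_dataset <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  h <- parse_header(lines)
  keys <- h$keys
  required <- c("kind", "instrument", "sample", "monitor", "transmission",
                "reduction_state", "q_units", "omega_units")
  missing <- setdiff(required, names(keys))
  if (length(missing))
    stop("NSTSV header is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(keys$temperature_K) && is.null(keys$temperature_column))
    stop("NSTSV header needs temperature_K or temperature_column", call. = FALSE)
  file_kind <- keys$kind
  if (!file_kind %in% c("qens", "elastic", "vanadium"))
    stop("unknown NSTSV kind: ", file_kind, call. = FALSE)
  if (!is.null(kind) && !identical(kind, file_kind))
    stop("expected kind '", kind, "' but file declares '", file_kind, "'",
         call. = FALSE)
  if (keys$q_units != "inv_angstrom" || keys$omega_units != "ueV")
    stop("unsupported units in NSTSV header", call. = FALSE)

  body <- lines[h$data_start:length(lines)]
  body <- body[nzchar(body)]
  expected_cols <- switch(file_kind,
    qens = c("q", "omega", "intensity", "sigma"),
    elastic = c("q", "temperature", "intensity", "sigma"),
    vanadium = c("q", "intensity", "sigma"))
  got_cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(got_cols, expected_cols))
    stop("malformed NSTSV column header at line ", h$data_start,
         ": expected '", paste(expected_cols, collapse = "\\t"), "'",
         call. = FALSE)
  dat <- utils::read.table(text = body[-1], sep = "\t", col.names = expected_cols,
                           colClasses = "numeric")

  red <- keys$reduction_state
  red <- if (identical(red, "raw")) character() else
    strsplit(red, ",", fixed = TRUE)[[1]]
  md <- new_metadata(sample = keys$sample, instrument = keys$instrument,
                     reduction_state = red)
  if (!is.null(keys$q_window))
    md$q_window <- as.numeric(strsplit(keys$q_window, ",")[[1]])

  grid_matrix <- function(dat, axis2) {
    qg <- sort(unique(dat$q)); g2 <- sort(unique(dat[[axis2]]))
    if (nrow(dat) != length(qg) * length(g2))
      stop("incomplete (q, ", axis2, ") grid: ", nrow(dat), " rows for ",
           length(qg), " x ", length(g2), " grid", call. = FALSE)
    m_i <- matrix(NA_real_, length(qg), length(g2))
    m_s <- m_i
    i <- match(dat$q, qg); j <- match(dat[[axis2]], g2)
    m_i[cbind(i, j)] <- dat$intensity
    m_s[cbind(i, j)] <- dat$sigma
    list(q = qg, axis2 = g2, intensity = m_i, sigma = m_s)
  }

  if (file_kind == "qens") {
    g <- grid_matrix(dat, "omega")
    spectrum_set(g$q, g$axis2, g$intensity, g$sigma,
                 temperature = as.numeric(keys$temperature_K),
                 monitor = as.numeric(keys$monitor),
                 transmission = as.numeric(keys$transmission), metadata = md)
  } else if (file_kind == "elastic") {
    # reject out-of-order temperature blocks before silently regridding
    temps_seen <- dat$temperature[dat$q == dat$q[1]]
    if (any(diff(temps_seen) <= 0))
      stop("temperatures out of order in elastic NSTSV file", call. = FALSE)
    g <- grid_matrix(dat, "temperature")
    elastic_scan(g$q, g$axis2, g$intensity, g$sigma,
                 monitor = as.numeric(strsplit(keys$monitor, ",")[[1]]),
                 transmission = as.numeric(keys$transmission), metadata = md)
  } else {
    md$temperature <- as.numeric(keys$temperature_K)
    vanadium_ref(dat$q, dat$intensity, dat$sigma, metadata = md)
  }
}
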