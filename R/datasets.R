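# Dataset containers. All three are lists with numeric grids, intensity and
# sigma arrays and a metadata list carrying sample/instrument labels and
# reduction-state flags. Grids are ascending; intensities may be noisy around
# zero after reduction but sigmas are always >= 0.

REDUCTION_FLAGS <- c("monitor_normalized", "empty_cell_subtracted",
                     "vanadium_normalized")

new_metadata <- function(sample = "unknown", instrument = "unknown",
                         reduction_state = character(), ...) {
  list(sample = sample, instrument = instrument,
       reduction_state = reduction_state, ...)
}

#' Energy-resolved quasi-elastic spectrum set
#'
#' Holds S(Q, omega) with uncertainties on a (Q, omega) grid, plus
#' acquisition metadata.
#'
#' @param q Ascending momentum-transfer grid (1/A).
#' @param omega Ascending energy-transfer grid (ueV), symmetric about zero.
#' @param intensity,sigma Matrices of dimension \code{length(q) x length(omega)}.
#' @param temperature Sample temperature (K).
#' @param monitor Monitor counts (scalar).
#' @param transmission Sample transmission, in (0, 1].
#' @param metadata List with at least \code{sample}, \code{instrument} and
#'   \code{reduction_state} entries.
#' @return An object of class \code{spectrum_set}.
#' @export
spectrum_set <- function(q, omega, intensity, sigma, temperature,
                         monitor = 1, transmission = 1,
                         metadata = new_metadata()) {
  obj <- structure(list(q = as.numeric(q), omega = as.numeric(omega),
                        intensity = as.matrix(intensity),
                        sigma = as.matrix(sigma),
                        temperature = temperature, monitor = monitor,
                        transmission = transmission, metadata = metadata),
                   class = "spectrum_set")
  validate_dataset(obj)
}

#' Temperature-resolved elastic fixed-window scan
#'
#' Holds the elastic intensity S_el(Q, T) with uncertainties.
#'
#' @param q Ascending momentum-transfer grid (1/A).
#' @param temperatures Strictly increasing temperatures (K).
#' @param intensity,sigma Matrices \code{length(q) x length(temperatures)}.
#' @param monitor Monitor counts, one per temperature (recycled if scalar).
#' @inheritParams spectrum_set
#' @return An object of class \code{elastic_scan}.
#' @export
elastic_scan <- function(q, temperatures, intensity, sigma,
                         monitor = 1, transmission = 1,
                         metadata = new_metadata()) {
  monitor <- rep_len(as.numeric(monitor), length(temperatures))
  obj <- structure(list(q = as.numeric(q),
                        temperatures = as.numeric(temperatures),
                        intensity = as.matrix(intensity),
                        sigma = as.matrix(sigma),
                        monitor = monitor, transmission = transmission,
                        metadata = metadata),
                   class = "elastic_scan")
  validate_dataset(obj)
}

#' Vanadium calibration reference
#'
#' Per-Q elastic intensity of a vanadium standard (purely elastic,
#' incoherent scatterer whose signal is constant in Q up to detector
#' efficiency), used for absolute calibration and efficiency correction.
#'
#' @param q Ascending momentum-transfer grid (1/A).
#' @param intensity,sigma Numeric vectors along Q; intensities must be > 0.
#' @inheritParams spectrum_set
#' @return An object of class \code{vanadium_ref}.
#' @export
vanadium_ref <- function(q, intensity, sigma, metadata = new_metadata()) {
  obj <- structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                        sigma = as.numeric(sigma), metadata = metadata),
                   class = "vanadium_ref")
  validate_dataset(obj)
}

check_ascending <- function(x, what, strict = TRUE) {
  d <- diff(x)
  if (any(!is.finite(x)) || (strict && any(d <= 0)) || (!strict && any(d < 0)))
    stop(what, " must be finite and strictly increasing", call. = FALSE)
  invisible(x)
}

validate_dataset <- function(obj) {
  if (any(obj$sigma < 0, na.rm = TRUE))
    stop("negative sigma values are not allowed", call. = FALSE)
  md <- obj$metadata
  stopifnot(is.list(md), !is.null(md$sample), !is.null(md$instrument))
  if (!all(md$reduction_state %in% REDUCTION_FLAGS))
    stop("unknown reduction-state flag: ",
         paste(setdiff(md$reduction_state, REDUCTION_FLAGS), collapse = ", "),
         call. = FALSE)
  if (inherits(obj, "spectrum_set")) {
    check_ascending(obj$q, "q grid")
    check_ascending(obj$omega, "omega grid")
    step <- if (length(obj$omega) > 1) min(diff(obj$omega)) else Inf
    if (max(abs(obj$omega + rev(obj$omega))) > step / 2 + 1e-9)
      stop("omega grid must be symmetric about 0 within one grid step",
           call. = FALSE)
    if (!all(dim(obj$intensity) == c(length(obj$q), length(obj$omega))) ||
        !all(dim(obj$sigma) == dim(obj$intensity)))
      stop("intensity/sigma dimensions disagree with (q, omega) grid lengths",
           call. = FALSE)
    if (!(obj$transmission > 0 && obj$transmission <= 1))
      stop("transmission must lie in (0, 1]", call. = FALSE)
  } else if (inherits(obj, "elastic_scan")) {
    check_ascending(obj$q, "q grid")
    check_ascending(obj$temperatures, "temperatures")
    if (!all(dim(obj$intensity) == c(length(obj$q), length(obj$temperatures))) ||
        !all(dim(obj$sigma) == dim(obj$intensity)))
      stop("intensity/sigma dimensions disagree with (q, T) grid lengths",
           call. = FALSE)
    if (length(obj$monitor) != length(obj$temperatures) || any(obj$monitor <= 0))
      stop("monitor must be positive, one value per temperature", call. = FALSE)
    if (!(obj$transmission > 0 && obj$transmission <= 1))
      stop("transmission must lie in (0, 1]", call. = FALSE)
  } else if (inherits(obj, "vanadium_ref")) {
    check_ascending(obj$q, "q grid")
    if (length(obj$intensity) != length(obj$q) ||
        length(obj$sigma) != length(obj$q))
      stop("intensity/sigma lengths disagree with q grid", call. = FALSE)
    if (any(obj$intensity <= 0))
      stop("vanadium intensities must all be positive", call. = FALSE)
  } else stop("unknown dataset class")
  obj
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %s on %s, T = %.5g K\n", x$metadata$sample,
              x$metadata$instrument, x$temperature))
  cat(sprintf("  %d Q in [%.3g, %.3g] 1/A, %d omega in [%.4g, %.4g] ueV\n",
              length(x$q), min(x$q), max(x$q),
              length(x$omega), min(x$omega), max(x$omega)))
  cat("  reduction:", if (length(x$metadata$reduction_state))
    paste(x$metadata$reduction_state, collapse = ", ") else "raw", "\n")
  invisible(x)
}

#' @export
print.elastic_scan <- function(x, ...) {
  cat(sprintf("<elastic_scan> %s on %s\n", x$metadata$sample,
              x$metadata$instrument))
  cat(sprintf("  %d Q in [%.3g, %.3g] 1/A, %d T in [%.4g, %.4g] K\n",
              length(x$q), min(x$q), max(x$q), length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  cat("  reduction:", if (length(x$metadata$reduction_state))
    paste(x$metadata$reduction_state, collapse = ", ") else "raw", "\n")
  invisible(x)
}

#' @export
print.vanadium_ref <- function(x, ...) {
  cat(sprintf("<vanadium_ref> %d Q in [%.3g, %.3g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Restrict a dataset to a momentum-transfer window
#'
#' Keeps exactly the Q points with \code{q_lo <= Q <= q_hi} (closed
#' interval, no interpolation). The applied window is recorded in the
#' metadata.
#'
#' @param obj A \code{spectrum_set}, \code{elastic_scan} or \code{vanadium_ref}.
#' @param q_lo,q_hi Window bounds in 1/A, \code{q_lo < q_hi}.
#' @return An object of the same class containing only the selected Q points.
#' @export
restrict_q <- function(obj, q_lo, q_hi) {
  stopifnot(is.numeric(q_lo), is.numeric(q_hi), q_lo < q_hi)
  keep <- obj$q >= q_lo & obj$q <= q_hi
  if (!any(keep))
    stop(sprintf("no Q points in [%g, %g]; available Q range is [%g, %g]",
                 q_lo, q_hi, min(obj$q), max(obj$q)), call. = FALSE)
  out <- obj
  out$q <- obj$q[keep]
  if (inherits(obj, "vanadium_ref")) {
    out$intensity <- obj$intensity[keep]
    out$sigma <- obj$sigma[keep]
  } else {
    out$intensity <- obj$intensity[keep, , drop = FALSE]
    out$sigma <- obj$sigma[keep, , drop = FALSE]
  }
  out$metadata$q_window <- c(q_lo, q_hi)
  validate_dataset(out)
}
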