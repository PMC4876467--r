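#' Cumulative dose-volume histogram for a single structure
#'
#' Constructs and validates a cumulative DVH: an ordered table of
#' (dose, volume) points where `volume` is the absolute structure volume
#' (cc) receiving *at least* `dose` (Gy). The first volume is the total
#' structure volume; volumes are non-increasing and doses strictly
#' increasing. Differential DVHs are not accepted.
#'
#' @param dose_gy numeric vector of dose points in Gy, strictly increasing.
#' @param volume_cc numeric vector of absolute volumes in cc, non-increasing,
#'   same length as `dose_gy`.
#' @param structure_id character label for the structure.
#' @return An object of class `dvh_curve`: a list with elements
#'   `structure_id`, `dose_gy`, `volume_cc`.
#' @examples
#' cv <- dvh_curve(c(0, 50, 70, 75), c(100, 50, 1, 0))
#' dose_at_volume(cv, 1)    # 70
#' volume_at_dose(cv, 60)   # 25.5
#' @export
dvh_curve <- function(dose_gy, volume_cc, structure_id = "structure") {
  dose_gy <- as.numeric(dose_gy)
  volume_cc <- as.numeric(volume_cc)
  if (length(dose_gy) != length(volume_cc))
    stop("dose and volume vectors must have equal length")
  if (length(dose_gy) < 2)
    stop("a DVH curve needs at least two points")
  if (anyNA(dose_gy) || anyNA(volume_cc))
    stop("DVH contains missing values")
  if (any(diff(dose_gy) <= 0))
    stop("dose not increasing: dose column must be strictly increasing")
  if (any(volume_cc < 0))
    stop("negative volume in DVH")
  if (any(diff(volume_cc) > 1e-9))
    stop("volume must be non-increasing for a cumulative DVH")
  structure(list(structure_id = as.character(structure_id),
                 dose_gy = dose_gy, volume_cc = volume_cc),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("Cumulative DVH for '", x$structure_id, "': ",
      length(x$dose_gy), " points, TLV = ",
      format(x$volume_cc[1], digits = 5), " cc, Dmax = ",
      format(max(x$dose_gy), digits = 5), " Gy\n", sep = "")
  invisible(x)
}

#' Read a cumulative DVH from CSV
#'
#' Expects a two-column numeric CSV with header `dose_gy,volume_cc`
#' (doses in Gy, absolute volumes in cc), one structure per file.
#'
#' @param path path to the CSV file.
#' @param structure_id optional structure label; defaults to the file name.
#' @return A validated [dvh_curve()].
#' @export
read_dvh <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("DVH file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("dose_gy", "volume_cc")
  if (!all(need %in% names(tab)))
    stop("DVH file must have header 'dose_gy,volume_cc'")
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  dvh_curve(tab$dose_gy, tab$volume_cc, structure_id = structure_id)
}

#' Write a cumulative DVH to CSV
#'
#' Inverse of [read_dvh()]; the round trip reproduces the points exactly.
#'
#' @param curve a [dvh_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  utils::write.csv(
    data.frame(dose_gy = curve$dose_gy, volume_cc = curve$volume_cc),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total structure volume of a DVH
#' @param curve a [dvh_curve()].
#' @return Volume in cc (the volume at dose 0).
#' @export
dvh_total_volume <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  curve$volume_cc[1]
}

#' Inverse DVH lookup: dose received by the hottest x cc
#'
#' Returns the dose D such that a volume of exactly `x` cc receives at
#' least D, by linear interpolation between the bracketing curve points
#' (the D_xcc family of metrics). `x = 0` returns the maximum point dose.
#' On a flat (tied-volume) segment the largest dose of the segment is
#' returned.
#'
#' @param curve a [dvh_curve()].
#' @param x volume in cc, `0 <= x <=` total volume.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (length(x) > 1) return(vapply(x, function(xx) dose_at_volume(curve, xx),
                                   numeric(1)))
  tlv <- curve$volume_cc[1]
  if (is.na(x) || x < 0) stop("volume must be non-negative")
  if (x > tlv + 1e-9) stop("requested volume exceeds total structure volume")
  v <- curve$volume_cc; d <- curve$dose_gy
  j <- max(which(v >= x - 1e-12))           # last point with volume >= x
  if (j == length(v) || abs(v[j] - x) <= 1e-12) {
    # exact hit (rightmost index handles flat segments) or beyond curve tail
    return(d[j])
  }
  # interpolate between (d[j], v[j]) and (d[j+1], v[j+1]), v[j] > x > v[j+1]
  d[j] + (v[j] - x) / (v[j] - v[j + 1]) * (d[j + 1] - d[j])
}

#' DVH lookup: volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative curve (the V_x family of
#' metrics, in absolute cc). Doses beyond the curve return 0; dose 0
#' returns the total volume.
#'
#' @param curve a [dvh_curve()].
#' @param d dose in Gy, `d >= 0`.
#' @return Volume in cc.
#' @export
volume_at_dose <- function(curve, d) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (length(d) > 1) return(vapply(d, function(dd) volume_at_dose(curve, dd),
                                   numeric(1)))
  if (is.na(d) || d < 0) stop("dose must be non-negative")
  dd <- curve$dose_gy; v <- curve$volume_cc
  if (d > dd[length(dd)]) return(0)
  if (d <= dd[1]) return(v[1])
  stats::approx(dd, v, xout = d, method = "linear", ties = "ordered")$y
}

#' Summarise a DVH into the 15 standard dosimetric metrics
#'
#' Computes the temporal-lobe volume (tlv), maximum point dose (d_max,
#' the largest dose coordinate of the curve), mean and median dose,
#' D_xcc for x in {0.1, 1, 5, 10, 20} cc, and V_x for x in
#' {40, 50, 60, 65, 70, 75} Gy in absolute cc. The mean dose is
#' `(1/tlv) * integral of V(d) dd` by the trapezoid rule over the curve
#' points; the median dose is the inverse lookup at half the volume.
#'
#' @param curve a [dvh_curve()].
#' @return A one-row data.frame of class `dose_metrics` with columns
#'   `tlv, d_max, mean_dose, median_dose, d_0.1cc, d_1cc, d_5cc, d_10cc,
#'   d_20cc, v_40, v_50, v_60, v_65, v_70, v_75`.
#' @export
dvh_metrics <- function(curve) {
  out <- as.data.frame(as.list(dvh_metrics_vector(curve)),
                       check.names = FALSE, optional = TRUE)
  class(out) <- c("dose_metrics", "data.frame")
  out
}

# named numeric version, used internally where data.frame overhead matters
dvh_metrics_vector <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  tlv <- curve$volume_cc[1]
  if (tlv <= 0) stop("degenerate structure: total volume is zero")
  d <- curve$dose_gy; v <- curve$volume_cc
  nn <- length(d)
  mean_dose <- sum(diff(d) * (v[-nn] + v[-1]) / 2) / tlv
  dxcc <- c(0.1, 1, 5, 10, 20)
  dx <- vapply(dxcc, function(x) {
    if (x > tlv) return(NA_real_)   # structure smaller than the probe volume
    dose_at_volume(curve, x)
  }, numeric(1))
  vx <- vapply(c(40, 50, 60, 65, 70, 75),
               function(g) volume_at_dose(curve, g), numeric(1))
  c(tlv = tlv, d_max = d[nn], mean_dose = mean_dose,
    median_dose = dose_at_volume(curve, tlv / 2),
    "d_0.1cc" = dx[1], d_1cc = dx[2], d_5cc = dx[3], d_10cc = dx[4],
    d_20cc = dx[5],
    v_40 = vx[1], v_50 = vx[2], v_60 = vx[3], v_65 = vx[4], v_70 = vx[5],
    v_75 = vx[6])
}

#' Names of the 15 DVH-derived metrics
#' @return Character vector of metric column names.
#' @export
dvh_metric_names <- function() {
  c("tlv", "d_max", "mean_dose", "median_dose",
    "d_0.1cc", "d_1cc", "d_5cc", "d_10cc", "d_20cc",
    "v_40", "v_50", "v_60", "v_65", "v_70", "v_75")
}
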