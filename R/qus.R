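# Per-line quantitative ultrasound parameters and per-explant summaries.

#' Pulse-echo time of flight to depth
#'
#' Converts a round-trip time of flight to one-way depth, `depth = c t / 2`.
#' With the 1500 m/s PBS sound speed, 16.93 us maps to the 12.7 mm focal
#' depth of the 35 MHz transducer and 67.73 us to the 50.8 mm focal depth of
#' the 15 MHz transducer.
#'
#' @param t_roundtrip Round-trip time(s) of flight, s (>= 0).
#' @param c Speed of sound, m/s.
#' @return Depth(s) in m.
#' @export
#' @examples
#' tof_to_depth(16.93e-6, 1500) * 1000  # ~12.7 mm
tof_to_depth <- function(t_roundtrip, c = 1500) {
  if (any(t_roundtrip < 0)) stop_cbi("time of flight must be >= 0.")
  assert_scalar_num(c, "c", 0, strict_lower = TRUE)
  c * t_roundtrip / 2
}

#' Axial resolution of a pulse-echo system
#'
#' `c / (2 f)`: about 23 um at 35 MHz and 53 um at 15 MHz for cartilage
#' (1600 m/s).
#'
#' @param f Center frequency, Hz.
#' @param c Speed of sound, m/s (default cartilage, 1600).
#' @return Axial resolution in m.
#' @export
axial_resolution <- function(f, c = 1600) {
  if (any(f <= 0)) stop_cbi("frequency must be > 0.")
  c / (2 * f)
}

#' Delta: ultrasound cartilage thickness
#'
#' Half the round-trip time between the AC and CBI peaks times a constant
#' cartilage sound speed (1600 m/s by default). Operates on QC-passing rows
#' of a peaks table.
#'
#' @param peaks Tibble from [detect_volume_peaks()] (or one row from
#'   [detect_line_peaks()]); every row must have `qc_pass = TRUE`.
#' @param c_cartilage Cartilage sound speed, m/s.
#' @return The peaks tibble with a `delta_mm` column appended.
#' @export
compute_delta <- function(peaks, c_cartilage = 1600) {
  if (!all(peaks$qc_pass)) {
    bad <- peaks$qc_reason[!peaks$qc_pass]
    stop_cbi("QC-failed line(s) passed to compute_delta (reasons: %s).",
             paste(unique(bad), collapse = ", "))
  }
  if (any(peaks$cbi_time <= peaks$ac_time)) {
    stop_cbi("cbi_time must exceed ac_time on every line.")
  }
  dplyr::mutate(peaks,
                delta_mm = c_cartilage * (.data$cbi_time - .data$ac_time) / 2 * 1000)
}

#' Alpha: backscatter upswing at the mineral front
#'
#' The dB difference between the CBI peak and a point `offset` micrometers
#' shallower (converted to time with the cartilage sound speed and rounded
#' to the nearest sample), divided by the offset in mm. High values indicate
#' a sharp rise in backscatter at the mineral front. Lines whose pre-point
#' falls before the AC peak or outside the window get `NA` (excluded, not
#' raised).
#'
#' @param env_db_line dB envelope samples of one scan line.
#' @param peaks One-row peaks tibble for that line (`qc_pass` required).
#' @param grid The [scan_grid()].
#' @param offset Pre-point offset in um (default 200).
#' @param c_cartilage Cartilage sound speed, m/s.
#' @return Alpha in dB/mm (scalar), or `NA` if the pre-point is invalid.
#' @export
compute_alpha <- function(env_db_line, peaks, grid, offset = 200,
                          c_cartilage = 1600) {
  stopifnot(nrow(peaks) == 1L)
  if (!peaks$qc_pass) {
    stop_cbi("QC-failed line passed to compute_alpha (reason: %s).",
             peaks$qc_reason)
  }
  cbi_idx <- round(time_to_index(peaks$cbi_time, grid))
  lag <- round(2 * offset * 1e-6 / c_cartilage * grid$sampling_rate)
  pre_idx <- cbi_idx - lag
  pre_time <- index_to_time(pre_idx, grid)
  if (pre_idx < 1L || pre_time <= peaks$ac_time) return(NA_real_)
  (env_db_line[cbi_idx] - env_db_line[pre_idx]) / (offset / 1000)
}

#' CBI backscatter intensity
#'
#' The dB amplitude of the CBI peak (relative to the volume maximum, so
#' always <= 0).
#'
#' @inheritParams compute_alpha
#' @return Intensity in dB (scalar).
#' @export
compute_cbi_intensity <- function(env_db_line, peaks, grid) {
  stopifnot(nrow(peaks) == 1L)
  if (!peaks$qc_pass) {
    stop_cbi("QC-failed line passed to compute_cbi_intensity (reason: %s).",
             peaks$qc_reason)
  }
  env_db_line[round(time_to_index(peaks$cbi_time, grid))]
}

#' All three QUS parameters for every accepted line of a volume
#'
#' Convenience layer over [compute_delta()], [compute_alpha()] and
#' [compute_cbi_intensity()]: takes the envelope volume and its peaks table,
#' keeps the QC-passing lines, and returns one record per line.
#'
#' @param env A `qus_envelope`.
#' @param peaks Tibble from [detect_volume_peaks()].
#' @param c_cartilage Cartilage sound speed, m/s.
#' @param alpha_offset Alpha pre-point offset, um.
#' @return Tibble with columns `ix`, `iy`, `delta_mm`, `alpha_db_per_mm`
#'   (`NA` where the pre-point was invalid), `cbi_db`.
#' @export
compute_qus <- function(env, peaks, c_cartilage = 1600, alpha_offset = 200) {
  stopifnot(inherits(env, "qus_envelope"))
  grid <- env$grid
  ok <- dplyr::filter(peaks, .data$qc_pass)
  if (nrow(ok) == 0L) {
    return(tibble(ix = integer(), iy = integer(), delta_mm = numeric(),
                  alpha_db_per_mm = numeric(), cbi_db = numeric()))
  }
  ok <- compute_delta(ok, c_cartilage)
  cbi_idx <- round(time_to_index(ok$cbi_time, grid))
  lag <- round(2 * alpha_offset * 1e-6 / c_cartilage * grid$sampling_rate)
  pre_idx <- cbi_idx - lag
  flat <- function(idx_t) {
    env$env_db[cbind(ok$ix, ok$iy, idx_t)]
  }
  cbi_db <- flat(cbi_idx)
  alpha <- rep(NA_real_, nrow(ok))
  pre_time <- index_to_time(pre_idx, grid)
  valid <- pre_idx >= 1L & pre_time > ok$ac_time
  if (any(valid)) {
    alpha[valid] <- (cbi_db[valid] - flat(pmax(pre_idx, 1L))[valid]) /
      (alpha_offset / 1000)
  }
  tibble(ix = ok$ix, iy = ok$iy, delta_mm = ok$delta_mm,
         alpha_db_per_mm = alpha, cbi_db = cbi_db)
}

#' Summarize QUS records for one explant scan
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' QUS parameter over the accepted lines; the sd of a single record is 0 by
#' convention so summaries are always defined. Lines with `NA` Alpha are
#' omitted from the Alpha moments only.
#'
#' @param records Tibble from [compute_qus()] (>= 1 row).
#' @param label Free-text scan label.
#' @return One-row tibble: `scan_label`, `n_lines`, `delta_mean`,
#'   `delta_sd` (mm), `alpha_mean`, `alpha_sd` (dB/mm), `cbi_mean`,
#'   `cbi_sd` (dB).
#' @export
summarize_explant <- function(records, label = "") {
  if (nrow(records) < 1L) stop_cbi("no QUS records to summarize.")
  sd0 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1L) 0 else stats::sd(x)
  }
  tibble(
    scan_label = label,
    n_lines = nrow(records),
    delta_mean = mean(records$delta_mm),
    delta_sd = sd0(records$delta_mm),
    alpha_mean = mean(records$alpha_db_per_mm, na.rm = TRUE),
    alpha_sd = sd0(records$alpha_db_per_mm),
    cbi_mean = mean(records$cbi_db),
    cbi_sd = sd0(records$cbi_db)
  )
}

#' Pair per-line QUS records from two scans of the same explant
#'
#' Joins two record tables by grid position (the holders fix sample
#' orientation between scans, so positions correspond) and returns per-line
#' differences `b - a`. Lines failing QC in either scan are absent from
#' their table and hence dropped by the inner join.
#'
#' @param a,b Tibbles from [compute_qus()] for the two scans.
#' @return Tibble with `ix`, `iy`, `d_delta_mm`, `d_alpha_db_per_mm`,
#'   `d_cbi_db`.
#' @export
pair_qus_records <- function(a, b) {
  j <- dplyr::inner_join(a, b, by = c("ix", "iy"), suffix = c("_a", "_b"))
  dplyr::transmute(
    j,
    ix = .data$ix, iy = .data$iy,
    d_delta_mm = .data$delta_mm_b - .data$delta_mm_a,
    d_alpha_db_per_mm = .data$alpha_db_per_mm_b - .data$alpha_db_per_mm_a,
    d_cbi_db = .data$cbi_db_b - .data$cbi_db_a
  )
}
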