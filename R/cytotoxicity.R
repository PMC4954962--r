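#' Read a wide-format growth CSV
#'
#' Bioscreen-style export: a `time_h` column followed by one OD column per
#' well.
#'
#' @param path CSV file.
#' @return data.frame with `time_h` first.
#' @export
read_growth_csv <- function(path) {
  od <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(od)) stop("growth CSV needs a time_h column")
  od
}

#' Estimate the generation (doubling) time from a growth curve
#'
#' Blank-corrected OD is floored at `od_floor`, log2-transformed, and the
#' maximal least-squares slope over sliding windows of `window_points`
#' samples gives the exponential-phase rate; the doubling time is its
#' reciprocal. Windows with a poor log-linear fit (`r2 < r2_min`, noise- or
#' curvature-dominated) are excluded when any window passes the gate, which
#' keeps the max-slope rule from locking onto noise spikes at low OD.
#'
#' @param times Numeric vector of hours (uniform, increasing).
#' @param od Numeric vector of OD readings.
#' @param blank Optical blank: a number, or `"first3"` for the median of the
#'   first three readings (use for raw, uncorrected plates). Default 0: the
#'   curve is already blank-corrected.
#' @param window_points Sliding-window length (default 9 = 4 h at 0.5-h
#'   sampling).
#' @param od_floor Floor applied to blank-corrected OD before the log.
#' @param r2_min Fit-quality gate on candidate windows.
#' @param min_od_frac Candidate windows must lie entirely above this fraction
#'   of the curve's blank-corrected maximum. OD noise is additive, so
#'   relative noise diverges at low density; without this guard the max-slope
#'   rule locks onto noise-inflated slopes near the detection floor.
#' @return List of class `generation_time`: `g_hours`, `window` (start/end
#'   indices), `fit_r2`, `blank_od`.
#' @export
generation_time <- function(times, od, blank = 0, window_points = 9L,
                            od_floor = 1e-4, r2_min = 0.98,
                            min_od_frac = 0.1) {
  stopifnot(length(times) == length(od), length(od) >= window_points,
            window_points >= 3, all(diff(times) > 0))
  blank_od <- if (identical(blank, "first3")) stats::median(od[1:3]) else blank
  if (blank_od >= max(od)) stop("blank exceeds the curve maximum")
  odc <- pmax(od - blank_od, od_floor)
  y <- log2(odc)
  n <- length(y)
  w <- window_points
  tw <- times[1:w]
  sxx <- sum((tw - mean(tw))^2)  # uniform grid: same for every window
  starts <- 1:(n - w + 1)
  od_gate <- min_od_frac * max(odc)
  slope <- r2 <- numeric(length(starts))
  ok_od <- logical(length(starts))
  for (s in starts) {
    yy <- y[s:(s + w - 1)]
    tt <- times[s:(s + w - 1)]
    b <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    slope[s] <- b
    ssy <- sum((yy - mean(yy))^2)
    r2[s] <- if (ssy == 0) 1 else b^2 * sxx / ssy
    ok_od[s] <- all(odc[s:(s + w - 1)] >= od_gate)
  }
  ok <- r2 >= r2_min & slope > 0 & ok_od
  cand <- if (any(ok)) which(ok) else which(slope > 0)
  if (length(cand) == 0) stop("no window with positive growth: no growth detected")
  best <- cand[which.max(slope[cand])]
  structure(list(g_hours = 1 / slope[best],
                 window = c(start = best, end = best + w - 1L),
                 fit_r2 = min(r2[best], 1), blank_od = blank_od),
            class = "generation_time")
}

#' Generation times for every well of a growth table
#'
#' @param od Wide growth data.frame ([read_growth_csv()] /
#'   [generate_growth_curves()] `$od`).
#' @param map Well map data.frame (well, strain_id, construct, replicate).
#' @param ... Passed to [generation_time()].
#' @return data.frame: well, strain_id, construct, replicate, g_hours,
#'   fit_r2, blank_od.
#' @export
generation_times <- function(od, map, ...) {
  out <- lapply(seq_len(nrow(map)), function(i) {
    w <- map$well[i]
    if (!w %in% names(od)) stop("well ", w, " missing from growth table")
    gt <- generation_time(od$time_h, od[[w]], ...)
    data.frame(well = w, strain_id = map$strain_id[i],
               construct = map$construct[i], replicate = map$replicate[i],
               g_hours = gt$g_hours, fit_r2 = gt$fit_r2,
               blank_od = gt$blank_od, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Synthetic-sick cytotoxicity test
#'
#' Per replicate, `delta_g` is the generation-time increase caused by
#' synphilin-1 expression: `g(dsRed_SY1) - g(dsRed_only)`. The mutant's
#' replicate `delta_g` sample is compared with the wild type's by Student's
#' t-test; `delta_delta_g` is the difference of their means. A significantly
#' positive excess marks a synthetic sick interaction.
#'
#' @param gtimes Generation-time table from [generation_times()], holding
#'   both constructs for the mutant and the wild type.
#' @param strain Mutant strain_id.
#' @param wt_strain Wild-type strain_id.
#' @param alpha Significance cutoff.
#' @return One-row data.frame: strain_id, delta_g_mean, delta_g_sd,
#'   wt_delta_g_mean, delta_delta_g, p, significant.
#' @export
toxicity_test <- function(gtimes, strain, wt_strain, alpha = 0.05) {
  delta_for <- function(id) {
    sub <- gtimes[gtimes$strain_id == id, , drop = FALSE]
    sy <- sub[sub$construct == "dsRed_SY1", , drop = FALSE]
    ct <- sub[sub$construct == "dsRed_only", , drop = FALSE]
    if (nrow(sy) == 0 || nrow(ct) == 0)
      stop("strain ", id, " is missing a construct (need dsRed_SY1 and dsRed_only)")
    sy <- sy[order(sy$replicate), ]; ct <- ct[order(ct$replicate), ]
    reps <- intersect(sy$replicate, ct$replicate)
    if (length(reps) < 2) stop("strain ", id, " has < 2 paired replicates")
    sy$g_hours[match(reps, sy$replicate)] - ct$g_hours[match(reps, ct$replicate)]
  }
  dm <- delta_for(strain)
  dw <- delta_for(wt_strain)
  tt <- students_t(dm, dw)
  data.frame(strain_id = strain, delta_g_mean = mean(dm),
             delta_g_sd = stats::sd(dm), wt_delta_g_mean = mean(dw),
             delta_delta_g = mean(dm) - mean(dw), p = tt$p,
             significant = tt$p <= alpha, stringsAsFactors = FALSE)
}
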