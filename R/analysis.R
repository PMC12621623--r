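## Observables computed from run records: signed force profiles, contact
## counts, detachment events and order, per-spatula adhesion minima,
## sliding velocity, and apparent friction coefficients.
##
## Sign convention throughout: compression positive, adhesion (tension)
## negative; an "adhesion force" quoted in text is the magnitude of the
## most negative force, |F_min|.

#' Per-spatula adhesion minima and the two averaging conventions
#'
#' For each spatula, the most negative substrate force during pull-off and
#' its time. Two per-spatula averages are reported: the naive convention
#' divides the seta-level minimum by the number of spatulae (as if all
#' detached simultaneously), while the per-spatula convention averages
#' each spatula's own |F_min|. Because individual minima are not
#' simultaneous, the per-spatula average is never below the naive one.
#'
#' @param run a [run_protocol()] result (or any list with `seta` and
#'   `spatula` tibbles covering a pull-off phase).
#' @return list with `per_spatula` (tibble: spatula, F_min, `|F_min|`,
#'   time_ns, in_contact), `naive_average`, `per_spatula_average` (nN,
#'   magnitudes), and `seta_min` (signed, nN).
#' @export
per_spatula_minima <- function(run) {
  po <- dplyr::filter(run$spatula, .data$phase == "pulloff")
  if (nrow(po) == 0) stop("run record contains no pull-off phase",
                          call. = FALSE)
  per <- po |>
    dplyr::group_by(.data$spatula) |>
    dplyr::summarise(
      F_min = min(.data$f_sub),
      time_ns = .data$time_ns[which.min(.data$f_sub)],
      in_contact = any(.data$contacts > 0), .groups = "drop") |>
    dplyr::mutate(F_min_abs = abs(.data$F_min))
  if (any(!per$in_contact))
    warning("spatula(e) ", paste(per$spatula[!per$in_contact],
                                 collapse = ", "),
            " never contacted the substrate; excluded from the per-spatula average",
            call. = FALSE)
  seta_po <- dplyr::filter(run$seta, .data$phase == "pulloff")
  seta_min <- min(seta_po$f_sub)
  n_spat <- run$n_spat %||% dplyr::n_distinct(run$spatula$spatula)
  list(per_spatula = per,
       naive_average = abs(seta_min) / n_spat,
       per_spatula_average = mean(per$F_min_abs[per$in_contact]),
       seta_min = seta_min)
}

#' Detect spatula detachment events
#'
#' A spatula counts as detached at the first load step at which its
#' contact count reaches zero and stays zero (transient contact loss, e.g.
#' during a tip slip, does not register). Events are ordered by time;
#' detachment time is the load step times the load-step duration.
#'
#' @param run a [run_protocol()] result.
#' @param confirm minimum length of the trailing zero-contact run unless
#'   it reaches the end of the record.
#' @return tibble of class `detachment_events`, ordered by detachment
#'   time: spatula, orientation, contact mode, detach_step, detach_time_ns,
#'   peak adhesion `F_min_abs` (nN) and its `peak_time_ns`.
#' @export
detect_detachment <- function(run, confirm = 3L) {
  dt_ls <- run$dt_ls_ns
  ev <- run$spatula |>
    dplyr::group_by(.data$spatula) |>
    dplyr::group_map(function(df, key) {
      cz <- df$contacts
      nz <- which(cz > 0)
      if (length(nz) == 0 || max(nz) == length(cz)) return(NULL)
      det_i <- max(nz) + 1L  # stays-zero rule: after the last contact
      if (length(cz) - det_i + 1L < confirm && cz[length(cz)] != 0)
        return(NULL)
      po <- df[df$phase == "pulloff" & df$step <= df$step[det_i], ]
      if (nrow(po) == 0) return(NULL)
      imin <- which.min(po$f_sub)
      tibble::tibble(
        spatula = key$spatula,
        orientation = df$orientation[1],
        mode = ifelse(df$orientation[1] == "tip_first", "tip-dominant",
                      "pad-dominant"),
        detach_step = df$step[det_i],
        detach_time_ns = df$step[det_i] * dt_ls,
        F_min_abs = abs(po$f_sub[imin]),
        peak_time_ns = po$time_ns[imin])
    }) |>
    dplyr::bind_rows()
  if (nrow(ev) == 0)
    ev <- tibble::tibble(spatula = integer(), orientation = character(),
                         mode = character(), detach_step = integer(),
                         detach_time_ns = numeric(), F_min_abs = numeric(),
                         peak_time_ns = numeric())
  out <- dplyr::arrange(ev, .data$detach_time_ns)
  class(out) <- c("detachment_events", class(out))
  out
}

#' Sliding velocity from a displacement series
#'
#' Least-squares slope of a lateral (X) group position against time over a
#' window; since positions are in nm and time in ns, the slope is directly
#' in m/s.
#'
#' @param time_ns time stamps, ns.
#' @param x_nm positions (e.g. mean pad X coordinate), nm.
#' @param window optional length-2 time range (ns) restricting the fit.
#' @return list with `velocity_m_s`, `se` (standard error), `n`.
#' @export
sliding_velocity <- function(time_ns, x_nm, window = NULL) {
  if (!is.null(window)) {
    sel <- time_ns >= window[1] & time_ns <= window[2]
    time_ns <- time_ns[sel]; x_nm <- x_nm[sel]
  }
  n <- length(time_ns)
  if (n < 3)
    stop("sliding-velocity window holds fewer than 3 samples", call. = FALSE)
  tc <- time_ns - mean(time_ns)
  slope <- sum(tc * x_nm) / sum(tc^2)
  res <- x_nm - mean(x_nm) - slope * tc
  se <- sqrt(sum(res^2) / (n - 2) / sum(tc^2))
  list(velocity_m_s = slope, se = se, n = n)
}

#' Apparent friction coefficient
#'
#' Ratio of the mean lateral to the mean normal substrate force magnitude
#' over a window. Windows in which the normal force changes sign are
#' rejected (the ratio would be ill-defined).
#'
#' @param f_lat lateral (X) force series, nN.
#' @param f_norm normal (Y) force series, nN; must not cross zero.
#' @return friction coefficient (dimensionless).
#' @export
friction_coefficient <- function(f_lat, f_norm) {
  stopifnot(length(f_lat) == length(f_norm), length(f_norm) >= 1)
  if (min(f_norm) < 0 && max(f_norm) > 0)
    stop("normal force changes sign over the window; choose a window with a definite contact state",
         call. = FALSE)
  if (all(f_norm == 0)) stop("normal force is zero over the window",
                             call. = FALSE)
  mean(abs(f_lat)) / mean(abs(f_norm))
}

#' Summarise a pull-off run
#'
#' Computes the standard report: detachment events and order, per-spatula
#' adhesion minima under both averaging conventions, per-orientation
#' adhesion, sliding velocities of the pad-dominant spatulae over the
#' steady pull-off window, and the apparent friction coefficient.
#'
#' @param run a [run_protocol()] result.
#' @param sliding_window optional length-2 time range (ns) for the sliding
#'   fit; defaults to the stretch of the pull-off phase before the first
#'   detachment.
#' @return list of class `seta_report`: `events`, `minima`, `sliding`
#'   (per-spatula tibble), `sliding_velocity_m_s`, `friction`, `summary`
#'   (one-row tibble).
#' @export
analyze_run <- function(run, sliding_window = NULL) {
  ev <- detect_detachment(run)
  mins <- per_spatula_minima(run)

  po <- dplyr::filter(run$seta, .data$phase == "pulloff")
  first_det <- if (nrow(ev) > 0) min(ev$detach_time_ns) else max(po$time_ns)
  if (is.null(sliding_window))
    sliding_window <- c(min(po$time_ns), first_det)

  pad_sp <- unique(run$spatula$spatula[run$spatula$orientation ==
                                         "pad_parallel"])
  sliding <- dplyr::bind_rows(lapply(pad_sp, function(s) {
    df <- dplyr::filter(run$spatula, .data$spatula == s,
                        .data$phase == "pulloff",
                        .data$time_ns >= sliding_window[1],
                        .data$time_ns <= sliding_window[2],
                        .data$contacts > 0)
    if (nrow(df) < 3) return(NULL)
    sv <- sliding_velocity(df$time_ns, df$pad_x)
    tibble::tibble(spatula = s, velocity_m_s = sv$velocity_m_s, se = sv$se,
                   n = sv$n)
  }))

  ## apparent friction over the adhesive (tensile) sliding window
  fr <- dplyr::filter(po, .data$time_ns >= sliding_window[1],
                      .data$time_ns <= sliding_window[2],
                      .data$f_sub < 0)
  friction <- if (nrow(fr) >= 3)
    tryCatch(friction_coefficient(fr$f_sub_x, fr$f_sub),
             error = function(e) NA_real_) else NA_real_

  summary <- tibble::tibble(
    n_spatulae = run$n_spat,
    load_steps = max(run$seta$step),
    duration_ns = max(run$seta$time_ns),
    peak_compression_nN = max(run$seta$f_sub),
    seta_min_nN = mins$seta_min,
    naive_average_nN = mins$naive_average,
    per_spatula_average_nN = mins$per_spatula_average,
    n_detached = nrow(ev),
    mean_sliding_velocity_m_s = if (nrow(sliding) > 0)
      mean(abs(sliding$velocity_m_s)) else NA_real_,
    friction_coefficient = friction)

  structure(list(events = ev, minima = mins, sliding = sliding,
                 sliding_window = sliding_window, friction = friction,
                 summary = summary),
            class = "seta_report")
}

#' @export
print.seta_report <- function(x, ...) {
  cat("<seta_report>\n")
  print(x$summary)
  cat("detachment order:", paste(x$events$spatula, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.seta_run
#' @export
tidy.seta_run <- function(x, ...) x$spatula

#' Tidy and summary methods for run records
#'
#' `tidy()` returns the long per-load-step, per-spatula tibble; `glance()`
#' a one-row summary of the run.
#'
#' @param x a [run_protocol()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.seta_run <- function(x, ...) {
  po <- x$seta[x$seta$phase == "pulloff", ]
  tibble::tibble(
    n_spatulae = x$n_spat,
    load_steps = max(x$seta$step),
    duration_ns = max(x$seta$time_ns),
    preload_end_step = unname(x$phase_end["preload"]),
    peak_compression_nN = max(x$seta$f_sub),
    peak_adhesion_nN = if (nrow(po) > 0) abs(min(po$f_sub)) else NA_real_,
    detached = all(utils::tail(x$seta$contacts, 1) == 0))
}

#' Export a run record
#'
#' Writes the per-load-step table as CSV and the parameters, seeds and
#' phase summaries as JSON.
#'
#' @param run a [run_protocol()] result.
#' @param csv_path,json_path output paths (`NULL` skips either).
#' @return invisibly, the paths written.
#' @export
write_run_record <- function(run, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(run$seta, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      seed = run$seed, n_spatulae = run$n_spat,
      dt_ls_ns = run$dt_ls_ns,
      protocol = unclass(run$protocol),
      phase_end = as.list(run$phase_end),
      glance = glance.seta_run(run)), json_path,
      auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
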