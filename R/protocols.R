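#' Dynamic restitution curve (steady-state downsweep)
#'
#' Paces to steady state at each cycle length of a decreasing grid and
#' records the steady (DI, APD) pair; the scan is warm-started from the
#' previous steady state. When the settling detects a period-2 (alternans)
#' regime, the point is marked and the scan stops (default) or continues.
#'
#' @param model a [cell_model()].
#' @param bcl_grid decreasing vector of basic cycle lengths (ms).
#' @param rel_tol,max_beats settling controls, see [settle()].
#' @param eigen if `TRUE`, attach per-BCL eigenmode columns (`lambda_alt_re`,
#'   `lambda_alt_im`, `lambda_mem_re`, `tau_mem_beats`).
#' @param stop_on_alternans stop the scan at the first alternans mark.
#'
#' @return Tibble of class `restitution_curve` with columns `bcl_ms`,
#'   `di_ms`, `apd_ms`, `status`; attribute `slope_at_operating_point`
#'   (centred finite difference of APD vs DI at the middle of the curve)
#'   and attribute `kind = "dynamic"`.
#' @export
dynamic_restitution <- function(model, bcl_grid, rel_tol = 1e-7,
                                max_beats = 1000, eigen = FALSE,
                                stop_on_alternans = TRUE) {
  if (is.unsorted(rev(bcl_grid), strictly = TRUE)) {
    abort("`bcl_grid` must be strictly decreasing.",
          class = "stochpace_input_error")
  }
  state <- init_state(model)
  rows <- list()
  for (b in bcl_grid) {
    res <- tryCatch(settle(model, b, rel_tol, max_beats, state0 = state),
                    stochpace_alternans = function(e) e,
                    stochpace_no_convergence = function(e) e,
                    stochpace_capture_error = function(e) e)
    if (inherits(res, "stochpace_alternans")) {
      rows[[length(rows) + 1]] <- tibble(
        bcl_ms = b, di_ms = NA_real_, apd_ms = NA_real_,
        status = "alternans")
      if (stop_on_alternans) break else next
    }
    if (inherits(res, "stochpace_no_convergence")) {
      # settling stalls very close to the bifurcation; record and move on
      rows[[length(rows) + 1]] <- tibble(
        bcl_ms = b, di_ms = NA_real_, apd_ms = NA_real_,
        status = "no_convergence")
      next
    }
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- tibble(
        bcl_ms = b, di_ms = NA_real_, apd_ms = NA_real_,
        status = "capture_failure")
      if (stop_on_alternans) break else next
    }
    state <- res$state
    row <- tibble(bcl_ms = b, di_ms = res$di_ms, apd_ms = res$apd_ms,
                  status = "period1")
    if (eigen) {
      es <- eigen_summary(jacobian_pack(model, b, v_ss = res$state))
      row$lambda_alt_re <- Re(es$lambda_alt)
      row$lambda_alt_im <- Im(es$lambda_alt)
      row$lambda_mem_re <- Re(es$lambda_mem)
      row$tau_mem_beats <- es$tau_mem_beats
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  ok <- out$status == "period1"
  slope <- curve_slope(out$di_ms[ok], out$apd_ms[ok])
  new_restitution_curve(out, kind = "dynamic", slope = slope)
}

new_restitution_curve <- function(df, kind, slope = NA_real_,
                                  bcl_context = NA_real_) {
  out <- as_tibble(df)
  class(out) <- c("restitution_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "slope_at_operating_point") <- slope
  attr(out, "bcl_context") <- bcl_context
  out
}

# centred finite-difference slope of apd vs di at the mid-point of a curve
curve_slope <- function(di, apd) {
  ok <- is.finite(di) & is.finite(apd)
  di <- di[ok]; apd <- apd[ok]
  if (length(di) < 3) return(NA_real_)
  o <- order(di)
  di <- di[o]; apd <- apd[o]
  i <- max(2, min(length(di) - 1, which.min(abs(di - stats::median(di)))))
  (apd[i + 1] - apd[i - 1]) / (di[i + 1] - di[i - 1])
}

#' S1S2 restitution protocol
#'
#' After settling at the S1S1 cycle length `bcl`, a single modified S2
#' interval is introduced and the APD of the following action potential is
#' recorded against the DI preceding it; repeating over `s2_list` traces the
#' S1S2 restitution curve for that BCL. The slope at the operating point
#' (S2 = S1) is measured from a symmetric +/- 1 ms S2 pair.
#'
#' @inheritParams dynamic_restitution
#' @param bcl S1S1 basic cycle length (ms).
#' @param s2_list vector of S2 intervals (ms).
#' @return Tibble of class `restitution_curve` (kind `"s1s2"`, attribute
#'   `bcl_context = bcl`) with columns `s2_ms`, `di_ms`, `apd_ms`.
#' @export
s1s2_protocol <- function(model, bcl, s2_list, rel_tol = 1e-7,
                          max_beats = 1000) {
  ss <- settle(model, bcl, rel_tol, max_beats)
  probe <- function(s2) {
    st1 <- model_beat(model, ss$state, s2)       # beat at the S2 interval
    nxt <- model_beat(model, st1$state, bcl)     # AP following the S2
    c(di = st1$di, apd = nxt$apd)
  }
  rows <- purrr::map(s2_list, function(s2) {
    res <- tryCatch(probe(s2), stochpace_capture_error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("S2 = %.1f ms skipped: %s", s2, conditionMessage(res)))
      return(NULL)
    }
    tibble(s2_ms = s2, di_ms = res[["di"]], apd_ms = res[["apd"]])
  })
  out <- dplyr::bind_rows(rows)
  op <- tryCatch({
    up <- probe(bcl + 1); dn <- probe(bcl - 1)
    (up[["apd"]] - dn[["apd"]]) / (up[["di"]] - dn[["di"]])
  }, stochpace_capture_error = function(e) NA_real_)
  new_restitution_curve(out, kind = "s1s2", slope = op, bcl_context = bcl)
}

#' Short-term memory amplitude from a family of S1S2 curves
#'
#' The memory amplitude is the range of APD values covered by S1S2
#' restitution curves from different basic cycle lengths, interpolated at a
#' predefined long diastolic interval. A memoryless model yields 0.
#'
#' @param curves list of S1S2 [restitution curves][s1s2_protocol].
#' @param di_ref reference DI (ms) at which the curves are compared.
#' @return Memory amplitude (ms).
#' @export
memory_amplitude <- function(curves, di_ref) {
  if (inherits(curves, "restitution_curve")) curves <- list(curves)
  vals <- purrr::map_dbl(curves, function(cv) {
    ok <- is.finite(cv$di_ms) & is.finite(cv$apd_ms)
    if (sum(ok) < 2 || di_ref < min(cv$di_ms[ok]) ||
        di_ref > max(cv$di_ms[ok])) {
      warn(sprintf("Curve excluded: DI = %.0f ms outside its span.", di_ref))
      return(NA_real_)
    }
    approx(cv$di_ms[ok], cv$apd_ms[ok], xout = di_ref)$y
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) return(0)
  diff(range(vals))
}

#' Detect sustained APD alternans in a beat series
#'
#' Sustained alternans is declared at the first beat from which the APD
#' difference series strictly alternates in sign for at least `k`
#' consecutive beats with `|dAPD| >= eps`; micro-alternans uses the same
#' rule with the smaller threshold `eps_micro`.
#'
#' @param series a [beat_series()] or numeric APD vector.
#' @param eps amplitude threshold (ms) for sustained alternans.
#' @param k minimum number of consecutive alternating beats.
#' @param eps_micro amplitude threshold (ms) for micro-alternans.
#' @return List with `onset` (beat index, `NA` if none), `amplitude`
#'   (mean `|dAPD|` over the qualifying run) and `micro_onset`.
#' @export
detect_alternans <- function(series, eps = 1, k = 20, eps_micro = 0.05) {
  apd <- if (is.numeric(series)) series else as_beat_frame(series)$apd_ms
  if (length(apd) <= k) {
    abort("Series must be longer than `k` beats.",
          class = "stochpace_input_error")
  }
  d <- diff(apd)
  find_onset <- function(thr) {
    good <- abs(d) >= thr
    altern <- c(good[-1] & good[-length(good)] &
                  (sign(d[-1]) == -sign(d[-length(d)])), FALSE)
    # altern[i]: d[i] and d[i+1] alternate; run of k beats needs k-1 diffs,
    # i.e. k-2 consecutive TRUEs starting at i
    need <- as.integer(max(1, k - 2))
    run <- 0L
    for (i in seq_along(altern)) {
      run <- if (altern[i]) run + 1L else 0L
      if (run >= need) {
        start_d <- as.integer(i - need + 1L)
        return(list(onset = start_d, amp = mean(abs(d[start_d:(i + 1)]))))
      }
    }
    NULL
  }
  res <- find_onset(eps)
  micro <- find_onset(eps_micro)
  list(onset = if (is.null(res)) NA_integer_ else res$onset,
       amplitude = if (is.null(res)) NA_real_ else res$amp,
       micro_onset = if (is.null(micro)) NA_integer_ else micro$onset)
}

#' Locate the alternans bifurcation by bisection on BCL
#'
#' Requires alternans at the low end and a period-1 response at the high end
#' of `bcl_range`; bisects to `resolution_ms` and returns the last
#' (shortest) non-alternating BCL. At that point the alternans eigenvalue of
#' the beat-map Jacobian is -1 within the bisection tolerance.
#'
#' @inheritParams dynamic_restitution
#' @param bcl_range length-2 numeric, `c(low, high)` in ms.
#' @param resolution_ms bisection resolution (ms).
#' @param max_beats settling budget per classification.
#' @return The onset BCL (ms) with attribute `bracket` (the final
#'   `c(alternans, period1)` bracket).
#' @export
find_bifurcation <- function(model, bcl_range, resolution_ms = 1,
                             rel_tol = 1e-7, max_beats = 4000) {
  lo <- min(bcl_range); hi <- max(bcl_range)
  cls <- function(b) pacing_regime(model, b, rel_tol, max_beats)$status
  s_lo <- cls(lo); s_hi <- cls(hi)
  if (s_lo != "alternans" || s_hi != "period1") {
    abort(sprintf(
      "No bifurcation bracketed: regime is %s at %.0f ms and %s at %.0f ms.",
      s_lo, lo, s_hi, hi),
      class = "stochpace_input_error")
  }
  while (hi - lo > resolution_ms) {
    mid <- (lo + hi) / 2
    if (cls(mid) == "alternans") lo <- mid else hi <- mid
  }
  structure(hi, bracket = c(alternans = lo, period1 = hi))
}
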