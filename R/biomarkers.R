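# Per-node and strand-level electrophysiological biomarkers.
#
# All threshold crossings use linear interpolation between samples; ties are
# broken by the first crossing.  Fibroblast nodes carry no action potential
# and are excluded from APD/RT/Ca biomarkers (NA), but remain conduction
# obstacles for CV and the safety factor.

# first linear-interpolated downward crossing of `level` at/after index i0
.cross_down <- function(v, t, level, i0) {
  n <- length(v)
  if (i0 >= n) return(NA_real_)
  idx <- which(v[i0:(n - 1)] >= level & v[(i0 + 1):n] < level)
  if (!length(idx)) return(NA_real_)
  i <- i0 + idx[1] - 1
  t[i] + (t[i + 1] - t[i]) * (v[i] - level) / (v[i] - v[i + 1])
}

# index of the maximum discrete derivative at/after stim_time
.upstroke_index <- function(v, t, stim_time) {
  dv <- diff(v) / diff(t)
  win <- which(t[-1] >= stim_time)
  if (!length(win)) return(NA_integer_)
  # ties (within floating-point noise of the maximum) break to the first
  mx <- max(dv[win])
  tol <- abs(mx) * 1e-9
  win[which(dv[win] >= mx - tol)[1]] + 1L
}

#' Action potential duration at 90% repolarization
#'
#' APD90 is measured from the maximum-dV/dt upstroke to the crossing of
#' `V_90 = V_peak - 0.9 (V_peak - V_rest)`, with linear interpolation between
#' samples.  `V_rest` is the diastolic membrane potential just before the
#' upstroke: the minimum of the trace between the start of the analyzed
#' window and the upstroke (in a paced strand the trace window opens at the
#' stimulus, so this is the end-diastolic potential).  This reference is
#' independent of the sampling interval.
#'
#' @param vm Sampled membrane potential, mV.
#' @param times Sample times, ms (monotone).
#' @param stim_time Stimulus time of the analyzed beat, ms.
#' @return APD90 in ms, or `NA` with attribute `no_capture = TRUE` when the
#'   trace never exceeds 0 mV after the stimulus.
#' @examples
#' t <- seq(0, 400, by = 0.5)
#' v <- ifelse(t < 10, -85, ifelse(t < 11, -85 + 120 * (t - 10),
#'      ifelse(t < 261, 35, ifelse(t < 311, 35 - 120 * (t - 261) / 50, -85))))
#' apd90(v, t, 9)  # trapezoid: 250 ms plateau + 45 ms of the 50-ms fall
#' @export
apd90 <- function(vm, times, stim_time) {
  iu <- .upstroke_index(vm, times, stim_time)
  if (is.na(iu)) return(structure(NA_real_, no_capture = TRUE))
  seg <- vm[times >= stim_time]
  if (max(seg) < 0) return(structure(NA_real_, no_capture = TRUE))
  v_rest <- min(vm[1:iu])  # diastolic minimum before the upstroke
  ipk <- iu - 1L + which.max(vm[iu:length(vm)])
  v_peak <- vm[ipk]
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  tc <- .cross_down(vm, times, v90, ipk)
  if (is.na(tc)) return(structure(NA_real_, no_capture = TRUE))
  tc - times[iu]
}

#' Strand-level dispersion with edge exclusion
#'
#' Max minus min over the interior of the strand: `edge_exclude` nodes are
#' dropped at each end before taking the range, and `NA` entries (fibroblast
#' or non-captured nodes) are ignored.
#'
#' @param values Per-node biomarker values in strand order.
#' @param edge_exclude Nodes dropped at each end (15 by default).
#' @return Dispersion (max - min) in the units of `values`.
#' @export
dispersion <- function(values, edge_exclude = 15) {
  n <- length(values)
  if (n <= 2 * edge_exclude) {
    stop("need more than 2*edge_exclude values, got ", n, call. = FALSE)
  }
  interior <- values[(edge_exclude + 1):(n - edge_exclude)]
  interior <- interior[!is.na(interior)]
  if (!length(interior)) return(NA_real_)
  max(interior) - min(interior)
}

#' Repolarization time and transmural dispersion of repolarization
#'
#' The repolarization time of a node is its activation delay (upstroke time
#' minus stimulus time) plus its APD90; TDR is the interior max - min of the
#' repolarization times (same 15-cell edge exclusion as APD dispersion).
#'
#' @param apd Per-node APD90, ms.
#' @param upstroke_time Per-node absolute upstroke times, ms.
#' @param stim_time Stimulus time, ms.
#' @return `repolarization_time`: per-node RT (ms); `tdr`: scalar dispersion.
#' @export
repolarization_time <- function(apd, upstroke_time, stim_time) {
  (upstroke_time - stim_time) + apd
}

#' @rdname repolarization_time
#' @param rts Per-node repolarization times.
#' @param edge_exclude Nodes dropped at each end.
#' @export
tdr <- function(rts, edge_exclude = 15) dispersion(rts, edge_exclude)

#' Calcium-transient duration at 80% recovery
#'
#' Measured from the Ca2+ upstroke (maximum dCa/dt after the stimulus) to the
#' decay through `Ca_rest + 0.2 * amplitude`.
#'
#' @param cai Sampled intracellular Ca2+, mM.
#' @inheritParams apd90
#' @return CaTD80 in ms, or `NA` (attribute `flat = TRUE`) for a flat trace.
#' @export
catd80 <- function(cai, times, stim_time) {
  iu <- .upstroke_index(cai, times, stim_time)
  if (is.na(iu)) return(structure(NA_real_, flat = TRUE))
  ca_rest <- min(cai[1:iu])  # diastolic minimum before the Ca upstroke
  ipk <- iu - 1L + which.max(cai[iu:length(cai)])
  amp <- cai[ipk] - ca_rest
  if (!is.finite(amp) || amp < 1e-6) return(structure(NA_real_, flat = TRUE))
  level <- ca_rest + 0.2 * amp
  tc <- .cross_down(cai, times, level, ipk)
  if (is.na(tc)) return(structure(NA_real_, flat = TRUE))
  tc - times[iu]
}

#' Delay between the action-potential and Ca2+-transient upstrokes
#'
#' @param vm,cai Sampled membrane potential and Ca2+ transient.
#' @inheritParams apd90
#' @return Delay in ms (Ca upstroke time minus V upstroke time).
#' @export
ap_ca_delay <- function(vm, cai, times, stim_time) {
  iv <- .upstroke_index(vm, times, stim_time)
  ic <- .upstroke_index(cai, times, stim_time)
  if (is.na(iv) || is.na(ic)) return(NA_real_)
  times[ic] - times[iv]
}

#' Conduction velocity between two cells
#'
#' Distance between the two cells divided by the difference of their
#' maximum-upstroke times (tracked at solver resolution), in cm/s.  The
#' default cells 15 and 150 avoid edge effects on the 165-node strand.
#'
#' @param traces A `trace_set` whose upstroke markers cover the analyzed
#'   beat.
#' @param layout Strand layout.
#' @param from_cell,to_cell 1-based cell numbers.
#' @return CV in cm/s.
#' @export
conduction_velocity <- function(traces, layout = traces$layout,
                                from_cell = 15, to_cell = 150) {
  ut <- traces$upstroke_time
  vz <- traces$vmax
  for (cell in c(from_cell, to_cell)) {
    if (is.na(ut[cell]) || vz[cell] < -20) {
      act <- which(vz > -20)
      stop(sprintf(
        "no capture at cell %d; last activated node: %s", cell,
        if (length(act)) max(act) else "none"), call. = FALSE)
    }
  }
  dt_up <- ut[to_cell] - ut[from_cell]
  ((to_cell - from_cell) * layout$dx) / dt_up * 1000
}

#' Safety factor for conduction
#'
#' Charge ratio `SF = (int I_c dt + int I_out dt) / (int I_in dt)` over the
#' node's depolarization window, from the time the membrane potential first
#' reaches 1% of its upstroke excursion above rest to the time of maximal
#' V_m.  `I_c = C_m dV/dt` (per unit capacitance, so `C_m = 1` in uA/uF
#' units); the axial terms come from [axial_currents()].  Integrals use the
#' trapezoid rule on the sampled traces; use a fine sampling interval
#' (<= 0.1 ms) for accuracy.
#'
#' @param traces A finely sampled `trace_set` covering the depolarization.
#' @param layout Strand layout.
#' @param nodes_idx Nodes to evaluate (default: all).
#' @param axial Optional precomputed [axial_currents()] result.
#' @return Numeric vector of SF values (NA where undefined, e.g. a
#'   stimulated node that receives no axial charge).
#' @export
safety_factor <- function(traces, layout = traces$layout,
                          nodes_idx = seq_len(layout$n_nodes),
                          axial = axial_currents(traces, layout)) {
  t <- traces$times
  vapply(nodes_idx, function(i) {
    v <- traces$vm[, i]
    ipk <- which.max(v)
    vmax <- v[ipk]
    vrest <- v[1]
    if (vmax - vrest < 10) return(NA_real_)  # no depolarization at all
    thr <- vrest + 0.01 * (vmax - vrest)
    below <- which(v[1:(ipk - 1)] < thr)
    if (!length(below)) return(NA_real_)
    i1 <- max(below)  # last sample below threshold before the peak
    win <- i1:ipk
    if (length(win) < 2) return(NA_real_)
    trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
    q_c <- v[ipk] - v[i1]  # exact integral of dV/dt over the window
    q_out <- trapz(t[win], axial$I_out[win, i])
    q_in <- trapz(t[win], axial$I_in[win, i])
    if (q_in <= 0) return(NA_real_)
    (q_c + q_out) / q_in
  }, 1.0)
}

#' Brute-force safety factor re-integration (reference path)
#'
#' Recomputes the safety factor of one node directly from the raw sampled
#' potentials with explicit rectangle-by-rectangle accumulation of the
#' capacitive and axial charges; independent of the vectorized
#' [safety_factor()] path and used to verify it.
#'
#' @inheritParams safety_factor
#' @param node Node index.
#' @return SF value.
#' @export
safety_factor_bruteforce <- function(traces, node, layout = traces$layout) {
  t <- traces$times
  v <- traces$vm[, node]
  D <- layout$D_elem * traces$diff_scale
  csn <- if (is.null(traces$cap_scale)) 1 else traces$cap_scale[node]
  D <- D * csn
  dx2 <- layout$dx^2
  n <- layout$n_nodes
  ipk <- which.max(v)
  vrest <- v[1]
  thr <- vrest + 0.01 * (v[ipk] - vrest)
  below <- which(v[1:(ipk - 1)] < thr)
  if (!length(below)) return(NA_real_)
  i1 <- max(below)
  q_c <- 0; q_in <- 0; q_out <- 0
  for (k in i1:(ipk - 1)) {
    h <- t[k + 1] - t[k]
    q_c <- q_c + (v[k + 1] - v[k])
    for (kk in c(k, k + 1)) {
      w <- h / 2
      inn <- 0; outt <- 0
      if (node > 1) {
        jl <- D[node - 1] * (traces$vm[kk, node - 1] - traces$vm[kk, node]) / dx2
        if (jl > 0) inn <- inn + jl else outt <- outt - jl
      }
      if (node < n) {
        jr <- D[node] * (traces$vm[kk, node + 1] - traces$vm[kk, node]) / dx2
        if (jr > 0) inn <- inn + jr else outt <- outt - jr
      }
      q_in <- q_in + w * inn
      q_out <- q_out + w * outt
    }
  }
  if (q_in <= 0) return(NA_real_)
  (q_c + q_out) / q_in
}

#' Welch two-sample t-test
#'
#' @param groupA,groupB Numeric vectors (each of length >= 2).
#' @return List with the Welch `t` statistic and two-sided `p` value.
#' @export
two_sample_ttest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  va <- stats::var(groupA); vb <- stats::var(groupB)
  if (va == 0 && vb == 0) {
    if (mean(groupA) == mean(groupB)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, p = 0))
  }
  res <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(res$statistic), p = unname(res$p.value))
}

#' Biomarker report for a paced strand beat
#'
#' Computes the per-node biomarkers (APD90, repolarization time, CaTD80,
#' AP-Ca delay) and the strand-level summaries (APD dispersion, TDR, CaTD80
#' and AP-Ca-delay dispersions, conduction velocity) from the final paced
#' beat of a strand.  Fibroblast nodes are NA in the per-node columns.
#'
#' @param traces `trace_set` of the analyzed beat (with Ca recorded).
#' @param stim_time Stimulus time of the beat, ms.
#' @param layout Strand layout.
#' @param edge_exclude Edge cells excluded from dispersions (15).
#' @param cv_cells Cells used for conduction velocity (15 and 150).
#' @param erp Optional precomputed ERP (ms) to include.
#' @param scenario Optional scenario descriptor string.
#' @return A `biomarker_report`: `per_node` data frame and `summary` list.
#' @export
biomarker_report <- function(traces, stim_time, layout = traces$layout,
                             edge_exclude = 15, cv_cells = c(15, 150),
                             erp = NULL, scenario = NULL) {
  n <- layout$n_nodes
  myo <- layout$node_class != "FIBROBLAST"
  apd <- rt <- ca80 <- dly <- rep(NA_real_, n)
  for (i in which(myo)) {
    apd[i] <- apd90(traces$vm[, i], traces$times, stim_time)
    if (!is.null(traces$cai)) {
      ca80[i] <- catd80(traces$cai[, i], traces$times, stim_time)
      dly[i] <- ap_ca_delay(traces$vm[, i], traces$cai[, i], traces$times,
                            stim_time)
    }
  }
  rt[myo] <- repolarization_time(apd[myo], traces$upstroke_time[myo],
                                 stim_time)
  cv <- tryCatch(conduction_velocity(traces, layout, cv_cells[1], cv_cells[2]),
                 error = function(e) NA_real_)
  summary <- list(
    APD_dispersion = dispersion(apd, edge_exclude),
    TDR = dispersion(rt, edge_exclude),
    CaTD80_dispersion = if (!is.null(traces$cai)) dispersion(ca80, edge_exclude)
                        else NA_real_,
    AP_Ca_delay_dispersion = if (!is.null(traces$cai))
      dispersion(dly, edge_exclude) else NA_real_,
    CV = cv, ERP = if (is.null(erp)) NA_real_ else as.numeric(erp),
    edge_exclude = edge_exclude, cv_cells = cv_cells,
    scenario = if (is.null(scenario)) layout$provenance else scenario)
  structure(list(
    per_node = data.frame(cell = seq_len(n), class = layout$node_class,
                          APD90 = apd, RT = rt, CaTD80 = ca80,
                          AP_Ca_delay = dly),
    summary = summary), class = "biomarker_report")
}

#' Export a biomarker report as delimited text
#'
#' One row per node followed by a key-value summary block.
#'
#' @param report A `biomarker_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.table(report$per_node, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("", con)
  s <- report$summary
  for (nm in names(s)) {
    writeLines(sprintf("# %s\t%s", nm, paste(s[[nm]], collapse = ",")), con)
  }
  invisible(path)
}
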