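#' Four-stage instruction scheduling
#'
#' Every instruction passes through configuration (CF), load (LD), execute
#' (EX) and write-back (WB), in that order; each stage is a distinct unit
#' resource serving one instruction at a time, in program order. Without
#' double buffering instructions run strictly back to back, so the makespan
#' is the plain sum of all stage costs. With the double-buffering (ping-pong)
#' strategy at most two instructions are in flight: instruction `i` may begin
#' its CF once instruction `i - 2` has fully retired, which lets the longest
#' stage mask the others - for `N` uniform instructions with dominant EX
#' (`e >= c + l + w`) the makespan collapses to `c + l + N*e + w`.
#' Layer-by-layer discipline is kept: an instruction of a later layer may
#' prefetch (CF/LD) but not start EX before every write-back of earlier
#' layers has completed.
#'
#' @param instrs instruction tibble with columns `cf`, `ld`, `ex`, `wb` and
#'   optionally `sched_layer` (defaults to a single layer).
#' @param double_buffered logical.
#' @return A `schedule_trace`: `timeline` tibble with per-stage start/end
#'   times, `makespan`, per-stage `busy` cycles, and the flags it was built
#'   with.
#' @export
schedule <- function(instrs, double_buffered = TRUE) {
  n <- nrow(instrs)
  layer <- if ("sched_layer" %in% names(instrs)) instrs$sched_layer else rep(1L, n)
  s <- matrix(0, n, 4); e <- matrix(0, n, 4)   # columns: CF, LD, EX, WB
  cost <- cbind(instrs$cf, instrs$ld, instrs$ex, instrs$wb)
  avail <- numeric(4)                          # stage-resource free times
  finish <- numeric(n)
  layer_wb_end <- 0                            # max WB end of all earlier layers
  cur_layer <- if (n > 0) layer[1] else 0L
  for (i in seq_len(n)) {
    if (layer[i] != cur_layer) {
      layer_wb_end <- if (i > 1) max(e[seq_len(i - 1L), 4]) else 0
      cur_layer <- layer[i]
    }
    gate <- if (double_buffered) {
      if (i > 2) finish[i - 2] else 0
    } else {
      if (i > 1) finish[i - 1] else 0
    }
    s[i, 1] <- max(gate, avail[1]);            e[i, 1] <- s[i, 1] + cost[i, 1]
    s[i, 2] <- max(e[i, 1], avail[2]);         e[i, 2] <- s[i, 2] + cost[i, 2]
    s[i, 3] <- max(e[i, 2], avail[3], layer_wb_end)
    e[i, 3] <- s[i, 3] + cost[i, 3]
    s[i, 4] <- max(e[i, 3], avail[4]);         e[i, 4] <- s[i, 4] + cost[i, 4]
    avail <- e[i, ]
    finish[i] <- e[i, 4]
  }
  timeline <- tibble::tibble(
    instr = seq_len(n), sched_layer = layer,
    cf_start = s[, 1], cf_end = e[, 1], ld_start = s[, 2], ld_end = e[, 2],
    ex_start = s[, 3], ex_end = e[, 3], wb_start = s[, 4], wb_end = e[, 4])
  structure(
    list(timeline = timeline, instrs = instrs,
         makespan = if (n > 0) max(e[, 4]) else 0,
         busy = c(cf = sum(cost[, 1]), ld = sum(cost[, 2]),
                  ex = sum(cost[, 3]), wb = sum(cost[, 4])),
         double_buffered = double_buffered),
    class = "schedule_trace")
}

#' @export
print.schedule_trace <- function(x, ...) {
  cat(sprintf("<schedule_trace> %d instructions, %s, makespan %s cycles\n",
              nrow(x$timeline),
              if (x$double_buffered) "double-buffered" else "serial",
              format(x$makespan)))
  invisible(x)
}

#' @export
tidy.schedule_trace <- function(x, ...) {
  tl <- x$timeline
  dplyr::bind_rows(lapply(c("cf", "ld", "ex", "wb"), function(st) {
    tibble::tibble(instr = tl$instr, sched_layer = tl$sched_layer,
                   stage = toupper(st),
                   start = tl[[paste0(st, "_start")]],
                   end = tl[[paste0(st, "_end")]])
  }))
}

#' @export
glance.schedule_trace <- function(x, ...) {
  tibble::tibble(
    n_instructions = nrow(x$timeline),
    double_buffered = x$double_buffered,
    makespan = x$makespan,
    ex_busy_fraction = if (x$makespan > 0) x$busy[["ex"]] / x$makespan else 0,
    stage_overlap = if (x$makespan > 0) sum(x$busy) / x$makespan else 0)
}

#' Multiplier occupancy and stage statistics
#'
#' Per PE mode, occupancy is the fraction of multiplier-cycles doing real
#' work during EX-busy cycles: `sum(real MACs) / (multipliers * sum(EX
#' cycles))`. Channel-padding lanes and capacity-capped lanes count as idle,
#' which is exactly the idle-multiplier proportion the three PE modes exist
#' to minimize. Stage busy fractions are relative to the makespan.
#'
#' @param trace a `schedule_trace` whose instructions carry `mode`,
#'   `macs_real` and `ex` columns.
#' @param rc a [resource_config()].
#' @return A list: `per_mode` tibble (`mode`, `ex_cycles`, `occupancy`),
#'   `overall_occupancy`, `stage_busy` tibble, `makespan`.
#' @export
utilization_report <- function(trace, rc) {
  ins <- trace$instrs
  per_mode <- dplyr::summarise(
    dplyr::group_by(ins, .data$mode),
    ex_cycles = sum(.data$ex),
    occupancy = ifelse(sum(.data$ex) > 0,
                       sum(.data$macs_real) / (rc$pe_multipliers * sum(.data$ex)),
                       0),
    .groups = "drop")
  overall <- if (sum(ins$ex) > 0) {
    sum(ins$macs_real) / (rc$pe_multipliers * sum(ins$ex))
  } else 0
  stage_busy <- tibble::tibble(
    stage = c("CF", "LD", "EX", "WB"),
    busy_cycles = as.numeric(trace$busy),
    busy_fraction = if (trace$makespan > 0) as.numeric(trace$busy) / trace$makespan
                    else rep(0, 4))
  list(per_mode = per_mode, overall_occupancy = overall,
       stage_busy = stage_busy, makespan = trace$makespan)
}
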