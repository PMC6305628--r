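#' Gate schedules for the five-level pulser bridge
#'
#' The pulser is built from three bridges providing +/-V1, +/-V2 and a
#' ground clamp, controlled through six MOSFET gates: active-low `nA2p`,
#' `nA1p`, `nA0p` driving pMOS devices (0 = ON) and active-high `A0n`,
#' `A1n`, `A2n` driving nMOS devices (1 = ON).  The ground clamp conducts
#' when its pMOS/nMOS pair (`nA0p` + `A0n`) are both on.  Because the
#' level-shifted gates are capacitively coupled, the four rail signals
#' (`nA1p`, `nA2p`, `A1n`, `A2n`) cannot be held on indefinitely; the clamp
#' pair is exempt from this on-time limit.
#'
#' @name gate_schedule
NULL

GATE_NAMES <- c("nA2p", "nA1p", "nA0p", "A0n", "A1n", "A2n")
# conduction paths: which gates must be on for each output level
PATH_GATES <- list(`2` = "nA2p", `1` = "nA1p", `0` = c("nA0p", "A0n"),
                   `-1` = "A1n", `-2` = "A2n")

new_gate_schedule <- function(on, sample_rate, dead_time, on_time_limit) {
  structure(list(on = on, sample_rate = sample_rate, dead_time = dead_time,
                 on_time_limit = on_time_limit),
            class = "gate_schedule")
}

#' Compile a five-level waveform into bridge gate traces
#'
#' Maps each output level to its conduction path (+2 -> `nA2p`,
#' +1 -> `nA1p`, 0 -> clamp pair, -1 -> `A1n`, -2 -> `A2n`) and inserts a
#' dead gap between any two distinct conducting paths so the supply rails
#' can never shoot through.  The clamp acts as the resting state: when a
#' rail follows the clamp, the clamp is released early; when the clamp
#' follows a rail, it is engaged late; between two rails the incoming rail
#' turns on late.  The output floats only during the dead gaps.
#'
#' @param waveform a `switched_waveform` with integer levels.
#' @param dead_time all-off interval inserted between distinct paths, in
#'   seconds; must span at least one sample.  Default 100 ns.
#' @param on_time_limit maximum continuous assertion of any level-shifted
#'   (non-clamp) gate, in seconds.  Default 1 ms.
#' @return a `gate_schedule`: logical matrix `on` (samples x 6 gates, TRUE =
#'   conducting) plus `sample_rate`, `dead_time`, `on_time_limit`.
#' @export
compile_gates <- function(waveform, dead_time = 100e-9, on_time_limit = 1e-3) {
  stopifnot(inherits(waveform, "switched_waveform"))
  if (waveform$scheme == "sine") {
    stop("the sine reference is not a switched waveform; no gate schedule exists")
  }
  fs <- waveform$sample_rate
  g <- round(dead_time * fs)
  if (g < 1) stop("dead_time must span at least one sample at this sample rate")
  lv <- as.integer(waveform$levels)
  n <- length(lv)
  on <- matrix(FALSE, n, 6L, dimnames = list(NULL, GATE_NAMES))

  r <- rle(lv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    a <- starts[i]; b <- ends[i]
    # dead gap before this run when the previous run used a different path
    if (i > 1L) {
      if (r$values[i - 1L] == 0L) {
        # clamp releases early: shave the gap off the clamp run's tail
        on[max(a - g, starts[i - 1L]):(a - 1L), PATH_GATES[["0"]]] <- FALSE
      } else {
        a <- min(a + g, b + 1L)      # incoming path turns on late
      }
    }
    if (a <= b) on[a:b, PATH_GATES[[as.character(r$values[i])]]] <- TRUE
  }

  sched <- new_gate_schedule(on, fs, dead_time, on_time_limit)
  viol <- gate_on_time_violations(sched)
  if (nrow(viol) > 0L) {
    stop(sprintf("gate %s asserted continuously for %.4g ms, exceeding the %.4g ms on-time limit",
                 viol$gate[1], viol$duration_s[1] * 1e3, on_time_limit * 1e3))
  }
  sched
}

# conducting path per sample: level in {-2..2}, or NA when no path conducts
# (dead-time samples); a half-asserted clamp pair does not conduct.
conducting_levels <- function(schedule) {
  on <- schedule$on
  lev <- rep(NA_integer_, nrow(on))
  lev[on[, "nA2p"]] <- 2L
  lev[on[, "nA1p"]] <- 1L
  lev[on[, "A1n"]] <- -1L
  lev[on[, "A2n"]] <- -2L
  lev[on[, "nA0p"] & on[, "A0n"]] <- 0L
  lev
}

#' Recover the level sequence from a gate schedule
#'
#' Inverse of [compile_gates()]: returns the conducting level at each
#' sample, `NA` during dead-time (floating) samples.
#'
#' @param schedule a `gate_schedule`.
#' @return integer vector of levels with `NA` at floating samples.
#' @export
decompile_gates <- function(schedule) {
  stopifnot(inherits(schedule, "gate_schedule"))
  conducting_levels(schedule)
}

gate_on_time_violations <- function(schedule) {
  limit <- schedule$on_time_limit * schedule$sample_rate
  out <- data.frame(gate = character(0), sample = integer(0),
                    duration_s = numeric(0))
  for (gname in c("nA2p", "nA1p", "A1n", "A2n")) {
    r <- rle(schedule$on[, gname])
    long <- which(r$values & r$lengths > limit)
    if (length(long)) {
      ends <- cumsum(r$lengths)
      out <- rbind(out, data.frame(
        gate = gname,
        sample = ends[long] - r$lengths[long] + 1L,
        duration_s = r$lengths[long] / schedule$sample_rate))
    }
  }
  out
}

#' Validate a gate schedule against the bridge hardware constraints
#'
#' Checks the three invariants: (1) mutual exclusion — at most one
#' conduction path at every sample (any two of the four rail gates, or a
#' rail gate together with an asserted clamp pair, is a shoot-through);
#' (2) a dead gap of at least `dead_time` between any two distinct
#' conducting paths; (3) no level-shifted gate asserted beyond the on-time
#' limit.
#'
#' @param schedule a `gate_schedule`.
#' @return data frame of violations with columns `sample` and `rule`;
#'   zero rows iff the schedule is valid.
#' @export
validate_gates <- function(schedule) {
  stopifnot(inherits(schedule, "gate_schedule"))
  on <- schedule$on
  viol <- data.frame(sample = integer(0), rule = character(0))

  clamp_on <- on[, "nA0p"] & on[, "A0n"]
  n_paths <- on[, "nA2p"] + on[, "nA1p"] + on[, "A1n"] + on[, "A2n"] + clamp_on
  bad <- which(n_paths > 1L)
  if (length(bad)) {
    viol <- rbind(viol, data.frame(sample = bad, rule = "shoot-through"))
  }

  g <- round(schedule$dead_time * schedule$sample_rate)
  lev <- conducting_levels(schedule)
  FLOAT <- -99L                       # sentinel: rle treats each NA as unequal
  r <- rle(ifelse(is.na(lev), FLOAT, lev))
  ends <- cumsum(r$lengths)
  vals <- r$values
  for (i in seq_along(vals)[-1]) {
    if (vals[i] == FLOAT || vals[i - 1L] == FLOAT) next
    if (vals[i] != vals[i - 1L]) {
      # adjacent distinct paths with no floating gap at all
      viol <- rbind(viol, data.frame(sample = ends[i - 1L] + 1L,
                                     rule = "dead-time"))
    }
  }
  # floating gaps shorter than the dead time between distinct paths
  for (i in seq_along(vals)) {
    if (i > 1L && i < length(vals) && vals[i] == FLOAT &&
        vals[i - 1L] != FLOAT && vals[i + 1L] != FLOAT &&
        vals[i - 1L] != vals[i + 1L] && r$lengths[i] < g) {
      viol <- rbind(viol, data.frame(sample = ends[i - 1L] + 1L,
                                     rule = "dead-time"))
    }
  }

  ot <- gate_on_time_violations(schedule)
  if (nrow(ot)) {
    viol <- rbind(viol, data.frame(sample = ot$sample, rule = "on-time"))
  }
  viol[order(viol$sample), , drop = FALSE]
}

#' @export
print.gate_schedule <- function(x, ...) {
  cat("<gate_schedule>\n")
  cat(sprintf("  %d samples at %.6g Hz, dead time %.3g ns, on-time limit %.3g ms\n",
              nrow(x$on), x$sample_rate, x$dead_time * 1e9,
              x$on_time_limit * 1e3))
  frac <- colMeans(x$on)
  cat("  duty: ", paste(sprintf("%s %.1f%%", colnames(x$on), 100 * frac),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Export a gate table for lookup-table ingestion
#'
#' Writes one row per sample with six 0/1 columns in the fixed order
#' `nA2p, nA1p, nA0p, A0n, A1n, A2n`, holding the *physical* line levels:
#' the active-low pMOS gates read 0 when conducting, the active-high nMOS
#' gates read 1 when conducting.
#'
#' @param schedule a `gate_schedule`.
#' @param path output file path (tab-separated, with header).
#' @return the written path, invisibly.
#' @export
write_gate_table <- function(schedule, path) {
  stopifnot(inherits(schedule, "gate_schedule"))
  on <- schedule$on
  phys <- matrix(0L, nrow(on), 6L, dimnames = list(NULL, GATE_NAMES))
  for (gname in GATE_NAMES) {
    active_low <- startsWith(gname, "n")
    phys[, gname] <- if (active_low) 1L - on[, gname] else on[, gname] + 0L
  }
  utils::write.table(phys, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gate table written by [write_gate_table()]
#'
#' @param path file path.
#' @param sample_rate,dead_time,on_time_limit schedule metadata (the table
#'   itself carries only the line levels).
#' @return a `gate_schedule`.
#' @export
read_gate_table <- function(path, sample_rate, dead_time = 100e-9,
                            on_time_limit = 1e-3) {
  phys <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (!identical(colnames(phys), GATE_NAMES)) {
    stop("gate table columns must be exactly: ",
         paste(GATE_NAMES, collapse = ", "))
  }
  on <- matrix(FALSE, nrow(phys), 6L, dimnames = list(NULL, GATE_NAMES))
  for (gname in GATE_NAMES) {
    active_low <- startsWith(gname, "n")
    on[, gname] <- if (active_low) phys[, gname] == 0L else phys[, gname] == 1L
  }
  new_gate_schedule(on, sample_rate, dead_time, on_time_limit)
}
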