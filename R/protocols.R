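#' Construct a drug-application protocol
#'
#' A protocol is pure data: an ordered list of timed events, each setting a
#' subset of the drug targets (agonist concentration, Rya-Caf exposure, CPA
#' exposure, external-Ca2+ presence), plus a total duration and the initial
#' state policy. Targets are piecewise constant: an event's settings hold
#' until another event changes them; when two events share a time stamp the
#' later-listed one wins. Before the first event the resting targets apply
#' (agonist 0, no drug, external Ca2+ present).
#'
#' @param events a data.frame with column `time` (s, non-decreasing,
#'   >= 0) and any of `agonist`, `ryacaf`, `cpa`, `external_ca`; `NA`
#'   entries leave the corresponding target unchanged.
#' @param duration total protocol duration (s, >= the last event time).
#' @param initial either the string `"resting_equilibrium"` (default: start
#'   from the drug-free physiological equilibrium) or an explicit
#'   [asm_state()].
#' @param param_overrides named numeric vector of parameter overrides the
#'   scenario calls for (e.g. a slow CPA timescale); applied by
#'   [simulate_protocol()].
#' @return An object of class `asm_protocol`.
#' @seealso [build_protocol()] for the named experimental protocols.
#' @export
asm_protocol <- function(events, duration,
                         initial = "resting_equilibrium",
                         param_overrides = NULL) {
  stopifnot(is.data.frame(events), "time" %in% names(events))
  cols <- c("agonist", "ryacaf", "cpa", "external_ca")
  for (nm in cols) if (!nm %in% names(events))
    events[[nm]] <- rep(NA, nrow(events))
  events <- events[, c("time", cols)]
  rownames(events) <- NULL
  if (nrow(events)) {
    if (any(events$time < 0)) stop("event times must be non-negative")
    if (is.unsorted(events$time)) stop("event times must be non-decreasing")
    ag <- events$agonist
    if (any(!is.na(ag) & ag < 0)) stop("agonist targets must be >= 0")
  }
  if (duration < if (nrow(events)) max(events$time) else 0)
    stop("duration must cover the last event")
  if (!identical(initial, "resting_equilibrium"))
    initial <- validate_state(initial)
  if (!is.null(param_overrides) &&
      (is.null(names(param_overrides)) || any(names(param_overrides) == "")))
    stop("param_overrides must be named")
  structure(list(events = events, duration = as.numeric(duration),
                 initial = initial, param_overrides = param_overrides),
            class = "asm_protocol")
}

#' Drug targets in force at a given time
#'
#' Resolves the piecewise-constant targets of a protocol at time `t`:
#' resting targets before the first event, then each event at or before `t`
#' applied in order (so the latest setting of each target wins, and of two
#' events at the same time the later-listed one wins).
#'
#' @param t time (s) within `[0, duration]`.
#' @param protocol an [asm_protocol()].
#' @return A [drug_targets()] list.
#' @export
drug_targets_at <- function(t, protocol) {
  stopifnot(inherits(protocol, "asm_protocol"))
  if (t < 0 || t > protocol$duration)
    stop("t outside [0, duration]")
  tg <- drug_targets()
  ev <- protocol$events
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > t) break
    tg <- apply_event(tg, ev[i, ])
  }
  tg
}

apply_event <- function(tg, row) {
  if (!is.na(row$agonist)) tg$agonist <- as.numeric(row$agonist)
  if (!is.na(row$ryacaf)) tg$ryacaf <- as.logical(row$ryacaf)
  if (!is.na(row$cpa)) tg$cpa <- as.logical(row$cpa)
  if (!is.na(row$external_ca)) tg$external_ca <- as.logical(row$external_ca)
  tg
}

#' Named experimental protocols
#'
#' Builds the event schedules of the modelled experiments:
#' \describe{
#'   \item{`fig3_threestep`}{agonist stimulation, washout, Rya-Caf
#'     treatment, washout, second agonist stimulation — the protocol used to
#'     clamp cytosolic Ca2+ by emptying the SR through locked-open RyR.}
#'   \item{`cpa_fast_full`, `cpa_slow_full`, `cpa_partial`}{the three
#'     competing hypotheses for CPA action: agonist alone, agonist + CPA,
#'     CPA alone (agonist washout), then agonist re-applied in CPA.
#'     `cpa_slow_full` only differs by a slow CPA timescale override
#'     (`tau_e = 600` s); `cpa_partial` relies on the parameter
#'     `cpa_block_fraction < 1` (full-block variants override it to 1).}
#'   \item{`cpa_long`}{the long-exposure variant: agonist + CPA for 5 min,
#'     CPA alone for 10 min, then agonist re-applied.}
#'   \item{`cpa_zero_ca`}{as `cpa_long`, but external Ca2+ is removed before
#'     the final agonist application, so any response must come from
#'     residual SR Ca2+.}
#' }
#' Default phase durations: agonist phases 400 s, washouts 200 s, Rya-Caf
#' exposure 200 s (overridable); building a protocol performs no simulation.
#'
#' @param name one of `"fig3_threestep"`, `"cpa_fast_full"`,
#'   `"cpa_slow_full"`, `"cpa_partial"`, `"cpa_long"`, `"cpa_zero_ca"`.
#' @param agonist agonist target concentration (uM) used in the agonist
#'   phases.
#' @param agonist_dur,washout_dur,ryacaf_dur phase durations (s).
#' @return An [asm_protocol()].
#' @examples
#' build_protocol("fig3_threestep")
#' @export
build_protocol <- function(name, agonist = 1, agonist_dur = 400,
                           washout_dur = 200, ryacaf_dur = 200) {
  ev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(time = r[[1]],
                 agonist = if (is.null(r$agonist)) NA else r$agonist,
                 ryacaf = if (is.null(r$ryacaf)) NA else r$ryacaf,
                 cpa = if (is.null(r$cpa)) NA else r$cpa,
                 external_ca = if (is.null(r$external_ca)) NA
                               else r$external_ca)))
  }
  a <- agonist_dur; w <- washout_dur; r <- ryacaf_dur
  switch(name,
    fig3_threestep = asm_protocol(
      ev(list(0, agonist = agonist),
         list(a, agonist = 0),
         list(a + w, ryacaf = TRUE),
         list(a + w + r, ryacaf = FALSE),
         list(a + 2 * w + r, agonist = agonist)),
      duration = 2 * a + 2 * w + r),
    cpa_fast_full = cpa_protocol(agonist, a, w, block_override = 1),
    cpa_slow_full = cpa_protocol(agonist, a, w, block_override = 1,
                                 tau_e_override = 600),
    cpa_partial = cpa_protocol(agonist, a, w),
    cpa_long = cpa_protocol(agonist, a, w, cpa_with_agonist = 300,
                            cpa_alone = 600),
    cpa_zero_ca = {
      pr <- cpa_protocol(agonist, a, w, cpa_with_agonist = 300,
                         cpa_alone = 600)
      # remove external Ca2+ shortly (10 s) before the final agonist
      # application; any longer delay lets the store drain passively and
      # the residual-release transient vanishes
      t_final <- pr$events$time[nrow(pr$events)]
      extra <- data.frame(time = t_final - 10, agonist = NA, ryacaf = NA,
                          cpa = NA, external_ca = FALSE)
      ev2 <- rbind(pr$events[pr$events$time < t_final - 10, ], extra,
                   pr$events[pr$events$time >= t_final - 10, ])
      asm_protocol(ev2, pr$duration, param_overrides = pr$param_overrides)
    },
    stop("unknown protocol name: ", name)
  )
}

# agonist, agonist+CPA, CPA alone (washout), agonist re-applied (CPA stays)
cpa_protocol <- function(agonist, a, w, cpa_with_agonist = 400,
                         cpa_alone = 400, block_override = NULL,
                         tau_e_override = NULL) {
  t1 <- a; t2 <- t1 + cpa_with_agonist; t3 <- t2 + cpa_alone
  events <- data.frame(
    time = c(0, t1, t2, t3),
    agonist = c(agonist, NA, 0, agonist),
    ryacaf = NA,
    cpa = c(NA, TRUE, NA, NA),
    external_ca = NA)
  ov <- c(if (!is.null(block_override))
            c(cpa_block_fraction = block_override),
          if (!is.null(tau_e_override)) c(tau_e = tau_e_override))
  asm_protocol(events, duration = t3 + a, param_overrides = ov)
}

#' @export
print.asm_protocol <- function(x, ...) {
  cat("asm_protocol:", nrow(x$events), "events over", x$duration, "s\n")
  print(x$events, row.names = FALSE)
  if (!is.null(x$param_overrides)) {
    cat("parameter overrides:\n")
    print(x$param_overrides)
  }
  cat("initial state:",
      if (identical(x$initial, "resting_equilibrium"))
        "resting equilibrium\n" else "explicit\n")
  invisible(x)
}

#' Write a protocol to a plain-text file
#'
#' Serializes the event table (and any parameter overrides) as delimited
#' text; [read_protocol()] reproduces the protocol exactly.
#'
#' @param protocol an [asm_protocol()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "asm_protocol"))
  hdr <- c("# asm_protocol v1",
           paste0("# duration = ", format(protocol$duration, digits = 17)))
  if (!is.null(protocol$param_overrides))
    hdr <- c(hdr, paste0("# override ", names(protocol$param_overrides),
                         " = ", format(protocol$param_overrides,
                                       digits = 17)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  ev <- protocol$events
  out <- data.frame(
    time = format(ev$time, digits = 17, trim = TRUE),
    agonist = ifelse(is.na(ev$agonist), "NA",
                     format(ev$agonist, digits = 17, trim = TRUE)),
    ryacaf = as.character(ev$ryacaf),
    cpa = as.character(ev$cpa),
    external_ca = as.character(ev$external_ca))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protocol written by [write_protocol()]
#'
#' @param path path to a protocol file.
#' @return An [asm_protocol()].
#' @export
read_protocol <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  dur_line <- grep("^# duration =", hdr, value = TRUE)
  if (!length(dur_line)) stop("not a protocol file: ", path)
  duration <- as.numeric(sub("^# duration = *", "", dur_line[1]))
  ov_lines <- grep("^# override ", hdr, value = TRUE)
  ov <- NULL
  if (length(ov_lines)) {
    kv <- sub("^# override ", "", ov_lines)
    ov <- stats::setNames(as.numeric(trimws(sub("^[^=]*=", "", kv))),
                          trimws(sub("=.*$", "", kv)))
  }
  body <- lines[!startsWith(lines, "#")]
  events <- utils::read.table(text = body, header = TRUE, sep = "\t",
                              na.strings = "NA")
  for (nm in c("ryacaf", "cpa", "external_ca"))
    events[[nm]] <- as.logical(events[[nm]])
  asm_protocol(events, duration, param_overrides = ov)
}
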