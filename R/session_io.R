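#' Read and write recording sessions
#'
#' Sessions are stored either as a set of plain-text files sharing a prefix
#' (`<path>.signals.tsv`, `<path>.frames.tsv`, `<path>.meta.yaml`) or as a
#' single EDF file (`<path>.edf`) with an optional `<path>.meta.yaml`
#' sidecar for the protocol. The table format is lossless for finite
#' doubles (values are written as round-trippable decimal strings); EDF
#' quantizes to 16 bits of the per-channel physical range.
#'
#' Channel roles are resolved from label prefixes: `LFP_`, `ACC_`, `EMG_`,
#' `STIM_`, `TRUTH_`. A session must contain at least one LFP channel; in
#' `"train"` mode it must also contain a label source (accelerometer or
#' EMG), while `"deploy"` mode accepts LFP-only files.
#'
#' @param session a [session_recording()].
#' @param path file prefix (no extension).
#' @param format `"table"` or `"edf"`.
#' @param mode `"train"` (require a label source) or `"deploy"`.
#' @return `read_session` returns a [session_recording()];
#'   `write_session` returns `path` invisibly.
#' @name session_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

role_of <- function(label) {
  if (startsWith(label, "LFP_")) "lfp"
  else if (startsWith(label, "ACC_")) "accel"
  else if (startsWith(label, "EMG_")) "emg"
  else if (startsWith(label, "STIM_")) "stim"
  else if (startsWith(label, "TRUTH_")) "truth"
  else "other"
}

protocol_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(task = p$task,
       blocks = lapply(seq_len(nrow(p$blocks)), function(i)
         list(state = p$blocks$state[i], duration_s = p$blocks$duration_s[i])))
}

protocol_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  session_protocol(
    data.frame(state = vapply(l$blocks, `[[`, "", "state"),
               duration_s = vapply(l$blocks, function(b)
                 as.numeric(b$duration_s), 0)),
    task = l$task)
}

#' @rdname session_io
#' @export
write_session <- function(session, path, format = c("table", "edf")) {
  format <- match.arg(format)
  if (!inherits(session, "session_recording"))
    tl_stop("invalid-session", "not a session_recording")
  sigs <- list()
  units <- character()
  for (part in c("lfp", "accel", "emg")) {
    s <- session[[part]]
    if (is.null(s)) next
    if (length(unique(s$channel_labels)) != n_channels(s))
      tl_stop("invalid-session", "duplicate channel labels")
    if (s$rate_hz != session$lfp$rate_hz)
      tl_stop("rate-mismatch", "constituent series have different rates")
    for (i in seq_len(n_channels(s))) {
      sigs[[s$channel_labels[i]]] <- s$samples[i, ]
      units[s$channel_labels[i]] <- s$units[i]
    }
  }
  if (length(unique(names(sigs))) != length(sigs))
    tl_stop("invalid-session", "channel labels collide across series")
  meta <- list(
    rate_hz = session$lfp$rate_hz,
    frame_s = session$stim_trace$frame_s,
    units = as.list(units),
    protocol = protocol_to_list(session$protocol)
  )
  if (format == "table") {
    rate <- session$lfp$rate_hz
    n <- n_samples(session$lfp)
    tab <- c(list(time_s = (seq_len(n) - 1) / rate), sigs)
    con <- file(paste0(path, ".signals.tsv"), "w")
    writeLines(paste(names(tab), collapse = "\t"), con)
    body <- do.call(paste, c(lapply(tab, fmt_num), sep = "\t"))
    writeLines(body, con)
    close(con)
    nf <- length(session$stim_trace$values)
    ftab <- list(time_s = (seq_len(nf) - 1) * session$stim_trace$frame_s,
                 STIM_AMP = session$stim_trace$values)
    if (!is.null(session$truth_states))
      ftab$TRUTH_STATE <- match(session$truth_states, MOTOR_STATES) - 1
    con <- file(paste0(path, ".frames.tsv"), "w")
    writeLines(paste(names(ftab), collapse = "\t"), con)
    writeLines(do.call(paste, c(lapply(ftab, fmt_num), sep = "\t")), con)
    close(con)
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  } else {
    frame_rate <- 1 / session$stim_trace$frame_s
    channels <- lapply(names(sigs), function(nm)
      list(label = nm, samples = sigs[[nm]],
           rate = session$lfp$rate_hz, unit = units[[nm]]))
    channels[[length(channels) + 1L]] <-
      list(label = "STIM_AMP", samples = session$stim_trace$values,
           rate = frame_rate, unit = "V")
    if (!is.null(session$truth_states))
      channels[[length(channels) + 1L]] <-
        list(label = "TRUTH_STATE",
             samples = match(session$truth_states, MOTOR_STATES) - 1,
             rate = frame_rate, unit = "code")
    write_edf(channels, paste0(path, ".edf"))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

assemble_session <- function(labels, samples_list, rate, units, frame_s,
                             stim_vals, truth_vals, protocol, mode) {
  roles <- vapply(labels, role_of, "")
  pick <- function(role) {
    i <- which(roles == role)
    if (!length(i)) return(NULL)
    m <- do.call(rbind, samples_list[i])
    timeseries(m, rate, labels[i],
               units = unlist(units[labels[i]], use.names = FALSE))
  }
  lfp <- pick("lfp")
  if (is.null(lfp)) tl_stop("role-missing", "no LFP channels found")
  accel <- pick("accel"); emg <- pick("emg")
  if (mode == "train" && is.null(accel) && is.null(emg))
    tl_stop("role-missing",
            "train mode requires a label source (ACC_ or EMG_ channels)")
  nf <- n_frames(n_samples(lfp) / rate, frame_s)
  stim <- if (is.null(stim_vals)) frameseries(numeric(nf), frame_s)
          else frameseries(stim_vals[seq_len(nf)], frame_s)
  truth <- if (is.null(truth_vals)) NULL
           else MOTOR_STATES[as.integer(round(truth_vals[seq_len(nf)])) + 1L]
  session_recording(lfp, accel, emg, stim, truth, protocol)
}

#' @rdname session_io
#' @export
read_session <- function(path, format = c("table", "edf"),
                         mode = c("train", "deploy")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  meta_file <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  frame_s <- if (!is.null(meta$frame_s)) meta$frame_s else 0.1
  protocol <- protocol_from_list(meta$protocol)
  if (format == "table") {
    sf <- paste0(path, ".signals.tsv")
    if (!file.exists(sf)) tl_stop("role-missing", paste("missing file:", sf))
    tab <- read.table(sf, header = TRUE, sep = "\t",
                      colClasses = "numeric", check.names = FALSE)
    labels <- setdiff(names(tab), "time_s")
    rate <- if (!is.null(meta$rate_hz)) meta$rate_hz
            else 1 / median(diff(tab$time_s))
    if (nrow(tab) > 1) {
      dt <- diff(tab$time_s[1:2])
      if (abs(dt - 1 / rate) > 1e-6 / rate)
        tl_stop("rate-mismatch",
                "time column spacing disagrees with declared rate")
    }
    stim_vals <- NULL; truth_vals <- NULL
    ff <- paste0(path, ".frames.tsv")
    if (file.exists(ff)) {
      ftab <- read.table(ff, header = TRUE, sep = "\t",
                         colClasses = "numeric", check.names = FALSE)
      stim_vals <- ftab$STIM_AMP
      truth_vals <- ftab$TRUTH_STATE
    }
    assemble_session(labels, lapply(labels, function(l) tab[[l]]),
                     rate, meta$units, frame_s, stim_vals, truth_vals,
                     protocol, mode)
  } else {
    edf <- read_edf(paste0(path, ".edf"))
    rates <- vapply(edf, `[[`, 0, "rate")
    sig <- edf[vapply(edf, function(ch)
      role_of(ch$label) %in% c("lfp", "accel", "emg"), TRUE)]
    if (length(sig)) {
      if (length(unique(vapply(sig, `[[`, 0, "rate"))) != 1)
        tl_stop("rate-mismatch", "signal channels have mixed rates")
    }
    labels <- vapply(sig, `[[`, "", "label")
    units <- as.list(stats::setNames(vapply(sig, `[[`, "", "unit"), labels))
    if (!is.null(meta$units)) units <- utils::modifyList(units, meta$units)
    stim_vals <- NULL; truth_vals <- NULL
    for (ch in edf) {
      if (ch$label == "STIM_AMP") stim_vals <- ch$samples
      if (ch$label == "TRUTH_STATE") truth_vals <- ch$samples
    }
    assemble_session(labels, lapply(sig, `[[`, "samples"),
                     sig[[1]]$rate, units, frame_s, stim_vals, truth_vals,
                     protocol, mode)
  }
}

#' Write a frame series to TSV
#' @param fs a [frameseries()].
#' @param path output file.
#' @export
write_frameseries <- function(fs, path) {
  con <- file(path, "w")
  writeLines("time_s\tvalue", con)
  t0 <- (seq_along(fs$values) - 1) * fs$frame_s
  writeLines(paste(fmt_num(t0), fmt_num(fs$values), sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Read a frame series from TSV
#' @param path input file.
#' @return A [frameseries()].
#' @export
read_frameseries <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
  frame_s <- if (nrow(tab) > 1) tab$time_s[2] - tab$time_s[1] else 0.1
  frameseries(tab$value, frame_s)
}

#' Write / read a session protocol as YAML
#' @param protocol a [session_protocol()].
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(protocol_to_list(protocol), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) protocol_from_list(yaml::read_yaml(path))
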