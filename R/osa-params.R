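#' Compute AHI, ODI and T90 from nocturnal recording summaries
#'
#' Derives the three obstructive sleep apnea parameters from per-participant
#' event counts and recording durations, applying the 4-hour validity rule per
#' recording channel:
#' \itemize{
#'   \item AHI (apnea-hypopnea index): apnea + hypopnea events per hour of
#'     air-flow recording. Valid only when both air flow and oxygen saturation
#'     were recorded for at least 4 h (hypopnea scoring requires the oximetry
#'     channel).
#'   \item ODI (oxygen desaturation index): desaturation events per hour of
#'     oxygen saturation recording; valid when SpO2 recording lasted >= 4 h.
#'   \item T90: percentage of the oxygen saturation recording spent below 90\%
#'     saturation; same validity rule as ODI.
#' }
#' The event-rate denominators are channel-specific (flow time for AHI, SpO2
#' time for ODI/T90) because validity is assessed per channel. Invalid
#' parameters are returned as `NA`, never as zero.
#'
#' @param records data frame with columns `n_apnea_hypopnea`,
#'   `n_desaturation`, `minutes_below_90`, `flow_recording_minutes`,
#'   `spo2_recording_minutes`. A `participant_id` column is carried through
#'   when present.
#' @param min_valid_minutes minimum recording length per channel for a
#'   parameter to be considered valid (default 240 min = 4 h).
#' @return data frame with columns `ahi` (events/h), `odi` (events/h),
#'   `t90` (percent), `ahi_valid`, `sat_valid`.
#' @examples
#' rec <- data.frame(n_apnea_hypopnea = 12, n_desaturation = 18,
#'                   minutes_below_90 = 30, flow_recording_minutes = 360,
#'                   spo2_recording_minutes = 360)
#' compute_osa_parameters(rec)
#' @export
compute_osa_parameters <- function(records, min_valid_minutes = 240) {
  records <- as.data.frame(records)
  req <- c("n_apnea_hypopnea", "n_desaturation", "minutes_below_90",
           "flow_recording_minutes", "spo2_recording_minutes")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("event records lack column(s): ", paste(missing_cols, collapse = ", "))
  for (nm in req) {
    v <- records[[nm]]
    if (any(v < 0, na.rm = TRUE)) stop("'", nm, "' must be non-negative")
  }
  if (any(records$minutes_below_90 > records$spo2_recording_minutes + 1e-9,
          na.rm = TRUE))
    stop("minutes_below_90 exceeds spo2_recording_minutes")
  bad_flow <- records$flow_recording_minutes == 0 & records$n_apnea_hypopnea > 0
  bad_sat <- records$spo2_recording_minutes == 0 &
    (records$n_desaturation > 0 | records$minutes_below_90 > 0)
  if (any(bad_flow, na.rm = TRUE) || any(bad_sat, na.rm = TRUE))
    stop("zero recording time with events present")

  ahi_valid <- records$flow_recording_minutes >= min_valid_minutes &
    records$spo2_recording_minutes >= min_valid_minutes
  sat_valid <- records$spo2_recording_minutes >= min_valid_minutes

  ahi <- ifelse(ahi_valid,
                records$n_apnea_hypopnea / (records$flow_recording_minutes / 60),
                NA_real_)
  odi <- ifelse(sat_valid,
                records$n_desaturation / (records$spo2_recording_minutes / 60),
                NA_real_)
  t90 <- ifelse(sat_valid,
                100 * records$minutes_below_90 / records$spo2_recording_minutes,
                NA_real_)
  out <- data.frame(ahi = ahi, odi = odi, t90 = t90,
                    ahi_valid = ahi_valid, sat_valid = sat_valid)
  if ("participant_id" %in% names(records))
    out <- cbind(participant_id = records$participant_id, out)
  out
}

#' Assign OSA severity groups from AHI, T90 and ODI
#'
#' Constructs the three severity groupings used throughout the analysis:
#' \itemize{
#'   \item AHI: clinical cut points at 5, 15 and 30 events/h (`no_osa`,
#'     `mild`, `moderate`, `severe`); intervals closed on the left, so
#'     AHI = 5 is `mild` and AHI = 30 is `severe`.
#'   \item T90: participants with T90 = 0 form their own group (`t90_0`);
#'     the remaining participants are split at empirical tertiles of the
#'     positive values (`t1` < `t2` < `t3`). Values tied with a tertile break
#'     go to the lower group.
#'   \item ODI: empirical quartiles (`q1`..`q4`), same tie rule.
#' }
#' Missing parameters yield missing labels.
#'
#' @param parameters data frame with columns `ahi`, `t90`, `odi` (any subset).
#' @return data frame of factor columns `ahi_group`, `t90_group`, `odi_group`
#'   (those whose input column is present).
#' @export
assign_severity_groups <- function(parameters) {
  parameters <- as.data.frame(parameters)
  out <- list()
  if ("ahi" %in% names(parameters)) {
    x <- parameters$ahi
    if (all(is.na(x))) stop("all AHI values missing")
    lab <- cut(x, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
               labels = c("no_osa", "mild", "moderate", "severe"))
    out$ahi_group <- lab
  }
  if ("t90" %in% names(parameters)) {
    x <- parameters$t90
    if (all(is.na(x))) stop("all T90 values missing")
    lab <- rep(NA_character_, length(x))
    lab[!is.na(x) & x == 0] <- "t90_0"
    pos <- !is.na(x) & x > 0
    if (any(pos)) {
      br <- stats::quantile(x[pos], probs = c(1, 2) / 3, type = 7)
      # ties at a break go to the lower tertile: right-closed intervals
      lab[pos] <- as.character(cut(x[pos], breaks = c(0, br, Inf),
                                   right = TRUE, include.lowest = TRUE,
                                   labels = c("t1", "t2", "t3")))
    }
    out$t90_group <- factor(lab, levels = c("t90_0", "t1", "t2", "t3"))
  }
  if ("odi" %in% names(parameters)) {
    x <- parameters$odi
    if (all(is.na(x))) stop("all ODI values missing")
    br <- stats::quantile(x, probs = c(1, 2, 3) / 4, na.rm = TRUE, type = 7)
    lab <- cut(x, breaks = c(-Inf, br, Inf), right = TRUE,
               labels = c("q1", "q2", "q3", "q4"))
    out$odi_group <- lab
  }
  if (!length(out)) stop("no parameter columns ('ahi', 't90', 'odi') found")
  as.data.frame(out)
}

#' Flag implausible total energy intake
#'
#' Dietary variables are set to missing for participants whose log total
#' energy intake lies more than 3 standard deviations from the sample mean of
#' the log intake. Mean and SD are computed once on the supplied (analysis)
#' sample before any flagging. With zero SD (all intakes equal) nothing is
#' flagged.
#'
#' @param energy numeric vector of total energy intake (kcal/d); `NA` allowed.
#' @param n_sd flagging band half-width in SD units (default 3).
#' @return `energy` with out-of-band entries replaced by `NA`.
#' @export
clean_energy_intake <- function(energy, n_sd = 3) {
  if (any(energy <= 0, na.rm = TRUE))
    stop("energy intake must be positive")
  le <- log(energy)
  m <- mean(le, na.rm = TRUE)
  s <- stats::sd(le, na.rm = TRUE)
  if (is.na(s) || s == 0) return(energy)
  flag <- !is.na(le) & abs(le - m) > n_sd * s
  energy[flag] <- NA_real_
  energy
}
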