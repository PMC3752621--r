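#' Channel registry for bedside-monitor numerics
#'
#' The engine works on a closed vocabulary of monitor-exported numerics
#' ("parameters" in monitor parlance), each with fixed units and a carrier
#' range used for validation at trace construction. The carrier range is
#' deliberately wide: it admits physically impossible but monitor-reportable
#' readings (a CVP of 200 mmHg, an arterial pressure of -10 mmHg) because such
#' readings are exactly the artifacts the evaluation layer must see.
#' Plausibility screening, when enabled, happens later and per rule.
#'
#' @return A data.frame with one row per channel: `channel`, `unit`,
#'   `low`/`high` (carrier range for non-missing values), `description`.
#' @examples
#' channelInfo()
#' @export
channelInfo <- function() {
  data.frame(
    channel = c("HR", "Pulse", "ARTsys", "ARTmean", "CVPmean",
                "PAPdia", "Perf", "NIBPm", "PVC", "VtachFlag"),
    unit = c("beats/min", "beats/min", "mmHg", "mmHg", "mmHg",
             "mmHg", "index", "mmHg", "count/min", "flag"),
    low  = c(0, 0, -50, -50, -50, -50, 0, -50, 0, 0),
    high = c(350, 350, 400, 400, 400, 400, 25, 400, 350, 1),
    description = c(
      "Heart rate from ECG",
      "Pulse rate from pulse oximeter / arterial line",
      "Systolic arterial pressure (arterial catheter)",
      "Mean arterial pressure (arterial catheter)",
      "Mean central venous pressure",
      "Diastolic pulmonary artery pressure",
      "Perfusion index (pulse oximeter)",
      "Mean non-invasive (cuff) blood pressure",
      "Premature ventricular contraction rate",
      "Ventricular tachycardia rhythm annotation (0/1)"),
    stringsAsFactors = FALSE
  )
}

.channelIds <- function() channelInfo()$channel

.channelRange <- function(channel) {
  info <- channelInfo()
  i <- match(channel, info$channel)
  if (is.na(i)) stop("unknown channel: ", channel, call. = FALSE)
  c(info$low[i], info$high[i])
}

.assertChannel <- function(channel) {
  if (!is.character(channel) || length(channel) != 1L ||
      !(channel %in% .channelIds())) {
    stop("unknown channel: ", paste(channel, collapse = ","),
         " (must be one of ", paste(.channelIds(), collapse = ", "), ")",
         call. = FALSE)
  }
  channel
}
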