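#' Write a RecordingSession to a directory
#'
#' Layout: `manifest.json` (sampling rates, start times, units, file names),
#' one little-endian float64 `<label>.bin` per continuous signal,
#' `spikes.csv` (`time_s`, `unit_id`, `region`, `cell_class`), `events.csv`
#' (`onset_s`, `duration_s`, `kind`), and `ground_truth.json` when the
#' session metadata carries a generator ground-truth block.
#'
#' @param session a [RecordingSession-class].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "RecordingSession"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sigMeta <- lapply(names(session@signals), function(nm) {
    sig <- session@signals[[nm]]
    fn <- paste0(nm, ".bin")
    con <- file(file.path(path, fn), "wb")
    writeBin(sig@samples, con, size = 8, endian = "little")
    close(con)
    list(label = nm, file = fn, fs_hz = sig@fs, t0_s = sig@t0,
         units = "uV", n_samples = length(sig@samples))
  })
  manifest <- list(format = "BetaOpto-session-v1", signals = sigMeta,
                   spikes_file = "spikes.csv", events_file = "events.csv")
  gt <- session@metadata$groundTruth
  if (!is.null(gt)) {
    manifest$ground_truth_file <- "ground_truth.json"
    gtOut <- gt[setdiff(names(gt), "config")]
    jsonlite::write_json(gtOut, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- do.call(rbind, lapply(session@spikeTrains, function(tr)
    if (length(tr@times)) data.frame(time_s = sprintf("%.17g", tr@times),
                                     unit_id = tr@unitId,
                                     region = tr@region,
                                     cell_class = tr@cellClass) else NULL))
  if (is.null(sp))
    sp <- data.frame(time_s = numeric(0), unit_id = character(0),
                     region = character(0), cell_class = character(0))
  write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  ev <- data.frame(onset_s = session@events@onset,
                   duration_s = session@events@duration,
                   kind = rep_len(session@events@kind,
                                  length(session@events@onset)))
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a RecordingSession from a directory
#'
#' Inverse of [writeSession()]; all container invariants (sorted spike
#' times, events within the signal support) are validated on load with
#' descriptive errors.
#'
#' @param path session directory containing `manifest.json`.
#' @return A [RecordingSession-class].
#' @export
readSession <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  sigs <- list()
  sm <- manifest$signals
  if (is.data.frame(sm)) sm <- split(sm, seq_len(nrow(sm)))
  for (s in sm) {
    fn <- file.path(path, s$file)
    if (!file.exists(fn)) stop("manifest references missing signal file ", s$file)
    con <- file(fn, "rb")
    x <- readBin(con, "double", n = as.numeric(s$n_samples), size = 8,
                 endian = "little")
    close(con)
    if (length(x) != s$n_samples)
      stop("signal file ", s$file, " truncated: expected ", s$n_samples,
           " samples, got ", length(x))
    sigs[[s$label]] <- continuousSignal(x, fs = as.numeric(s$fs_hz),
                                        t0 = as.numeric(s$t0_s),
                                        label = s$label)
  }
  spFile <- file.path(path, manifest$spikes_file)
  if (!file.exists(spFile)) stop("missing spike table ", spFile)
  sp <- read.csv(spFile, stringsAsFactors = FALSE)
  trains <- lapply(split(sp, if (nrow(sp)) sp$unit_id else character(0)),
    function(d) {
      bad <- which(diff(d$time_s) <= 0)
      if (length(bad))
        stop("spike times for unit ", d$unit_id[1],
             " not strictly increasing at row ", bad[1] + 1)
      spikeTrain(d$time_s, unitId = d$unit_id[1], region = d$region[1],
                 cellClass = d$cell_class[1])
    })
  names(trains) <- NULL
  evFile <- file.path(path, manifest$events_file)
  if (!file.exists(evFile)) stop("missing event table ", evFile)
  ev <- read.csv(evFile, stringsAsFactors = FALSE)
  events <- if (nrow(ev))
    stimEvents(ev$onset_s, ev$duration_s, kind = ev$kind[1])
  else new("StimEvents")
  meta <- list()
  if (!is.null(manifest$ground_truth_file)) {
    gt <- jsonlite::read_json(file.path(path, manifest$ground_truth_file),
                              simplifyVector = TRUE)
    meta$groundTruth <- gt
  }
  new("RecordingSession", signals = sigs, spikeTrains = trains,
      events = events, metadata = meta)
}

#' Run the full beta-dynamics analysis pipeline on one session
#'
#' Orchestrates the analysis chain: epoch extraction and inclusion check,
#' preprocessing, beta-band filtering, burst detection and per-epoch burst
#' statistics, per-stimulation beta-AUC differences (pulse protocol), beta
#' peak detection, and per-unit PSTH classification, OFF/ON rates,
#' modulation index and OFF/ON circular statistics.
#'
#' @param session a [RecordingSession-class].
#' @param band beta band in Hz (default `c(12, 30)`).
#' @param burstPercentile envelope percentile for burst detection
#'   (default 75).
#' @param burstMinDurS minimum burst duration (default 0.05 s).
#' @param peakThreshSd beta-peak threshold in SD units (default 1).
#' @param enforceInclusion abort (with machine-readable reasons) when the
#'   session fails [checkSessionInclusion()] (default TRUE).
#' @return A list of results: `epochs`, `inclusion`, `bursts`, `burstStats`,
#'   `aucRecords` (pulse mode only), `units` (per-unit data.frame),
#'   `circOff`/`circOn` (per-unit [CircResult-class] lists), `psth` (list),
#'   and `log` (parameters and dropped counts).
#' @export
runPipeline <- function(session, band = c(12, 30), burstPercentile = 75,
                        burstMinDurS = 0.05, peakThreshSd = 1,
                        enforceInclusion = TRUE) {
  stopifnot(is(session, "RecordingSession"))
  sig <- session@signals[[1]]
  bounds <- c(sig@t0, sig@t0 + signalDuration(sig))
  epochs <- buildEpochs(session@events, bounds)
  inclusion <- checkSessionInclusion(epochs)
  if (enforceInclusion && !inclusion$include)
    stop("session fails inclusion: ",
         paste(inclusion$reasons$failed, collapse = "; "))
  prep <- if (sig@fs >= 1000) preprocessEcog(sig) else sig
  betaSig <- bandpassFilter(prep, band[1], band[2])
  env <- signalEnvelope(betaSig)
  bursts <- detectBursts(env, percentile = burstPercentile,
                         minDurS = burstMinDurS)
  burstStats <- burstStatsByEpoch(bursts, epochs)
  aucRecords <- if (epochs@protocol == "pulse")
    epochAucDifferences(prep, epochs, band = band) else NULL
  peaks <- detectBetaPeaks(betaSig, threshSd = peakThreshSd)
  tb <- epochs@table
  inClass <- function(tt, cl) {
    wins <- tb[tb$class == cl, , drop = FALSE]
    vapply(tt, function(s) any(s >= wins$start & s < wins$end), logical(1))
  }
  units <- list(); circOff <- list(); circOn <- list(); psths <- list()
  for (tr in session@spikeTrains) {
    r <- ratesByEpoch(tr, epochs)
    mi <- modulationIndex(r$fOff, r$fOn)
    ps <- classifyResponse(buildPsth(tr, session@events))
    ph <- if (length(peaks) >= 2) spikePhases(tr, peaks)
          else data.frame(time = numeric(0), phase = numeric(0))
    co <- con <- NULL
    phOff <- ph$phase[inClass(ph$time, "off")]
    phOn <- ph$phase[inClass(ph$time, "on")]
    if (length(phOff) >= 4) co <- rayleighTest(phOff)
    if (length(phOn) >= 4) con <- rayleighTest(phOn)
    units[[tr@unitId]] <- data.frame(
      unitId = tr@unitId, region = tr@region, cellClass = tr@cellClass,
      fOff = r$fOff, fOn = r$fOn, mi = mi, label = ps@label,
      circMeanOff = if (!is.null(co)) co@meanAngle else NA_real_,
      rOff = if (!is.null(co)) co@R else NA_real_,
      rayleighPOff = if (!is.null(co)) co@p else NA_real_,
      circMeanOn = if (!is.null(con)) con@meanAngle else NA_real_,
      rOn = if (!is.null(con)) con@R else NA_real_,
      rayleighPOn = if (!is.null(con)) con@p else NA_real_)
    circOff[[tr@unitId]] <- co
    circOn[[tr@unitId]] <- con
    psths[[tr@unitId]] <- ps
  }
  list(epochs = epochs, inclusion = inclusion, bursts = bursts,
       burstStats = burstStats, aucRecords = aucRecords,
       units = if (length(units)) do.call(rbind, c(units,
         make.row.names = FALSE)) else NULL,
       circOff = circOff, circOn = circOn, psth = psths,
       log = list(band = band, burstPercentile = burstPercentile,
                  burstMinDurS = burstMinDurS, peakThreshSd = peakThreshSd,
                  nPeaks = length(peaks),
                  nDroppedEvents = epochs@nDropped))
}
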