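Package: BetaOpto
Title: Beta-Oscillation and Optogenetic-Response Analysis for Basal Ganglia Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo electrophysiology recorded under
    optogenetic stimulation protocols, centred on parkinsonian beta-band
    (12-30 Hz) dynamics in cortico-basal-ganglia circuits. Provides epoch
    extraction from laser events (Pre/OFF/ON), beta-burst detection by
    Hilbert-envelope percentile thresholding, epoch-wise beta band-power
    statistics as the area between the power spectrum and its band chord,
    spike-phase locking with circular statistics (Rayleigh, Watson-Williams),
    peri-stimulus time histogram response classification, spike-field
    coherence with a spike-thinning rate-bias control, and a seedable
    synthetic-data generator emulating ECoG with transient beta bursts and
    von Mises phase-locked Poisson spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
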