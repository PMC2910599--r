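#' Replicate-level quality control of an aCGH profile
#'
#' Flags clones whose replicate spots have a standard deviation above
#' `maxReplicateSD` or a signal-to-noise ratio below `minSNR` as missing.
#' Flagged clones keep their genomic position but lose their combined log2
#' ratio; retained clones keep the mean of their replicate spots unchanged.
#' The defaults (SD > 0.075, SNR < 3) are the conventional thresholds for
#' tiling-path BAC arrays.
#'
#' @param profile an [AcghProfile-class].
#' @param maxReplicateSD clones with replicate SD strictly above this are
#'   removed (default 0.075).
#' @param minSNR clones with SNR strictly below this are removed (default 3).
#' @return The profile with `missing` flags and `qcReport` (a list with
#'   `nInput`, `nRemoved`, `nRemovedSD`, `nRemovedSNR`, `nRetained`) updated.
#' @export
qcFilter <- function(profile, maxReplicateSD = 0.075, minSNR = 3) {
    stopifnot(is(profile, "AcghProfile"),
              maxReplicateSD > 0, minSNR > 0)
    failSD  <- profile@replicateSD > maxReplicateSD
    failSNR <- profile@snr < minSNR
    fail    <- failSD | failSNR
    if (all(fail))
        stop("empty profile: all clones removed by quality control in sample '",
             profile@sampleName, "'")
    profile@missing   <- fail
    profile@log2Ratio <- ifelse(fail, NA_real_, rowMeans(profile@replicates))
    profile@qcReport  <- list(
        nInput      = length(fail),
        nRemoved    = sum(fail),
        nRemovedSD  = sum(failSD),
        nRemovedSNR = sum(failSNR),
        nRetained   = sum(!fail))
    validObject(profile)
    profile
}
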