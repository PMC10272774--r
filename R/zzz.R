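#' synergykit: stable muscle-synergy extraction and EMG-driven angle regression
#'
#' Deterministic MCR-ALS synergy extraction (SIMPLISMA initialisation +
#' non-negativity-constrained alternating least squares) with NMF and PCA
#' baselines, VAF-based synergy-count selection, accelerometer-derived elbow
#' angle, a compiled bidirectional LSTM angle regressor, cross-session
#' stability metrics, and a synthetic multi-day sEMG generator with known
#' ground truth.
#'
#' @useDynLib synergykit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
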