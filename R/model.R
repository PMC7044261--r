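#' Two-channel gain-control response
#'
#' Response of the divisive gain-control combination model to modulation
#' depths \code{C_L} and \code{C_R} (percent). Each channel's excitatory
#' drive \eqn{C^p} is divided by a pool containing the saturation constant
#' \eqn{Z^q}, the channel's own depth raised to \eqn{q}, and the other
#' channel's depth weighted by \eqn{\omega}; the two channel outputs are then
#' summed. The function is symmetric under swapping the ears and vectorises
#' over depths (inputs recycled to a common length).
#'
#' @param C_L,C_R modulation depths in percent (>= 0).
#' @param params a \code{\link{model_params}} object.
#' @return numeric vector of model responses (response units, >= 0).
#' @examples
#' pars <- model_params(2.86, 2.47, 10.22, 0.02, 0.88)
#' gain_control_response(50, 50, pars)   # ~ 8.84
#' @export
gain_control_response <- function(C_L, C_R, params) {
  .check_depths(C_L, C_R)
  p <- params$p; q <- params$q; Zq <- params$Z^q; w <- params$omega
  C_L^p / (Zq + C_L^q + w * C_R^q) + C_R^p / (Zq + C_R^q + w * C_L^q)
}

#' Linear-summation response
#'
#' Alternative model that sums modulation depths linearly across the ears
#' before a single nonlinear transducer:
#' \eqn{resp = (C_L+C_R)^p / (Z^q + (C_L+C_R)^q)}. There is no interaural
#' suppression, so \code{params$omega} is ignored and the output depends on
#' the inputs only through their sum — monaural and dichotic arrangements of
#' the same total depth are indistinguishable.
#'
#' @inheritParams gain_control_response
#' @return numeric vector of model responses.
#' @export
linear_sum_response <- function(C_L, C_R, params) {
  .check_depths(C_L, C_R)
  S <- C_L + C_R
  S^params$p / (params$Z^params$q + S^params$q)
}

.check_depths <- function(C_L, C_R) {
  if (any(!is.finite(C_L)) || any(!is.finite(C_R)) ||
      any(C_L < 0) || any(C_R < 0)) {
    stop("modulation depths must be finite and non-negative")
  }
  invisible(NULL)
}

#' Ear signal constructor
#'
#' A per-ear stimulus descriptor: modulation depth (percent) and frequency
#' tag. Tag \code{"F40"} and \code{"F35"} denote 40-Hz and 35-Hz amplitude
#' modulation; \code{"NONE"} denotes the unmodulated carrier (depth 0).
#'
#' @param depth modulation depth in percent (>= 0).
#' @param tag one of \code{"F40"}, \code{"F35"}, \code{"NONE"}.
#' @return a list with elements \code{depth} and \code{tag}.
#' @export
ear_signal <- function(depth, tag = if (depth > 0) "F40" else "NONE") {
  if (!is.finite(depth) || depth < 0) stop("ear depth must be >= 0")
  tag <- match.arg(tag, c("F40", "F35", "NONE"))
  if (depth == 0) tag <- "NONE"
  if (depth > 0 && tag == "NONE") {
    stop("a modulated ear (depth > 0) needs a frequency tag")
  }
  list(depth = depth, tag = tag)
}

#' Frequency-tagged model response
#'
#' Generalises the gain-control response to stimuli whose two ears may carry
#' different modulation frequencies (the frequency-tagged EEG conditions).
#' The response read out at tag \code{at} sums, over ears, the excitatory
#' term of that ear's depth only if its tag matches \code{at}; the divisive
#' pool always includes the other ear's full depth (weighted by
#' \eqn{\omega}) regardless of its tag, i.e. interaural suppression is
#' untuned for modulation frequency. When both ears carry the tag
#' \code{at}, this reduces exactly to \code{\link{gain_control_response}}.
#'
#' @param left,right \code{\link{ear_signal}} descriptors.
#' @param at frequency tag to read the response at (\code{"F40"} or
#'   \code{"F35"}).
#' @param params a \code{\link{model_params}} object.
#' @return scalar model response at the requested tag.
#' @examples
#' pars <- table1_params("6d")
#' # cross-dichotic: 100% 40-Hz signal in one ear, 50% 35-Hz masker in the
#' # other; response at the masker frequency
#' tagged_response(ear_signal(100, "F40"), ear_signal(50, "F35"), "F35", pars)
#' @export
tagged_response <- function(left, right, at, params) {
  if (!at %in% c("F40", "F35")) stop("unknown readout tag '", at, "'")
  p <- params$p; q <- params$q; Zq <- params$Z^q; w <- params$omega
  term <- function(self, other) {
    C <- if (self$tag == at) self$depth else 0
    C^p / (Zq + C^q + w * other$depth^q)
  }
  term(left, right) + term(right, left)
}

#' Convert a model response to a steady-state SNR
#'
#' The EEG linking function: \eqn{SNR = (resp + \sigma)/\sigma}. An absent
#' signal (resp = 0) maps to the nominal noise baseline SNR = 1, and the
#' transform is affine and strictly increasing in the response.
#'
#' @param resp model response (>= 0); vectorised.
#' @param sigma noise parameter in response units (> 0).
#' @return SNR (dimensionless, >= 1 for non-negative responses).
#' @export
snr_transform <- function(resp, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  (resp + sigma) / sigma
}

# ---- stimulus arrangements ------------------------------------------------

.PSY_CONDITIONS <- c("MON", "BIN", "DICH", "HALF_BIN")
.EEG_CONDITIONS <- c("MON", "BIN", "DICH", "CROSS_MON", "CROSS_BIN",
                     "CROSS_DICH")

#' Psychophysical stimulus arrangement
#'
#' Resolves a discrimination-task condition to per-ear modulation depths for
#' the standard (pedestal-only) and signal (pedestal + target) intervals.
#' All modulations are at 40 Hz. Arrangements:
#' \describe{
#'   \item{MON}{pedestal and target in one ear, unmodulated carrier in the
#'     other.}
#'   \item{BIN}{pedestal and target in both ears, in phase.}
#'   \item{DICH}{pedestal in one ear, target in the other.}
#'   \item{HALF_BIN}{pedestal in both ears, target in one ear only.}
#' }
#' With pedestal 0, MON, DICH and HALF_BIN resolve to the same stimulus
#' (target in one ear, plain carrier in the other), which is why detection
#' data are pooled across those conditions.
#'
#' @param condition one of \code{"MON"}, \code{"BIN"}, \code{"DICH"},
#'   \code{"HALF_BIN"}.
#' @param pedestal pedestal modulation depth, percent.
#' @param target target increment depth, percent.
#' @return list with \code{standard} and \code{signal}, each a numeric
#'   \code{c(L, R)} pair of depths in percent.
#' @export
psy_arrangement <- function(condition, pedestal, target) {
  condition <- match.arg(condition, .PSY_CONDITIONS)
  if (pedestal < 0 || target < 0) stop("pedestal and target must be >= 0")
  switch(condition,
    MON      = list(standard = c(pedestal, 0),
                    signal   = c(pedestal + target, 0)),
    BIN      = list(standard = c(pedestal, pedestal),
                    signal   = c(pedestal + target, pedestal + target)),
    DICH     = list(standard = c(pedestal, 0),
                    signal   = c(pedestal, target)),
    HALF_BIN = list(standard = c(pedestal, pedestal),
                    signal   = c(pedestal + target, pedestal))
  )
}

#' EEG stimulus arrangement
#'
#' Resolves a frequency-tagged steady-state condition to a pair of
#' \code{\link{ear_signal}}s. The signal carries depth \code{depth}; where a
#' masker is present it has fixed depth \code{masker} (50 percent by
#' default). Arrangements:
#' \describe{
#'   \item{MON}{signal at 40 Hz in one ear, carrier in the other.}
#'   \item{BIN}{signal at 40 Hz in both ears.}
#'   \item{DICH}{signal at 40 Hz in one ear, 40-Hz masker in the other.}
#'   \item{CROSS_MON}{signal at 35 Hz in one ear, carrier in the other.}
#'   \item{CROSS_BIN}{signal at 40 Hz in one ear and at 35 Hz (same depth)
#'     in the other.}
#'   \item{CROSS_DICH}{signal at 40 Hz in one ear, 35-Hz masker in the
#'     other.}
#' }
#'
#' @param condition one of the six EEG condition labels.
#' @param depth signal modulation depth, percent.
#' @param masker masker modulation depth, percent (default 50).
#' @return list with \code{left} and \code{right} ear signals.
#' @export
eeg_arrangement <- function(condition, depth, masker = 50) {
  condition <- match.arg(condition, .EEG_CONDITIONS)
  if (depth < 0) stop("depth must be >= 0")
  sig40 <- ear_signal(depth, if (depth > 0) "F40" else "NONE")
  sig35 <- ear_signal(depth, if (depth > 0) "F35" else "NONE")
  none  <- ear_signal(0, "NONE")
  switch(condition,
    MON        = list(left = sig40, right = none),
    BIN        = list(left = sig40, right = sig40),
    DICH       = list(left = sig40, right = ear_signal(masker, "F40")),
    CROSS_MON  = list(left = sig35, right = none),
    CROSS_BIN  = list(left = sig40, right = sig35),
    CROSS_DICH = list(left = sig40, right = ear_signal(masker, "F35"))
  )
}

#' @rdname psy_arrangement
#' @export
psy_conditions <- function() .PSY_CONDITIONS

#' @rdname eeg_arrangement
#' @export
eeg_conditions <- function() .EEG_CONDITIONS
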