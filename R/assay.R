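## Quantification of co-immunoprecipitation and FRET readouts: the IP
## ratio with its reciprocal positivity call, the photobleaching FRET
## efficiency, and the background-derived positivity threshold.

#' Immunoprecipitation ratio (IPR)
#'
#' `IPR = (IIP / IIC) * (AIC / AIP) * 100%`: the band intensity of the
#' immunoprecipitated protein relative to its input loading control,
#' normalized by the protein amounts used in each, expressed as a
#' percentage.
#'
#' @param iip band intensity of the immunoprecipitated protein (> 0).
#' @param iic band intensity of the input loading control (> 0).
#' @param aip protein amount used for immunoprecipitation, in
#'   micrograms (> 0).
#' @param aic protein amount used for the input control, in micrograms
#'   (> 0).
#' @return IPR in percent.
#' @export
ipr <- function(iip, iic, aip, aic) {
  if (any(c(iip, iic, aip, aic) <= 0))
    stop_campnets("all IP measurements must be positive")
  (iip / iic) * (aic / aip) * 100
}

#' Call a positive interaction from reciprocal IP assays
#'
#' Positive when both the forward and the reciprocal IPR strictly
#' exceed the threshold (default 3%).
#'
#' @param ipr_forward,ipr_reciprocal IPR percentages of the two
#'   reciprocal assays.
#' @param threshold positivity threshold in percent (default 3).
#' @return logical.
#' @export
call_ip_positive <- function(ipr_forward, ipr_reciprocal, threshold = 3.0) {
  ipr_forward > threshold & ipr_reciprocal > threshold
}

#' FRET efficiency after acceptor photobleaching
#'
#' `FE = (D_post - D_pre) / D_post` when the donor brightens after
#' photobleaching (`D_post > D_pre`); otherwise there is no resonance
#' transfer signal and the efficiency is 0.
#'
#' @param d_pre donor fluorescence intensity before photobleaching
#'   (>= 0).
#' @param d_post donor fluorescence intensity after photobleaching
#'   (> 0).
#' @return efficiency in `[0, 1)`.
#' @export
fret_efficiency <- function(d_pre, d_post) {
  if (any(d_post <= 0)) stop_campnets("D_post must be positive")
  if (any(d_pre < 0)) stop_campnets("intensities must be nonnegative")
  ifelse(d_post > d_pre, (d_post - d_pre) / d_post, 0)
}

#' FRET positivity threshold from background candidates
#'
#' The maximum over candidates of mean FRET efficiency plus its
#' standard error; an interaction is called positive when its
#' efficiency strictly exceeds this cut.
#'
#' @param mfe per-candidate mean FRET efficiencies.
#' @param se per-candidate standard errors.
#' @return the threshold `max(mfe + se)`.
#' @export
fret_cut <- function(mfe, se) {
  if (length(mfe) == 0L) stop_campnets("need at least one candidate")
  if (length(mfe) != length(se)) stop_campnets("mfe and se lengths differ")
  max(mfe + se)
}
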