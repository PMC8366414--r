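#' Kaplan-Meier estimate of the censoring survival function
#'
#' Estimates `S_C(t) = P(C > t)` by the product-limit (Kaplan-Meier)
#' estimator with the status indicator reversed (`1 - event`): censorings
#' of the survival process are the "events" of the censoring process, and
#' observed deaths act as censorings of `C`. At tied times deaths are
#' assumed to precede censorings, so a censoring jump at `t` uses a risk
#' set that still contains subjects who died at `t`.
#'
#' @param data a [SurvivalData-class] object with at least 2 samples.
#' @return a [CensoringCurve-class] step function, identically 1 when no
#'   observation is censored.
#' @examples
#' sd <- SurvivalData(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 0, 1, 1))
#' estimateCensoringSurvival(sd)   # one jump at t = 2, value 2/3
#' @seealso [reweightTimes()], [evalCensoringCurve()]
#' @export
estimateCensoringSurvival <- function(data) {
  stopifnot(is(data, "SurvivalData"))
  n <- length(data@time)
  if (n < 2L) stop("need at least 2 observations to estimate the censoring curve")
  fit <- survival::survfit(
    survival::Surv(data@time, 1 - data@event) ~ 1,
    conf.type = "none"
  )
  drop <- fit$n.event > 0
  new("CensoringCurve",
      jumpTimes = fit$time[drop],
      survValues = fit$surv[drop],
      nAtRisk = as.integer(fit$n.risk[drop]))
}

#' Evaluate a censoring survival curve
#'
#' Right-continuous evaluation `S_C(t)`, or the left limit `S_C(t-)`
#' (product over censoring jumps strictly before `t`) when
#' `leftLimit = TRUE`.
#'
#' @param curve a [CensoringCurve-class].
#' @param t numeric vector of evaluation times (`>= 0`).
#' @param leftLimit evaluate the left limit instead of the value at `t`.
#' @return numeric vector of curve values.
#' @export
evalCensoringCurve <- function(curve, t, leftLimit = FALSE) {
  stopifnot(is(curve, "CensoringCurve"))
  if (!length(curve@jumpTimes)) return(rep(1, length(t)))
  vapply(t, function(ti) {
    keep <- if (leftLimit) curve@jumpTimes < ti else curve@jumpTimes <= ti
    if (!any(keep)) 1 else curve@survValues[max(which(keep))]
  }, numeric(1))
}

#' Reweight survival times by inverse censoring probability
#'
#' Computes the adjusted response `y*_i = delta_i * y_i / S_C(y_i-)` used
#' as the sMBPLS outcome: censored observations get weight 0 and a
#' reweighted time of 0, while observed events are inflated by the inverse
#' probability of remaining uncensored just before their event time. The
#' identity `E[delta * y / S_C(y-)] = E[y_true]` makes the weighted sample
#' mean an unbiased estimate of the uncensored mean survival time.
#'
#' If `S_C(y_i-) = 0` for an uncensored sample (an event after the last
#' censoring exhausted the risk set), the smallest positive value attained
#' by the curve is substituted and a warning is emitted, keeping `y*`
#' finite.
#'
#' @param data a [SurvivalData-class] object, not yet reweighted.
#' @param curve a [CensoringCurve-class] from [estimateCensoringSurvival()],
#'   estimated on the same samples (or a designated training split).
#' @return `data` with `ipcWeight` and `reweightedTime` filled in and the
#'   `reweighted` flag set; calling again on the result is an error.
#' @examples
#' sd <- SurvivalData(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 0, 1, 1))
#' rw <- reweightTimes(sd, estimateCensoringSurvival(sd))
#' reweightedTimes(rw)   # 1, 0, 4.5, 6
#' @export
reweightTimes <- function(data, curve) {
  stopifnot(is(data, "SurvivalData"), is(curve, "CensoringCurve"))
  if (data@reweighted)
    stop("survival data are already reweighted; refusing to reweight twice")
  scLeft <- evalCensoringCurve(curve, data@time, leftLimit = TRUE)
  zero <- scLeft <= 0 & data@event == 1
  if (any(zero)) {
    floorVal <- min(curve@survValues[curve@survValues > 0])
    warning(sprintf(
      "S_C(y-) = 0 for %d uncensored sample(s); flooring at smallest positive KM value %.4g",
      sum(zero), floorVal))
    scLeft[zero] <- floorVal
  }
  w <- ifelse(data@event == 1, 1 / scLeft, 0)
  data@ipcWeight <- w
  data@reweightedTime <- w * data@time
  data@reweighted <- TRUE
  validObject(data)
  data
}
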