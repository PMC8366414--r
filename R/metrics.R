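#' Harrell's concordance index
#'
#' Fraction of usable pairs -- pairs in which the shorter observed time is
#' an event -- where the shorter-time sample has the higher predicted
#' risk; risk ties count 1/2. Perfect risk ranking gives 1, a constant
#' risk gives 0.5.
#'
#' @param risk numeric risk scores (higher = higher hazard).
#' @param data a [SurvivalData-class] object of the same length.
#' @return concordance in `[0, 1]`; errors when no usable pair exists.
#' @export
harrellC <- function(risk, data) {
  stopifnot(is(data, "SurvivalData"))
  time <- data@time; event <- data@event
  n <- length(time)
  if (length(risk) != n) stop("risk and survival data lengths differ")
  ## usable pairs (i, j): time_i < time_j and event_i == 1
  usable <- outer(time, time, "<") & (event == 1)
  conc <- sum(usable & outer(risk, risk, ">")) +
    0.5 * sum(usable & outer(risk, risk, "=="))
  nUsable <- sum(usable)
  if (nUsable == 0) stop("no usable pairs for the concordance index")
  conc / nUsable
}

#' Uno's IPCW cumulative/dynamic AUC at time t
#'
#' Estimates `P(risk_i > risk_j | T_i <= t, T_j > t)` -- discrimination
#' between cases with an event by `t` and controls still event-free at
#' `t` -- reweighting each case `i` by `1 / S_C(T_i-)^2`, the inverse
#' squared Kaplan-Meier censoring survival just before its event time.
#' Risk ties are half-weighted. Without censoring the estimator reduces
#' exactly to the Mann-Whitney AUC of the case/control dichotomy at `t`.
#'
#' @param risk numeric risk scores.
#' @param data a [SurvivalData-class] object.
#' @param t evaluation time within follow-up.
#' @param curve optional precomputed [CensoringCurve-class]; estimated
#'   from `data` when `NULL`.
#' @return AUC in `[0, 1]`, or `NA` (with attribute `"reason"`) when
#'   there is no case or no control at `t`.
#' @export
cdAucUno <- function(risk, data, t, curve = NULL) {
  stopifnot(is(data, "SurvivalData"))
  if (is.null(curve)) curve <- estimateCensoringSurvival(data)
  case <- data@time <= t & data@event == 1
  ctrl <- data@time > t
  if (!any(case) || !any(ctrl)) {
    out <- NA_real_
    attr(out, "reason") <- "no cases or no controls at t"
    return(out)
  }
  sc <- evalCensoringCurve(curve, data@time[case], leftLimit = TRUE)
  sc[sc <= 0] <- min(curve@survValues[curve@survValues > 0], 1)
  w <- 1 / sc^2
  rc <- risk[case]; rj <- risk[ctrl]
  gt <- outer(rc, rj, ">")
  eq <- outer(rc, rj, "==")
  num <- sum(w * (rowSums(gt) + 0.5 * rowSums(eq)))
  den <- sum(w) * length(rj)
  num / den
}

#' Chambless-Diao cumulative/dynamic AUC at time t
#'
#' Kaplan-Meier-increment estimator of the same cumulative/dynamic AUC:
#' each distinct event time `t_k <= t` contributes the KM mass
#' `dF(t_k)` (split equally over tied events), and its case markers are
#' compared against the markers of the subjects still at risk beyond `t`;
#' the weighted comparison is normalized by `F(t)`. Without censoring the
#' KM masses are `1/n` and the estimator equals the Mann-Whitney AUC.
#'
#' @inheritParams cdAucUno
#' @return AUC in `[0, 1]`, or flagged `NA` as in [cdAucUno()].
#' @export
cdAucChambless <- function(risk, data, t) {
  stopifnot(is(data, "SurvivalData"))
  ctrl <- data@time > t
  evIdx <- which(data@time <= t & data@event == 1)
  if (!length(evIdx) || !any(ctrl)) {
    out <- NA_real_
    attr(out, "reason") <- "no cases or no controls at t"
    return(out)
  }
  km <- survival::survfit(survival::Surv(data@time, data@event) ~ 1,
                          conf.type = "none")
  ## KM mass dF at each distinct event time
  drop <- km$n.event > 0
  evTimes <- km$time[drop]
  surv <- km$surv[drop]
  survBefore <- c(1, surv[-length(surv)])
  mass <- survBefore - surv
  rj <- risk[ctrl]
  num <- 0; den <- 0
  for (ki in which(evTimes <= t)) {
    cases <- which(data@time == evTimes[ki] & data@event == 1)
    mk <- mass[ki] / length(cases)
    for (i in cases) {
      num <- num + mk * (sum(risk[i] > rj) + 0.5 * sum(risk[i] == rj)) /
        length(rj)
      den <- den + mk
    }
  }
  num / den
}

#' Incident/dynamic AUC
#'
#' At an event time `t`, the incident/dynamic AUC is the probability that
#' the subject failing AT `t` outranks the subjects still event-free past
#' `t`, estimated by the rank of the failing subject's risk within the
#' risk set (ties half-weighted; tied failures averaged). The integrated
#' summary weights the per-time AUCs by `2 * f(t_k) * S(t_k)`
#' (Kaplan-Meier density mass times survival), normalized over the
#' evaluation times.
#'
#' @param risk numeric risk scores.
#' @param data a [SurvivalData-class] object.
#' @param t single event time, or `NULL` to evaluate at every distinct
#'   event time and return the integrated summary too. A `t` that is not
#'   an event time is moved to the nearest event time with a warning.
#' @return for a single `t`: the AUC at that time. For `t = NULL`: list
#'   with `times`, `auc` (per-time), `weights` and `integrated`.
#' @export
idAuc <- function(risk, data, t = NULL) {
  stopifnot(is(data, "SurvivalData"))
  evTimes <- sort(unique(data@time[data@event == 1]))
  if (!length(evTimes)) stop("no event times")

  aucAt <- function(tt) {
    cases <- which(data@time == tt & data@event == 1)
    ctrl <- which(data@time > tt)
    if (!length(ctrl)) return(NA_real_)
    mean(vapply(cases, function(i)
      (sum(risk[i] > risk[ctrl]) + 0.5 * sum(risk[i] == risk[ctrl])) /
        length(ctrl), numeric(1)))
  }

  if (!is.null(t)) {
    if (!t %in% evTimes) {
      tNew <- evTimes[which.min(abs(evTimes - t))]
      warning(sprintf("t = %g is not an event time; using nearest event time %g",
                      t, tNew))
      t <- tNew
    }
    return(aucAt(t))
  }

  km <- survival::survfit(survival::Surv(data@time, data@event) ~ 1,
                          conf.type = "none")
  drop <- km$n.event > 0
  kmTimes <- km$time[drop]
  surv <- km$surv[drop]
  mass <- c(1, surv[-length(surv)]) - surv
  auc <- vapply(evTimes, aucAt, numeric(1))
  wRaw <- vapply(evTimes, function(tt) {
    j <- match(tt, kmTimes)
    2 * mass[j] * surv[j]
  }, numeric(1))
  ok <- !is.na(auc) & wRaw > 0
  w <- wRaw
  w[!ok] <- 0
  integrated <- if (any(ok)) sum(w[ok] * auc[ok]) / sum(w[ok]) else NA_real_
  list(times = evTimes, auc = auc, weights = w, integrated = integrated)
}

#' Performance report for a risk score on test data
#'
#' Convenience wrapper computing Harrell's C, Uno and Chambless
#' cumulative/dynamic AUC at the evaluation times (default: the quartiles
#' of the observed event times), and the incident/dynamic AUC with its
#' integrated summary.
#'
#' @param risk numeric risk scores.
#' @param data a [SurvivalData-class] object.
#' @param evalTimes evaluation times for the C/D AUCs.
#' @return list with `cIndex`, `evalTimes`, `cdAucUno`, `cdAucChambless`
#'   (per-time vectors and their means ignoring flagged times), `idAuc`
#'   and `idAucIntegrated`.
#' @export
performanceReport <- function(risk, data, evalTimes = NULL) {
  if (is.null(evalTimes)) {
    ev <- data@time[data@event == 1]
    evalTimes <- unname(quantile(ev, c(0.25, 0.5, 0.75)))
  }
  curve <- estimateCensoringSurvival(data)
  uno <- vapply(evalTimes, function(t) as.numeric(cdAucUno(risk, data, t, curve)),
                numeric(1))
  cham <- vapply(evalTimes, function(t) as.numeric(cdAucChambless(risk, data, t)),
                 numeric(1))
  id <- idAuc(risk, data)
  list(cIndex = harrellC(risk, data),
       evalTimes = evalTimes,
       cdAucUno = uno, cdAucUnoMean = mean(uno, na.rm = TRUE),
       cdAucChambless = cham, cdAucChamblessMean = mean(cham, na.rm = TRUE),
       idAuc = id$auc, idAucIntegrated = id$integrated)
}
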