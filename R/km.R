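#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator. At each distinct observed time the
#' risk set contains all subjects whose observed time is at or beyond
#' it, so subjects censored at an event time are still counted at risk
#' there (the usual convention, stated explicitly). S(0) = 1 and the
#' curve is non-increasing.
#'
#' @param times non-negative observed times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return object of class `km_curve`: data.frame with columns `time`
#'   (distinct observed times, ascending), `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))  # S = 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input")
  if (anyNA(times) || anyNA(events)) stop("missing values in input")
  if (any(times < 0)) stop("negative times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(u) sum(times >= u), numeric(1L))
  n_event <- vapply(tt, function(u) sum(times == u & events == 1), numeric(1L))
  n_censor <- vapply(tt, function(u) sum(times == u & events == 0), numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at a time point
#'
#' Evaluates a [km_estimate()] curve at `t` (step-function convention:
#' the estimate from the latest event time at or before `t`). If `t`
#' lies beyond the largest observed time in the data the estimate is
#' not defined and `NA` is returned with attribute
#' `not_reached = TRUE`, rather than extrapolating.
#'
#' @param curve a `km_curve`.
#' @param t time point (same units as the input times).
#' @return survival probability in \[0, 1\], or `NA` if not reached.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), length(t) == 1L, t >= 0)
  if (t > max(curve$time))
    return(structure(NA_real_, not_reached = TRUE))
  i <- findInterval(t, curve$time)
  if (i == 0L) 1 else curve$surv[i]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n_risk[1L], sum(x$n_event)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @param x a `km_curve`.
#' @param ... passed to [graphics::plot()].
#' @rdname km_estimate
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability", ...)
  cens <- x$time[x$n_censor > 0]
  if (length(cens)) {
    si <- vapply(cens, function(t) km_survival_at(x, t), numeric(1L))
    graphics::points(cens, si, pch = 3)
  }
  invisible(x)
}
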