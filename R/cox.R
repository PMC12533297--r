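#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood with Breslow
#' (default) or Efron handling of tied event times. Convergence is
#' declared when the relative change in the partial log-likelihood
#' falls below `tol`; the step is halved on overshoot. Wald 95%
#' confidence intervals are exp(coef +/- z_0.975 x SE). A diverging
#' coefficient path (monotone likelihood / separation) is flagged in
#' the result and warned about, never silent; a singular information
#' matrix is an error.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param covariates numeric matrix or data.frame of covariates (no
#'   constant column; n must exceed the number of covariates).
#' @param ties `"breslow"` or `"efron"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `cox_fit`: coefficients, `se`, `hr`,
#'   `ci_lower`, `ci_upper` (95%), `z`, `p`, `loglik`, `iterations`,
#'   `converged`, `flag` (`"ok"` or `"monotone_likelihood"`), `ties`,
#'   `n`, `n_events`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  n <- length(times)
  stopifnot(length(events) == n, nrow(x) == n)
  if (anyNA(times) || anyNA(events) || anyNA(x))
    stop("missing values in input")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) == 0) stop("no events")
  p <- ncol(x)
  if (n <= p) stop("need more subjects than covariates")
  const <- apply(x, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(x)[const] %||% which(const), collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  ord <- order(times)
  y <- times[ord]; ev <- events[ord] == 1; x <- x[ord, , drop = FALSE]
  # distinct event times: first sorted index and event count per block
  evt <- unique(y[ev])
  first <- match(evt, y)            # risk set = sorted indices >= first
  dct <- vapply(evt, function(u) sum(y == u & ev), numeric(1L))
  tied_rows <- lapply(seq_along(evt), function(j) which(y == evt[j] & ev))

  lik_parts <- function(beta) {
    eta <- drop(x %*% beta)
    eta <- eta - max(eta)           # guards exp overflow; cancels in ratios
    w <- exp(eta)
    wx <- w * x
    s0 <- rev(cumsum(rev(w)))[first]
    s1 <- apply(wx, 2L, function(col) rev(cumsum(rev(col))))[first, ,
                                                             drop = FALSE]
    # suffix sums of w * x_a * x_b, upper triangle
    s2 <- array(0, c(length(first), p, p))
    for (a in seq_len(p)) for (b in a:p) {
      sab <- rev(cumsum(rev(w * x[, a] * x[, b])))[first]
      s2[, a, b] <- sab; s2[, b, a] <- sab
    }
    ll <- sum(eta[ev])
    U <- colSums(x[ev, , drop = FALSE])
    H <- matrix(0, p, p)
    if (ties == "breslow") {
      ll <- ll - sum(dct * log(s0))
      U <- U - colSums((dct / s0) * s1)
      for (j in seq_along(first)) {
        m <- s1[j, ] / s0[j]
        H <- H + dct[j] * (s2[j, , ] / s0[j] - tcrossprod(m))
      }
    } else {
      for (j in seq_along(first)) {
        rows <- tied_rows[[j]]
        t0 <- sum(w[rows])
        t1 <- colSums(wx[rows, , drop = FALSE])
        t2 <- crossprod(x[rows, , drop = FALSE] * w[rows],
                        x[rows, , drop = FALSE])
        d <- dct[j]
        for (l in seq_len(d) - 1) {
          den <- s0[j] - (l / d) * t0
          num1 <- s1[j, ] - (l / d) * t1
          ll <- ll - log(den)
          U <- U - num1 / den
          H <- H + (s2[j, , ] - (l / d) * t2) / den -
            tcrossprod(num1 / den)
        }
      }
    }
    list(ll = ll, U = U, H = H)
  }

  beta <- rep(0, p)
  parts <- lik_parts(beta)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$H, parts$U), error = function(e)
      stop("singular information matrix", call. = FALSE))
    new_beta <- beta + step
    new_parts <- lik_parts(new_beta)
    halvings <- 0L
    while ((!is.finite(new_parts$ll) || new_parts$ll < parts$ll) &&
           halvings < 20L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      new_parts <- lik_parts(new_beta)
    }
    rel <- abs(new_parts$ll - parts$ll) / (abs(parts$ll) + 0.1)
    beta <- new_beta; parts <- new_parts
    if (rel < tol) { converged <- TRUE; break }
  }
  flag <- "ok"
  if (any(abs(beta) > 15)) {
    flag <- "monotone_likelihood"
    warning("coefficient path diverging (monotone likelihood / separation)")
  }
  if (!converged)
    warning(sprintf("Newton-Raphson did not converge in %d iterations",
                    max_iter))
  beta <- stats::setNames(beta, colnames(x))
  se <- stats::setNames(sqrt(diag(solve(parts$H))), colnames(x))
  z975 <- stats::qnorm(0.975)
  structure(list(
    coefficients = beta,
    se = se,
    hr = exp(beta),
    ci_lower = exp(beta - z975 * se),
    ci_upper = exp(beta + z975 * se),
    z = beta / se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = parts$ll,
    iterations = iter, converged = converged, flag = flag, ties = ties,
    n = n, n_events = sum(ev)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  if (!x$converged) cat("  ** did not converge **\n")
  if (x$flag != "ok") cat("  ** flag:", x$flag, "**\n")
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    `lower95` = x$ci_lower, `upper95` = x$ci_upper,
                    z = x$z, p = x$p)
  print(round(tab, digits))
  invisible(x)
}
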