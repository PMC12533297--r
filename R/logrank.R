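#' Log-rank test for k groups
#'
#' Observed-minus-expected test over the pooled distinct event times.
#' For each event time the expected events per group are allocated in
#' proportion to the group's share of the risk set, with the usual
#' hypergeometric variance (and covariance between groups); the
#' chi-square statistic uses the first k-1 groups with df = k-1. Times
#' contributing a risk set of size 1 add no variance.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param group group membership (factor or vector); every level must
#'   contain at least one subject.
#' @return object of class `logrank_test`: list with `statistic`, `df`,
#'   `p.value`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (anyNA(times) || anyNA(events) || anyNA(group))
    stop("missing values in input")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (!is.factor(group)) group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups")
  cnt <- table(group)
  if (any(cnt == 0L)) stop("group with zero subjects: ",
                           paste(names(cnt)[cnt == 0L], collapse = ", "))
  g <- as.integer(group)

  et <- sort(unique(times[events == 1]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (tj in et) {
    at_risk <- times >= tj
    nj <- sum(at_risk)
    dj <- sum(times == tj & events == 1)
    nij <- tabulate(g[at_risk], nbins = k)
    dij <- tabulate(g[times == tj & events == 1], nbins = k)
    O <- O + dij
    E <- E + dj * nij / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj - 1)
      V <- V + f * (diag(nij / nj, k) - tcrossprod(nij / nj))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(as.numeric(t(u) %*% solve(Vk, u)),
                   error = function(e) as.numeric(t(u) %*% .pinv(Vk) %*% u))
  if (!is.finite(stat)) stat <- 0
  structure(list(statistic = stat, df = k - 1L,
                 p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                 observed = O, expected = E, n = length(times)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}

# Two-group log-rank chi-square statistics for ALL threshold splits of a
# feature at once. Subjects are ordered by decreasing feature value; the
# "high" group at threshold c = the first k subjects (feature >= c).
# Cumulating at-risk and event indicator matrices over that ordering
# gives every split's O-E and hypergeometric variance in one pass.
# Returns list(k, cutoff, stat, n_high) for admissible distinct-value
# boundaries only. Used by the cutoff search and its permutation test;
# per-split logrank_test() calls serve as the independent oracle.
.maxsel_logrank_stats <- function(feature, times, events,
                                  min_group_frac = 0.10) {
  n <- length(feature)
  ord <- order(feature, decreasing = TRUE)
  f <- feature[ord]; y <- times[ord]; ev <- events[ord]

  et <- sort(unique(y[ev == 1]))
  if (!length(et)) stop("no events")
  nj <- vapply(et, function(u) sum(y >= u), numeric(1L))
  dj <- vapply(et, function(u) sum(y == u & ev == 1), numeric(1L))

  A <- outer(et, y, function(u, yy) as.numeric(yy >= u))
  B <- outer(et, y, function(u, yy) as.numeric(yy == u)) *
    rep(ev, each = length(et))
  N1 <- t(apply(A, 1L, cumsum))
  D1 <- t(apply(B, 1L, cumsum))
  if (length(et) == 1L) { N1 <- matrix(N1, 1L); D1 <- matrix(D1, 1L) }

  U <- colSums(D1 - (dj / nj) * N1)
  cf <- ifelse(nj > 1, dj * (nj - dj) / (nj^2 * (nj - 1)), 0)
  V <- colSums(cf * N1 * (nj - N1))
  stat <- ifelse(V > 0, U^2 / V, 0)

  min_n <- ceiling(min_group_frac * n)
  ks <- which(seq_len(n) >= max(min_n, 1L) &
              (n - seq_len(n)) >= max(min_n, 1L))
  ks <- ks[f[ks] > f[pmin(ks + 1L, n)]]  # distinct-value boundaries only
  list(k = ks, cutoff = f[ks], stat = stat[ks],
       n_high = ks, n_low = n - ks)
}
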