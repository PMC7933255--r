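#' Barnard's unconditional exact test for a 2x2 table
#'
#' Two-sided unconditional exact test with fixed column margins. For
#' every candidate table with the same column totals, the Wald statistic
#' for the difference of the two column proportions is computed; for a
#' nuisance common success probability \eqn{\pi} the tail probability
#' sums the probabilities of all tables whose statistic is at least as
#' extreme (in absolute value) as observed, and the p-value is the
#' maximum of this tail over a grid of \eqn{\pi} values
#' (0.001, 0.002, ..., 0.999), clamped to [0, 1]. Unlike Fisher's exact
#' test, only the column margins are conditioned on, which makes the
#' test uniformly at least as powerful for 2x2 tables with one fixed
#' margin.
#'
#' @param a,b,c,d cell counts: rows are the success/failure classes
#'   (e.g. high/low neo-antigenicity), columns the two fixed groups
#'   (e.g. low/high non-synonymous load), so the column totals
#'   \code{a + c} and \code{b + d} are the fixed margins. A 2x2 matrix
#'   may be given as \code{a}.
#' @param piGrid nuisance-parameter grid.
#' @return list with \code{pValue}, \code{statistic} (observed Wald
#'   statistic) and \code{piMax} (grid value attaining the maximum).
#' @examples
#' barnardTest(5, 5, 5, 5)$pValue   # 1: perfectly homogeneous
#' @export
barnardTest <- function(a, b = NULL, c = NULL, d = NULL,
                        piGrid = seq(0.001, 0.999, by = 0.001)) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == c(2L, 2L)))
        b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
    }
    cnt <- c(a, b, c, d)
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
        .stopf("cell counts must be non-negative integers")
    if (sum(cnt) < 1L) .stopf("empty table: test undefined")
    m1 <- a + c; m2 <- b + d          # fixed column totals
    if (m1 == 0L && m2 == 0L) .stopf("both column margins are zero")
    x1 <- 0:m1; x2 <- 0:m2
    p1 <- if (m1 > 0) x1 / m1 else 0
    p2 <- if (m2 > 0) x2 / m2 else 0
    pooled <- outer(x1, x2, `+`) / (m1 + m2)
    se <- sqrt(pooled * (1 - pooled) * (1 / max(m1, 1) + 1 / max(m2, 1)))
    T <- outer(p1, p2, `-`) / se
    T[!is.finite(T)] <- 0             # degenerate pooled proportion
    Tobs <- T[a + 1L, b + 1L]
    R <- (abs(T) >= abs(Tobs) - 1e-7) * 1
    pvals <- vapply(piGrid, function(p) {
        d1 <- stats::dbinom(x1, m1, p)
        d2 <- stats::dbinom(x2, m2, p)
        as.numeric(t(d1) %*% R %*% d2)
    }, 0)
    i <- which.max(pvals)
    list(pValue = min(max(pvals[i], 0), 1), statistic = Tobs,
         piMax = piGrid[i])
}
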