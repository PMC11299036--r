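#' Expected rooted-triplet probabilities on a one-reticulation network
#'
#' For groups (A, B = hybrid, C) with inheritance probability `gamma` from
#' the A side and internal branch lengths `tA`, `tC` (coalescent units)
#' above the two attachment points:
#' \deqn{P(AB|C) = \gamma (1 - \tfrac{2}{3} e^{-tA}) + (1-\gamma) \tfrac{1}{3} e^{-tC}}
#' \deqn{P(BC|A) = (1-\gamma)(1 - \tfrac{2}{3} e^{-tC}) + \gamma \tfrac{1}{3} e^{-tA}}
#' \deqn{P(AC|B) = \gamma \tfrac{1}{3} e^{-tA} + (1-\gamma) \tfrac{1}{3} e^{-tC}}
#' The three probabilities sum to one for any parameter values.
#'
#' @param gamma inheritance probability, in \[0,1\].
#' @param tA,tC internal branch lengths (>= 0).
#' @return named numeric: `AB`, `BC`, `AC`.
#' @export
tripletModelProbs <- function(gamma, tA, tC) {
  xa <- exp(-tA) / 3; xc <- exp(-tC) / 3
  c(AB = gamma * (1 - 2 * xa) + (1 - gamma) * xc,
    BC = (1 - gamma) * (1 - 2 * xc) + gamma * xa,
    AC = gamma * xa + (1 - gamma) * xc)
}

#' Fit gamma on a fixed one-reticulation network from triplet counts
#'
#' Maximizes the multinomial likelihood of the rooted-triplet counts
#' (`nAB`, `nBC`, `nAC`) under [tripletModelProbs()].  With three counts
#' the unconstrained model (gamma, tA, tC) has one more parameter than the
#' data have degrees of freedom and its likelihood surface is an exact
#' ridge, so the default fit constrains `tA == tC` (a single reticulation
#' time), under which gamma is exactly identified with closed form
#' `gamma_hat = (nAB - nAC) / (nAB + nBC - 2 nAC)`.  The unconstrained fit
#' is available with `equalDepths = FALSE` and reports
#' `identifiable = FALSE` when the profile likelihood over gamma is flat
#' within `flatTol` log units.
#'
#' @param counts a [TripletCounts-class] (see [tripletFrequencies()]) with
#'   groups ordered (A, B = hybrid, C).
#' @param equalDepths constrain `tA == tC` (default `TRUE`).
#' @param flatTol log-likelihood range below which the gamma profile is
#'   considered flat.
#' @return a [NetworkFit-class].
#' @export
fitTripletNetwork <- function(counts, equalDepths = TRUE, flatTol = 0.01) {
  stopifnot(is(counts, "TripletCounts"))
  n <- c(AB = counts@nAB, BC = counts@nBC, AC = counts@nAC)
  if (any(n < 0)) stop("negative counts")
  if (sum(n) < 1) stop("triplet counts sum to zero")
  eps <- 1e-12
  nll <- function(par) {  # par = (gamma, tA, tC)
    p <- tripletModelProbs(par[1], par[2], par[3])
    -sum(n * log(pmax(p, eps)))
  }
  if (equalDepths) {
    obj <- function(par) nll(c(par[1], par[2], par[2]))
    best <- NULL
    for (g0 in c(0.2, 0.5, 0.8)) {
      o <- stats::optim(c(g0, 1), obj, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    gam <- best$par[1]; tA <- tC <- best$par[2]
    val <- -best$value
    prof <- vapply(seq(0.02, 0.98, length.out = 25), function(g)
      -stats::optimize(function(t) obj(c(g, t)), c(0, 10))$objective, 1)
    ident <- (max(prof) - min(prof)) > flatTol
  } else {
    best <- NULL
    for (g0 in c(0.2, 0.5, 0.8)) {
      o <- stats::optim(c(g0, 1, 1), nll, method = "L-BFGS-B",
                        lower = c(0, 0, 0), upper = c(1, 10, 10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    gam <- best$par[1]; tA <- best$par[2]; tC <- best$par[3]
    val <- -best$value
    prof <- vapply(seq(0.02, 0.98, length.out = 25), function(g) {
      o <- stats::optim(c(1, 1), function(tt) nll(c(g, tt[1], tt[2])),
                        method = "L-BFGS-B", lower = c(0, 0),
                        upper = c(10, 10))
      -o$value
    }, 1)
    ident <- (max(prof) - min(prof)) > flatTol
  }
  new("NetworkFit", gammaHat = gam, tA = tA, tC = tC, logPL = val,
      identifiable = ident, equalDepths = equalDepths)
}
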