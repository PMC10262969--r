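#' Discrete-gamma category rates
#'
#' Rates for `ncat` equal-probability categories of a mean-1 gamma
#' distribution with shape `alpha`: each category's rate is the conditional
#' mean of its gamma slice (not the median), renormalized so the rates
#' average exactly 1.
#'
#' @param alpha gamma shape (> 0); small values mean strong rate variation
#' @param ncat number of categories (>= 1)
#' @return numeric vector of `ncat` positive rates with mean 1
#' @examples
#' gammaCategoryRates(0.5, 4)
#' @export
gammaCategoryRates <- function(alpha, ncat) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(1)
  ncat <- as.integer(ncat)
  qs <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  # E[X; X in slice] for mean-1 gamma = F_{alpha+1}(upper) - F_{alpha+1}(lower)
  cum <- pgamma(qs, shape = alpha + 1, rate = alpha)
  r <- ncat * diff(cum)
  r / mean(r)
}

.exchToMatrix <- function(exch, ns) {
  S <- matrix(0, ns, ns)
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  S
}

#' Build a GTR+Gamma substitution model
#'
#' Constructs the normalized model used by both the simulator and the
#' likelihood engine. The rate matrix is `Q[i,j] = s[i,j] * pi[j]` for
#' `i != j`, scaled so the expected substitution rate at equilibrium is 1
#' (when `pInv > 0` the gamma category rates are rescaled by `1/(1-pInv)` so
#' the overall mean rate, counting invariant sites, is 1). Detailed balance
#' `pi_i Q_ij = pi_j Q_ji` holds by construction.
#'
#' @param pi base frequencies (A, C, G, T), non-negative, summing to 1 within
#'   1e-9
#' @param exch six positive exchangeabilities, order AC, AG, AT, CG, CT, GT
#' @param alpha gamma shape (> 0)
#' @param ncat number of discrete gamma categories (default 4)
#' @param pInv proportion of invariant sites in \[0, 1) (default 0)
#' @return a [GTRGamma-class] object
#' @examples
#' jc <- buildModel(rep(0.25, 4), rep(1, 6), alpha = 1)
#' @export
buildModel <- function(pi, exch, alpha, ncat = 4, pInv = 0) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 4 non-negative frequencies summing to 1")
  if (length(exch) != 6 || any(exch <= 0))
    stop("exch must be 6 positive exchangeabilities (AC,AG,AT,CG,CT,GT)")
  if (alpha <= 0) stop("alpha must be positive")
  if (pInv < 0 || pInv >= 1) stop("pInv must be in [0, 1)")
  pi <- setNames(as.numeric(pi), ACGT)
  # order AC,AG,AT,CG,CT,GT fills the lower triangle column-wise:
  # (2,1)=AC (3,1)=AG (4,1)=AT (3,2)=CG (4,2)=CT (4,3)=GT
  S <- .exchToMatrix(exch, 4)
  .finishModel(ACGT, pi, as.numeric(exch), S, alpha, ncat, pInv)
}

#' Two-state purine/pyrimidine reversible model
#'
#' The 2-state reduction of GTR used for RY-coded alignments: states R
#' (purines) and Y (pyrimidines), an estimable state frequency and a single
#' exchange rate, normalized to mean rate 1, with the same discrete-gamma
#' machinery as the nucleotide model.
#'
#' @param piR equilibrium frequency of R (default 0.5)
#' @param alpha gamma shape
#' @param ncat gamma categories
#' @param pInv invariant proportion
#' @return a [GTRGamma-class] with 2 states
#' @export
ryModel <- function(piR = 0.5, alpha = 1, ncat = 4, pInv = 0) {
  stopifnot(piR > 0, piR < 1)
  pi <- c(R = piR, Y = 1 - piR)
  S <- matrix(c(0, 1, 1, 0), 2, 2)
  .finishModel(c("R", "Y"), pi, 1, S, alpha, ncat, pInv)
}

.finishModel <- function(states, pi, exch, S, alpha, ncat, pInv) {
  ns <- length(states)
  Q <- S * rep(pi, each = ns)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("non-normalizable model (zero total rate)")
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  # symmetric decomposition: B = D^{1/2} Q D^{-1/2} with D = diag(pi)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  evec <- eig$vectors / sq          # D^{-1/2} U
  ievec <- t(eig$vectors) * rep(sq, each = ns)  # U' D^{1/2}
  rates <- gammaCategoryRates(alpha, ncat)
  if (pInv > 0) rates <- rates / (1 - pInv)
  new("GTRGamma", states = states, pi = pi, exch = exch, alpha = alpha,
      ncat = as.integer(ncat), pInv = pInv, Q = Q, catRates = rates,
      eigenVals = eig$values, eigenVecs = evec, eigenInv = ievec)
}

#' Rebuild a model with new equilibrium frequencies
#'
#' Keeps the exchangeabilities and the rate-variation settings, replaces the
#' base frequencies, and renormalizes; used by the nonstationary simulator to
#' derive branch-specific generators.
#'
#' @param model a [GTRGamma-class]
#' @param pi new frequency vector (must sum to 1)
#' @return a new [GTRGamma-class]
#' @export
withFrequencies <- function(model, pi) {
  ns <- length(model@states)
  if (length(pi) != ns || abs(sum(pi) - 1) > 1e-8)
    stop("frequency vector must match the state space and sum to 1")
  pi <- setNames(as.numeric(pi), model@states)
  S <- .exchToMatrix(model@exch, ns)
  .finishModel(model@states, pi, model@exch, S, model@alpha, model@ncat,
               model@pInv)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model a [GTRGamma-class]
#' @param t branch length (expected substitutions/site at rate 1), >= 0
#' @param rate category rate multiplier (default 1)
#' @return a stochastic matrix (rows sum to 1)
#' @examples
#' transitionMatrix(buildModel(rep(.25, 4), rep(1, 6), 1), 0.1)
#' @export
transitionMatrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  ns <- length(model@states)
  P <- model@eigenVecs %*% (exp(model@eigenVals * t * rate) * model@eigenInv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model@states, model@states)
  P
}

#' Category rates and weights including the invariant class
#'
#' Internal: appends the rate-0 invariant class (weight `pInv`) to the gamma
#' categories (each weight `(1-pInv)/ncat`), the layout the likelihood core
#' expects.
#' @noRd
.modelCats <- function(model) {
  w <- rep((1 - model@pInv) / model@ncat, model@ncat)
  r <- model@catRates
  if (model@pInv > 0) {
    r <- c(r, 0)
    w <- c(w, model@pInv)
  }
  list(rates = r, weights = w)
}

#' Serialize / parse a model as a small structured text block
#'
#' A human-readable `key: value` block (frequencies, exchangeabilities,
#' alpha, ncat, pInv) for embedding in config files and result logs.
#'
#' @param model a [GTRGamma-class]
#' @return `modelText()`: a character scalar; `parseModelText()`: a
#'   [GTRGamma-class]
#' @export
modelText <- function(model) {
  paste0(
    "states: ", paste(model@states, collapse = " "), "\n",
    "pi: ", paste(format(model@pi, digits = 12), collapse = " "), "\n",
    "exch: ", paste(format(model@exch, digits = 12), collapse = " "), "\n",
    "alpha: ", format(model@alpha, digits = 12), "\n",
    "ncat: ", model@ncat, "\n",
    "pInv: ", format(model@pInv, digits = 12), "\n"
  )
}

#' @rdname modelText
#' @param text a block produced by `modelText()`
#' @export
parseModelText <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  kv <- strsplit(lines, ":\\s*")
  vals <- setNames(lapply(kv, function(x) strsplit(trimws(x[2]), "\\s+")[[1]]),
                   vapply(kv, `[`, "", 1))
  pi <- as.numeric(vals$pi)
  if (identical(vals$states, c("R", "Y")))
    ryModel(pi[1], as.numeric(vals$alpha), as.integer(vals$ncat),
            as.numeric(vals$pInv))
  else
    buildModel(pi, as.numeric(vals$exch), as.numeric(vals$alpha),
               as.integer(vals$ncat), as.numeric(vals$pInv))
}
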