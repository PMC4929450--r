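#' GTR instantaneous rate matrix
#'
#' Builds the 4x4 general time-reversible rate matrix `Q` with off-diagonal
#' entries `q_xy = s_xy * pi_y`, where `s_xy` are the six exchangeabilities
#' (`a`: A-C, `b`: A-G, `c`: A-T, `d_rate`: C-G, `e`: C-T, `f`: G-T) and
#' `pi` the stationary base frequencies. Rows sum to zero and detailed
#' balance `pi_x q_xy = pi_y q_yx` holds by construction.
#'
#' @param gtr_rates Named list of the six exchangeabilities (see
#'   [sim_config()] for defaults).
#' @param base_freqs Stationary base frequencies in A, C, G, T order.
#' @param normalize If `TRUE` (default) scale `Q` so the expected number of
#'   substitutions per site per unit time, `-sum(pi * diag(Q))`, equals 1.
#' @return A 4x4 numeric matrix with dimnames `A, C, G, T`.
#' @export
#' @examples
#' Q <- build_gtr_matrix()
#' rowSums(Q)  # ~0
build_gtr_matrix <- function(gtr_rates = list(a = 0.987, b = 0.11, c = 0.218,
                                              d_rate = 0.243, e = 0.395,
                                              f = 1.0),
                             base_freqs = rep(0.25, 4),
                             normalize = TRUE) {
  s <- unlist(gtr_rates[c("a", "b", "c", "d_rate", "e", "f")])
  if (any(is.na(s)) || any(s < 0))
    stop("gtr_rates must supply non-negative a, b, c, d_rate, e, f")
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-12)
    stop("base_freqs must be 4 non-negative values summing to 1")
  bases <- c("A", "C", "G", "T")
  R <- matrix(0, 4, 4, dimnames = list(bases, bases))
  R["A", "C"] <- R["C", "A"] <- s[1]
  R["A", "G"] <- R["G", "A"] <- s[2]
  R["A", "T"] <- R["T", "A"] <- s[3]
  R["C", "G"] <- R["G", "C"] <- s[4]
  R["C", "T"] <- R["T", "C"] <- s[5]
  R["G", "T"] <- R["T", "G"] <- s[6]
  Q <- R %*% diag(base_freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(base_freqs * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  dimnames(Q) <- list(bases, bases)
  Q
}

#' Mean rates of the discrete-gamma rate-heterogeneity categories
#'
#' Equal-probability discretization of a Gamma(`alpha`, rate = `alpha`)
#' distribution (mean 1): category `c` carries the conditional mean of the
#' distribution between its quantile boundaries.
#'
#' @param alpha Gamma shape parameter.
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rate multipliers with mean 1.
#' @export
#' @examples
#' gamma_category_rates(1, 8)
gamma_category_rates <- function(alpha, ncat) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1L) return(1)
  b <- qgamma((0:ncat) / ncat, shape = alpha, rate = alpha)
  r <- ncat * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r) * 1  # guard against discretization round-off
}

# eigen machinery for P(t) = exp(Qt); GTR is reversible, so Q is
# symmetrizable and the decomposition is numerically stable
gtr_eigen <- function(Q, base_freqs) {
  d <- sqrt(base_freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  list(U = diag(1 / d) %*% eg$vectors,
       Uinv = t(eg$vectors) %*% diag(d),
       values = eg$values)
}

# 4x4 transition probability matrix for elapsed substitution time t
gtr_ptrans <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
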