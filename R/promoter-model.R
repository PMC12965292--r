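#' Promoter kinetics for the nonsequential three-state bursting model
#'
#' The model has one transcriptionally competent ON state and two OFF states,
#' each connected to ON but not to each other (ON <-> OFF1, ON <-> OFF2).
#' While ON, Pol II initiates as a Poisson process with rate `k_ini`.
#' `k1_minus`/`k2_minus` are the ON -> OFF entry rates and `k1_plus`/`k2_plus`
#' the OFF -> ON exit rates, so the mean OFF sojourns are `1/k1_plus` and
#' `1/k2_plus`. All rates are per second.
#'
#' @param k_ini Pol II initiation rate while ON (initiations / s).
#' @param k1_minus,k1_plus ON -> OFF1 and OFF1 -> ON rates (/ s).
#' @param k2_minus,k2_plus ON -> OFF2 and OFF2 -> ON rates (/ s).
#' @return An object of class `promoter_kinetics` with the five rates plus
#'   derived `p_on` (stationary ON probability) and mean OFF durations
#'   `off1_duration_s = 1/k1_plus`, `off2_duration_s = 1/k2_plus`.
#' @examples
#' k <- promoter_kinetics(k_ini = 0.25, k1_minus = 0.15, k1_plus = 1 / 6,
#'                        k2_minus = 0.01, k2_plus = 1 / 145)
#' k$p_on
#' @export
promoter_kinetics <- function(k_ini, k1_minus, k1_plus, k2_minus, k2_plus) {
  rates <- c(k_ini = k_ini, k1_minus = k1_minus, k1_plus = k1_plus,
             k2_minus = k2_minus, k2_plus = k2_plus)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (k1_minus > 0 && k1_plus <= 0)
    stop("k1_plus must be > 0 when OFF1 is reachable (k1_minus > 0)")
  if (k2_minus > 0 && k2_plus <= 0)
    stop("k2_plus must be > 0 when OFF2 is reachable (k2_minus > 0)")
  ratio1 <- if (k1_minus > 0) k1_minus / k1_plus else 0
  ratio2 <- if (k2_minus > 0) k2_minus / k2_plus else 0
  p_on <- 1 / (1 + ratio1 + ratio2)
  structure(list(
    k_ini = k_ini, k1_minus = k1_minus, k1_plus = k1_plus,
    k2_minus = k2_minus, k2_plus = k2_plus,
    p_on = p_on,
    off1_duration_s = if (k1_plus > 0) 1 / k1_plus else Inf,
    off2_duration_s = if (k2_plus > 0) 1 / k2_plus else Inf
  ), class = "promoter_kinetics")
}

#' @export
print.promoter_kinetics <- function(x, ...) {
  cat("Nonsequential 3-state promoter kinetics (per second):\n")
  cat(sprintf("  k_ini = %.4g  k1- = %.4g  k1+ = %.4g  k2- = %.4g  k2+ = %.4g\n",
              x$k_ini, x$k1_minus, x$k1_plus, x$k2_minus, x$k2_plus))
  cat(sprintf("  p_ON = %.4g; mean OFF durations %.4g s and %.4g s\n",
              x$p_on, x$off1_duration_s, x$off2_duration_s))
  invisible(x)
}

#' Default kinetic regime used by the synthetic-data generators
#'
#' ON/OFF architecture with short (~6 s) and long (~145 s) OFF states and an
#' initiation rate giving tens of nascent transcripts at the peak of an active
#' period, the regime characteristic of strongly induced Notch-target
#' promoters in the follicular epithelium.
#'
#' @return A `promoter_kinetics` object.
#' @export
default_kinetics <- function() {
  promoter_kinetics(k_ini = 0.25, k1_minus = 0.15, k1_plus = 1 / 6,
                    k2_minus = 0.01, k2_plus = 1 / 145)
}

#' Absorbing generator of the inter-initiation waiting time
#'
#' Sub-generator on the transient states (ON, OFF1, OFF2) of the chain in
#' which a Pol II initiation (rate `k_ini`, possible only from ON) is treated
#' as absorption. The waiting time between successive initiations is the
#' phase-type absorption time of this chain started in ON.
#'
#' @param kinetics A `promoter_kinetics` object.
#' @return A 3x3 matrix (rows/cols ON, OFF1, OFF2).
#' @keywords internal
absorbing_generator <- function(kinetics) {
  with(kinetics, rbind(
    c(-(k_ini + k1_minus + k2_minus), k1_minus, k2_minus),
    c(k1_plus, -k1_plus, 0),
    c(k2_plus, 0, -k2_plus)
  ))
}

#' Closed-form phase-type survival of inter-initiation waiting times
#'
#' Eigen-decomposes the absorbing generator to express the waiting-time
#' survival as S(t) = sum_i A_i exp(lambda_i t) with sum(A_i) = 1 and
#' lambda_i < 0. Components are ordered by |lambda| descending.
#'
#' @param kinetics A `promoter_kinetics` object with `k_ini > 0`.
#' @return List with `amplitudes`, `rates` (the negative exponents),
#'   `survival` (vectorized function of time), `cdf`, and `mean_wait_s`
#'   (equal to 1 / (p_on * k_ini)).
#' @export
phase_type_survival <- function(kinetics) {
  if (kinetics$k_ini <= 0) stop("k_ini must be > 0 for a finite waiting time")
  Q <- absorbing_generator(kinetics)
  eig <- eigen(Q)
  lambda <- eig$values
  V <- eig$vectors
  # S(t) = e_ON' exp(Qt) 1  =>  A_i = V[1, i] * (V^-1 1)_i
  A <- V[1, ] * solve(V, rep(1, 3))
  if (max(abs(Im(lambda))) > 1e-9 * max(abs(Re(lambda))))
    stop("complex eigenvalues: generator is not diagonalizable over the reals")
  lambda <- Re(lambda); A <- Re(A)
  ord <- order(abs(lambda), decreasing = TRUE)
  lambda <- lambda[ord]; A <- A[ord]
  surv <- function(t) {
    vapply(t, function(ti) sum(A * exp(lambda * ti)), numeric(1))
  }
  list(amplitudes = A, rates = lambda,
       survival = surv,
       cdf = function(t) 1 - surv(t),
       mean_wait_s = 1 / (kinetics$p_on * kinetics$k_ini))
}

#' Invert a three-component survival fit into promoter rates
#'
#' Solves the five rates of the nonsequential three-state model whose
#' analytic phase-type waiting-time survival has the fitted amplitudes and
#' exponents. With the constraint sum(A_i) = 1 the fit carries five free
#' quantities, matching the five rates, so the system is determined. The
#' inversion uses moment/charpoly identities of the absorbing generator Q:
#' sum(A l)   = -k_ini,
#' sum(A l^2) =  k_ini (k_ini + k1- + k2-),
#' trace(Q)   =  sum(l),
#' det(Q)     = -k_ini k1+ k2+ = prod(l),
#' e2(Q)      =  k1+ k2+ + k2+ (k_ini + k1-) + k1+ (k_ini + k2-).
#' OFF1 is canonicalized as the shorter-lived OFF state (k1+ >= k2+).
#'
#' @param fit A `multiexp_fit` with 3 components, or a list with numeric
#'   `amplitudes` and `rates` (negative exponents, length 3).
#' @param tol Tolerance below which small negative rate estimates are
#'   clipped to zero before the feasibility check.
#' @return A `promoter_kinetics` object.
#' @export
infer_kinetics <- function(fit, tol = 1e-8) {
  A <- fit$amplitudes; l <- fit$rates
  if (length(A) != 3L || length(l) != 3L)
    stop("kinetic inversion requires a 3-component fit")
  if (abs(sum(A) - 1) > 1e-6)
    stop("amplitudes must sum to 1")
  if (any(l >= 0)) stop("exponents must be negative")
  k_ini <- -sum(A * l)
  if (k_ini <= 0) stop("infeasible fit: implied k_ini <= 0")
  s <- sum(A * l^2) / k_ini - k_ini            # k1- + k2-
  p <- -sum(l) - k_ini - s                     # k1+ + k2+
  q <- -prod(l) / k_ini                        # k1+ k2+
  disc <- p^2 - 4 * q
  if (p < -tol || q < -tol || disc < -tol * max(p^2, 1))
    stop("infeasible fit: no real nonnegative solution for the OFF exit rates")
  disc <- max(disc, 0)
  k1p <- (p + sqrt(disc)) / 2                  # short-lived OFF first
  k2p <- (p - sqrt(disc)) / 2
  e2 <- l[1] * l[2] + l[1] * l[3] + l[2] * l[3]
  if (abs(k2p - k1p) < tol * max(k1p, 1))
    stop("infeasible fit: degenerate OFF exit rates (k1+ == k2+)")
  k1m <- (e2 - q - k_ini * p - k1p * s) / (k2p - k1p)
  k2m <- s - k1m
  rates <- c(k1m, k2m, k1p, k2p)
  if (any(rates < -tol * max(abs(rates), 1)))
    stop("infeasible fit: negative promoter rates; fit inconsistent with the topology")
  rates <- pmax(rates, 0)
  promoter_kinetics(k_ini = k_ini, k1_minus = rates[1], k1_plus = rates[3],
                    k2_minus = rates[2], k2_plus = rates[4])
}
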