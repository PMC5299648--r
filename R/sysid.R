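#' Discrete rational transfer function
#'
#' Constructs a discrete-time transfer function
#' \deqn{G(z) = \frac{b_n z^n + \dots + b_0}{z^m + a_{m-1} z^{m-1} + \dots + a_0}}
#' with coefficients stored in descending powers of \eqn{z}. The denominator
#' is monic (leading coefficient exactly 1) and the model has no feedthrough:
#' the numerator order \eqn{n} is strictly below the denominator order
#' \eqn{m}, so the current output never depends on the current input sample.
#'
#' @param num numeric vector of numerator coefficients \eqn{b_n \dots b_0}
#'   (descending powers).
#' @param den numeric vector of denominator coefficients
#'   \eqn{1, a_{m-1} \dots a_0} (descending powers, monic).
#' @return An object of class `"dtf"` with elements `num` and `den`.
#' @examples
#' dtf(1, c(1, -0.5))   # G(z) = 1 / (z - 0.5)
#' @export
dtf <- function(num, den) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (length(den) < 2L)
    stop("denominator order must be at least 1", call. = FALSE)
  if (!all(is.finite(num)) || !all(is.finite(den)))
    stop("transfer-function coefficients must be finite", call. = FALSE)
  if (den[1L] != 1)
    stop("denominator must be monic (leading coefficient exactly 1)",
         call. = FALSE)
  if (length(num) > length(den) - 1L)
    stop("no feedthrough allowed: numerator order must be strictly below ",
         "denominator order", call. = FALSE)
  structure(list(num = num, den = den), class = "dtf")
}

#' @export
print.dtf <- function(x, ...) {
  cat(sprintf("Discrete transfer function (num order %d, den order %d)\n",
              num_order(x), den_order(x)))
  cat("  num:", paste(signif(x$num, 6), collapse = " "), "\n")
  cat("  den:", paste(signif(x$den, 6), collapse = " "), "\n")
  invisible(x)
}

#' @rdname dtf
#' @param tf a `"dtf"` object.
#' @export
num_order <- function(tf) length(tf$num) - 1L

#' @rdname dtf
#' @export
den_order <- function(tf) length(tf$den) - 1L

is_dtf <- function(x) inherits(x, "dtf")

## Core simulator: difference equation with zero initial conditions.
## May return non-finite values; callers decide how to react.
.sim_dtf <- function(num, den, x) {
  m <- length(den) - 1L
  n <- length(num) - 1L
  nx <- length(x)
  ## MA part: numerator taps sit at delays (m-n)..m  (no feedthrough)
  bb <- c(rep(0, m - n), num)
  xpad <- c(rep(0, m), x)
  v <- stats::filter(xpad, bb, method = "convolution", sides = 1L)
  v <- as.numeric(v)[(m + 1L):(m + nx)]
  ## AR part: y[t] = v[t] - sum_k a_{m-k} y[t-k]
  y <- stats::filter(v, -den[-1L], method = "recursive")
  as.numeric(y)
}

#' Simulate a transfer function's response
#'
#' Runs the difference equation
#' \eqn{y_t = -\sum_{k=1}^m a_{m-k} y_{t-k} + \sum_{j=0}^n b_j x_{t-(m-j)}}
#' with zero initial conditions (terms reaching before the first sample are
#' zero). The output has the same length as the input.
#'
#' @param tf a [dtf()] object.
#' @param x numeric input vector (all values finite).
#' @return Numeric vector `y`, same length as `x`.
#' @examples
#' simulate_tf(dtf(1, c(1, -0.5)), c(1, 0, 0, 0, 0))  # 0 1 0.5 0.25 0.125
#' @export
simulate_tf <- function(tf, x) {
  stopifnot(is_dtf(tf))
  x <- as.numeric(x)
  if (!all(is.finite(x)))
    stop("input signal must be finite", call. = FALSE)
  y <- .sim_dtf(tf$num, tf$den, x)
  if (!all(is.finite(y))) {
    bad <- which(!is.finite(y))[1L]
    stop(sprintf("unstable simulation: non-finite output at sample %d", bad),
         call. = FALSE)
  }
  y
}

#' Goodness of fit between measured and simulated signals
#'
#' The normalized-root-mean-square fit expressed as a percentage,
#' \deqn{GF = 100 \left(1 - \frac{\lVert y_m - y_s\rVert_2}
#'   {\lVert y_m - \bar y_m\rVert_2}\right),}
#' where \eqn{y_m} is the measured signal and \eqn{y_s} the model
#' simulation. 100 means a perfect fit; 0 means the model does no better
#' than the mean of the measured signal; the value can be negative.
#'
#' @param y_measured measured signal (must not be constant).
#' @param y_simulated simulated signal, same length.
#' @return Scalar fit percentage (at most 100).
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # 100 * (1 - 1/sqrt(2))
#' @export
goodness_of_fit <- function(y_measured, y_simulated) {
  y_measured <- as.numeric(y_measured)
  y_simulated <- as.numeric(y_simulated)
  if (length(y_measured) != length(y_simulated))
    stop("signals must have equal length", call. = FALSE)
  if (length(y_measured) < 2L)
    stop("signals must have length at least 2", call. = FALSE)
  denom <- sqrt(sum((y_measured - mean(y_measured))^2))
  if (denom == 0)
    stop("measured signal is constant: goodness of fit undefined",
         call. = FALSE)
  100 * (1 - sqrt(sum((y_measured - y_simulated)^2)) / denom)
}

## Pack/unpack the free parameters: theta = (b_n..b_0, a_{m-1}..a_0)
.theta_to_tf <- function(theta, n, m) {
  dtf(theta[seq_len(n + 1L)], c(1, theta[(n + 2L):(n + 1L + m)]))
}

## ARX (equation-error) least squares at the stated orders.
.arx_init <- function(x, y, n, m) {
  N <- length(y)
  t_idx <- (m + 1L):N
  xcols <- lapply((m - n):m, function(d) x[t_idx - d])
  ycols <- lapply(1:m, function(k) -y[t_idx - k])
  X <- do.call(cbind, c(xcols, ycols))
  fit <- stats::lm.fit(X, y[t_idx])
  theta <- fit$coefficients
  theta[!is.finite(theta)] <- 0
  unname(theta)
}

## Reflect poles outside the unit circle to its inside (1/conj), keeping
## the denominator real and monic.
.reflect_poles <- function(den) {
  r <- polyroot(rev(den))
  out <- Mod(r) >= 1
  if (!any(out)) return(den)
  r[out] <- 1 / Conj(r[out])
  still <- Mod(r) >= 1                   # poles exactly on the circle
  r[still] <- 0.99 * r[still] / Mod(r[still])
  poly_from_roots(r)
}

## Least-squares numerator given a fixed denominator: the simulated
## output is linear in the numerator coefficients.
.num_ls_given_den <- function(x, y, n, m, den) {
  S <- vapply(n:0, function(j) .sim_dtf(c(1, rep(0, j)), den, x),
              numeric(length(x)))
  fit <- stats::lm.fit(S, y)
  num <- fit$coefficients
  num[!is.finite(num)] <- 0
  unname(num)
}

#' Estimate a transfer function between an input and output signal
#'
#' Output-error identification of a discrete rational transfer function
#' with no feedthrough. Two stages: an equation-error (ARX) linear
#' least-squares fit of the difference equation provides the starting
#' point, then a damped Gauss-Newton (Levenberg-Marquardt) iteration
#' minimizes the simulation error \eqn{\sum_t (y_t - \hat y_t(\theta))^2},
#' where \eqn{\hat y(\theta)} is the zero-initial-condition simulation of
#' the candidate model. Steps are accepted only when they reduce the cost,
#' so the refinement never does worse than its initialization; if the
#' refinement cannot simulate finitely it is abandoned and the
#' initialization is returned with `converged = FALSE`.
#'
#' @param x input signal.
#' @param y output signal, same length as `x`, not constant.
#' @param num_order numerator order \eqn{n} (at most `den_order - 1`).
#' @param den_order denominator order \eqn{m} (at least 1).
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param tol relative cost-change convergence tolerance.
#' @return A `"tf_fit"` object: `tf` (the [dtf()] estimate), `gf`
#'   (goodness of fit of the simulation against `y`), `converged`, and
#'   `n_iter`.
#' @export
estimate_tf <- function(x, y, num_order, den_order,
                        max_iter = 100L, tol = 1e-8) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- as.integer(num_order); m <- as.integer(den_order)
  if (m < 1L) stop("den_order must be at least 1", call. = FALSE)
  if (n > m - 1L)
    stop("num_order must be at most den_order - 1 (no feedthrough)",
         call. = FALSE)
  if (n < 0L) stop("num_order must be non-negative", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(y) <= 10L * m)
    stop("signals too short for the requested denominator order",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("signals must be finite", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("output signal is constant: fit undefined", call. = FALSE)

  p <- n + 1L + m
  sim_theta <- function(th) .sim_dtf(th[seq_len(n + 1L)],
                                     c(1, th[(n + 2L):p]), x)
  cost_of <- function(ys) {
    if (!all(is.finite(ys))) return(Inf)
    sum((y - ys)^2)
  }

  ## Initialization: equation-error (ARX) least squares; when its poles
  ## land outside the unit circle (common for smooth, heavily averaged
  ## signals) the simulation explodes, so two stabilized alternatives are
  ## also scored — the ARX denominator with unstable poles reflected
  ## inside the circle (numerator re-fit by least squares, which is
  ## linear given fixed poles), and an all-zero denominator (FIR) start.
  ## The finite-cost candidate with the smallest simulation error seeds
  ## the refinement.
  theta_arx <- .arx_init(x, y, n, m)
  candidates <- list(theta_arx)
  den_arx <- c(1, theta_arx[(n + 2L):p])
  den_ref <- .reflect_poles(den_arx)
  if (any(den_ref != den_arx))
    candidates <- c(candidates,
                    list(c(.num_ls_given_den(x, y, n, m, den_ref),
                           den_ref[-1L])))
  den_fir <- c(1, rep(0, m))
  candidates <- c(candidates,
                  list(c(.num_ls_given_den(x, y, n, m, den_fir),
                         den_fir[-1L])))
  costs <- vapply(candidates,
                  function(th) cost_of(sim_theta(th)), numeric(1))
  theta <- candidates[[which.min(costs)]]

  ys <- sim_theta(theta)
  cost <- cost_of(ys)
  converged <- FALSE
  iter <- 0L

  if (is.finite(cost)) {
    lambda <- 1e-3
    while (iter < max_iter) {
      iter <- iter + 1L
      ## numerical Jacobian of the simulation wrt theta
      J <- matrix(0, length(y), p)
      for (i in seq_len(p)) {
        h <- 1e-6 * (abs(theta[i]) + 1e-6)
        th2 <- theta; th2[i] <- th2[i] + h
        yi <- sim_theta(th2)
        if (!all(is.finite(yi))) yi <- ys   # one-sided fallback: zero column
        J[, i] <- (yi - ys) / h
      }
      r <- y - ys
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, r)
      dscale <- diag(JtJ)
      dscale[dscale < 1e-12] <- 1e-12
      accepted <- FALSE
      for (try_i in 1:12) {
        A <- JtJ + lambda * diag(dscale, p)
        delta <- tryCatch(solve(A, Jtr), error = function(e) NULL)
        if (!is.null(delta)) {
          th_new <- theta + as.numeric(delta)
          ys_new <- sim_theta(th_new)
          cost_new <- cost_of(ys_new)
          if (cost_new < cost) {
            rel <- (cost - cost_new) / max(cost, .Machine$double.eps)
            theta <- th_new; ys <- ys_new; cost <- cost_new
            lambda <- lambda * 0.1
            accepted <- TRUE
            if (rel <= tol) converged <- TRUE
            break
          }
        }
        lambda <- lambda * 10
      }
      if (!accepted) { converged <- TRUE; break }  # no improving step exists
      if (converged) break
    }
  }

  tf <- .theta_to_tf(theta, n, m)
  gf <- if (all(is.finite(ys))) goodness_of_fit(y, ys) else -Inf
  structure(list(tf = tf, gf = gf, converged = converged, n_iter = iter),
            class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  cat(sprintf("Transfer-function fit: GF = %.2f%% (%s after %d iterations)\n",
              x$gf, if (x$converged) "converged" else "not converged",
              x$n_iter))
  print(x$tf)
  invisible(x)
}

#' Stability of a discrete transfer function
#'
#' A discrete system is (asymptotically) stable when every pole, i.e. every
#' root of the denominator polynomial, lies strictly inside the unit
#' circle. Reported as a diagnostic only; estimation does not constrain
#' stability because the fit criterion is evaluated over a finite window.
#'
#' @param tf a [dtf()] object.
#' @return `TRUE` if all poles have modulus below 1.
#' @export
is_stable <- function(tf) {
  stopifnot(is_dtf(tf))
  roots <- polyroot(rev(tf$den))
  all(Mod(roots) < 1)
}

#' Build the monic polynomial with given roots
#'
#' Returns real coefficients in descending powers. Complex roots must come
#' in conjugate pairs for the result to be genuinely real; a tiny residual
#' imaginary part from floating arithmetic is dropped.
#'
#' @param roots numeric or complex vector of roots (may be empty).
#' @return Numeric coefficient vector, leading coefficient 1.
#' @export
poly_from_roots <- function(roots) {
  p <- c(1 + 0i)
  for (r in roots) p <- c(p, 0) - r * c(0, p)
  Re(p)
}

## Evaluate a descending-power polynomial at a point.
.polyval <- function(coef, z) sum(coef * z^(rev(seq_along(coef)) - 1))

#' Draw a random stable transfer function
#'
#' Poles are placed inside a disc of radius `pole_radius` (complex poles in
#' conjugate pairs), zeros likewise within `zero_radius`, and the gain is
#' normalized so the DC gain \eqn{G(1)} equals `dc_gain`. Used to seed
#' simulation studies of the estimator.
#'
#' @param num_order,den_order model orders (`num_order <= den_order - 1`).
#' @param pole_radius,zero_radius maximum root modulus.
#' @param dc_gain target gain at \eqn{z = 1}.
#' @return A stable [dtf()] object.
#' @export
random_stable_dtf <- function(num_order, den_order,
                              pole_radius = 0.8, zero_radius = 0.9,
                              dc_gain = 1) {
  draw_roots <- function(k, radius) {
    roots <- complex(0)
    while (k >= 2L) {
      r <- stats::runif(1, 0.1, radius)
      th <- stats::runif(1, 0.05, pi - 0.05)
      roots <- c(roots, complex(modulus = r, argument = th),
                 complex(modulus = r, argument = -th))
      k <- k - 2L
    }
    if (k == 1L) roots <- c(roots, complex(real = stats::runif(1, -radius, radius)))
    roots
  }
  den <- poly_from_roots(draw_roots(den_order, pole_radius))
  num <- poly_from_roots(draw_roots(num_order, zero_radius))
  g1 <- .polyval(num, 1)
  if (abs(g1) < 1e-3) num[length(num)] <- num[length(num)] + sign(g1 + 1e-12) * 0.5
  num <- num * dc_gain * .polyval(den, 1) / .polyval(num, 1)
  dtf(num, den)
}

#' Read and write transfer functions as JSON
#'
#' The JSON dialect is `{"num": [b_n..b_0], "den": [1, a_{m-1}..a_0],
#' "fs": <Hz>}` with full-precision numbers; a write-then-read round trip
#' reproduces the coefficients exactly as written.
#'
#' @param tf a [dtf()] object.
#' @param path file path.
#' @param fs optional sampling frequency (Hz) recorded alongside.
#' @return `read_tf_json` returns a list with elements `tf` and `fs`.
#' @export
write_tf_json <- function(tf, path, fs = NULL) {
  stopifnot(is_dtf(tf))
  obj <- list(num = tf$num, den = tf$den)
  if (!is.null(fs)) obj$fs <- fs
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tf_json
#' @export
read_tf_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(tf = dtf(obj$num, obj$den),
       fs = if (is.null(obj$fs)) NA_real_ else as.numeric(obj$fs))
}
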