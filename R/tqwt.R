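#' Tunable Q-factor wavelet transform parameters
#'
#' Bundles and validates the three TQWT parameters: the Q-factor `Q`
#' (oscillation count of the wavelet), the redundancy `r` (oversampling of
#' the frame) and the number of decomposition levels `J`. The derived
#' scaling factors are `beta = 2 / (Q + 1)` (high-pass) and
#' `alpha = 1 - beta / r` (low-pass); validity requires `alpha + beta > 1`
#' (oversampled filter bank), which holds for all `Q >= 1`, `r > 1`.
#'
#' The pipeline default `tqwt_params(2, 3, 17)` yields 18 sub-bands.
#'
#' @param q_factor Q-factor, real `>= 1`.
#' @param redundancy Redundancy r, real `> 1`.
#' @param levels Number of levels J, positive integer.
#' @return An object of class `"tqwt_params"`: a list with the three
#'   parameters plus `alpha` and `beta`.
#' @examples
#' tqwt_params()          # Q = 2, r = 3, J = 17
#' tqwt_params(1, 3, 4)
#' @export
tqwt_params <- function(q_factor = 2, redundancy = 3, levels = 17) {
  if (!is.numeric(q_factor) || length(q_factor) != 1L || q_factor < 1) {
    stop("`q_factor` must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(redundancy) || length(redundancy) != 1L || redundancy <= 1) {
    stop("`redundancy` must be a single number > 1", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 1L) {
    stop("`levels` must be a single positive integer", call. = FALSE)
  }
  beta <- 2 / (q_factor + 1)
  alpha <- 1 - beta / redundancy
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta <= 1, alpha + beta > 1)
  structure(
    list(q_factor = q_factor, redundancy = redundancy, levels = levels,
         alpha = alpha, beta = beta),
    class = "tqwt_params"
  )
}

#' @export
print.tqwt_params <- function(x, ...) {
  cat(sprintf("TQWT parameters: Q = %g, r = %g, J = %d (alpha = %.4f, beta = %.4f)\n",
              x$q_factor, x$redundancy, x$levels, x$alpha, x$beta))
  invisible(x)
}

# Daubechies-style transition function theta(w) = (1 + cos w) sqrt(2 - cos w) / 2
# evaluated on a t-point grid; satisfies theta(w)^2 + theta(pi - w)^2 = 1,
# which is what gives the filter bank perfect reconstruction.
tqwt_transition <- function(t) {
  v <- seq_len(t) / (t + 1) * pi
  (1 + cos(v)) * sqrt(2 - cos(v)) / 2
}

# Sub-band DFT lengths at level j for an (even) input length n.
tqwt_sizes <- function(n, params, j) {
  list(n0 = 2 * round(params$alpha^j * n / 2),
       n1 = 2 * round(params$beta * params$alpha^(j - 1) * n / 2))
}

# One analysis split in the DFT domain. X is the unitary DFT of the current
# low-pass signal; returns the unitary DFTs of the next low-pass (length n0)
# and the high-pass sub-band (length n1).
tqwt_afb <- function(X, n0, n1) {
  n <- length(X)
  p <- (n - n1) / 2              # low-pass pass-band
  t <- (n0 + n1 - n) / 2 - 1     # transition band
  s <- (n - n0) / 2              # low-pass stop-band
  if (p < 0 || t < 0 || s < 0) {
    stop("TQWT level infeasible for this signal length", call. = FALSE)
  }
  tr <- tqwt_transition(t)
  V0 <- complex(n0)
  V1 <- complex(n1)
  ip <- seq_len(p); it <- seq_len(t); is <- seq_len(s)
  V0[1] <- X[1]
  if (p > 0) {
    V0[1 + ip] <- X[1 + ip]
    V0[n0 + 1 - ip] <- X[n + 1 - ip]
  }
  if (t > 0) {
    V0[1 + p + it] <- X[1 + p + it] * tr
    V0[n0 + 1 - p - it] <- X[n + 1 - p - it] * tr
    V1[1 + it] <- X[1 + p + it] * tr[t + 1 - it]
    V1[n1 + 1 - it] <- X[n + 1 - p - it] * tr[t + 1 - it]
  }
  if (s > 0) {
    V1[1 + t + is] <- X[1 + p + t + is]
    V1[n1 + 1 - t - is] <- X[n + 1 - p - t - is]
  }
  V1[n1 / 2 + 1] <- X[n / 2 + 1]   # Nyquist goes to the high-pass band
  list(V0 = V0, V1 = V1)
}

# One synthesis merge, inverting tqwt_afb exactly (theta^2 + theta_rev^2 = 1).
tqwt_sfb <- function(V0, V1, n) {
  n0 <- length(V0)
  n1 <- length(V1)
  p <- (n - n1) / 2
  t <- (n0 + n1 - n) / 2 - 1
  s <- (n - n0) / 2
  tr <- tqwt_transition(t)
  Y <- complex(n)
  ip <- seq_len(p); it <- seq_len(t); is <- seq_len(s)
  Y[1] <- V0[1]
  if (p > 0) {
    Y[1 + ip] <- V0[1 + ip]
    Y[n + 1 - ip] <- V0[n0 + 1 - ip]
  }
  if (t > 0) {
    Y[1 + p + it] <- V0[1 + p + it] * tr + V1[1 + it] * tr[t + 1 - it]
    Y[n + 1 - p - it] <- V0[n0 + 1 - p - it] * tr + V1[n1 + 1 - it] * tr[t + 1 - it]
  }
  if (s > 0) {
    Y[1 + p + t + is] <- V1[1 + t + is]
    Y[n + 1 - p - t - is] <- V1[n1 + 1 - t - is]
  }
  Y[n / 2 + 1] <- V1[n1 / 2 + 1]
  Y
}

udft <- function(x) stats::fft(x) / sqrt(length(x))
iudft <- function(X) Re(stats::fft(X, inverse = TRUE) / sqrt(length(X)))

#' Maximum feasible TQWT depth for a signal length
#'
#' The low-pass branch shrinks by the factor `alpha` per level, so only
#' finitely many levels fit. The depth returned is the largest `J` whose
#' every level keeps a valid (non-negative pass/transition/stop band) split
#' and whose coarsest low-pass band retains at least 8 samples — the
#' documented floor that avoids degenerate sub-bands.
#'
#' @param signal_length Number of samples (odd lengths are padded by one
#'   before analysis, which is accounted for here).
#' @param params A [tqwt_params()] object; `params$levels` is ignored.
#' @return The largest feasible number of levels (0 when even one level
#'   does not fit).
#' @examples
#' max_levels(7650, tqwt_params(2, 3, 17))  # >= 17
#' max_levels(16, tqwt_params(2, 3, 1))
#' @export
max_levels <- function(signal_length, params = tqwt_params()) {
  n <- as.integer(signal_length)
  if (is.na(n) || n <= 0) return(0L)
  if (n %% 2L == 1L) n <- n + 1L
  j <- 0L
  ncur <- n
  repeat {
    sz <- tqwt_sizes(n, params, j + 1L)
    if (sz$n0 < 8 || sz$n1 < 2 ||
        (ncur - sz$n1) / 2 < 0 ||
        (sz$n0 + sz$n1 - ncur) / 2 - 1 < 0 ||
        (ncur - sz$n0) / 2 < 0) {
      return(j)
    }
    j <- j + 1L
    ncur <- sz$n0
  }
}

#' Tunable Q-factor wavelet decomposition
#'
#' Decomposes a real signal into `J + 1` sub-bands (J high-pass detail
#' bands, finest first, followed by the final low-pass band) with the
#' DFT-domain two-channel filter bank: at each level the spectrum is split
#' by low-pass scaling with factor `alpha` and high-pass scaling with
#' factor `beta`, joined over a Daubechies-style transition band, and the
#' recursion continues on the low-pass part. The transform is linear and
#' invertible ([tqwt_reconstruct()] recovers the signal to machine
#' precision).
#'
#' Odd-length signals are zero-padded by one sample before analysis (the
#' DFT splits require even lengths); the pad is recorded and stripped again
#' on reconstruction.
#'
#' @param signal Real-valued numeric vector.
#' @param params A [tqwt_params()] object; the default (Q = 2, r = 3,
#'   J = 17) produces 18 sub-bands.
#' @return An object of class `"tqwt_subbands"`: list with `bands` (list of
#'   `J + 1` numeric vectors of non-increasing length), `params`,
#'   `original_length` and `padded`.
#' @examples
#' sb <- tqwt_decompose(rnorm(512), tqwt_params(1, 3, 4))
#' length(sb$bands)   # 5
#' @export
tqwt_decompose <- function(signal, params = tqwt_params()) {
  if (!is.numeric(signal) || anyNA(signal)) {
    stop("`signal` must be a numeric vector without missing values",
         call. = FALSE)
  }
  n_orig <- length(signal)
  padded <- n_orig %% 2L == 1L
  x <- if (padded) c(signal, 0) else signal
  n <- length(x)
  jmax <- max_levels(n_orig, params)
  if (params$levels > jmax) {
    stop("levels = ", params$levels, " exceeds the maximum feasible depth ",
         jmax, " for a signal of length ", n_orig, call. = FALSE)
  }
  X <- udft(x)
  bands <- vector("list", params$levels + 1L)
  for (j in seq_len(params$levels)) {
    sz <- tqwt_sizes(n, params, j)
    ab <- tqwt_afb(X, sz$n0, sz$n1)
    bands[[j]] <- iudft(ab$V1)
    X <- ab$V0
  }
  bands[[params$levels + 1L]] <- iudft(X)
  structure(
    list(bands = bands, params = params, original_length = n_orig,
         padded = padded),
    class = "tqwt_subbands"
  )
}

#' Inverse tunable Q-factor wavelet transform
#'
#' Rebuilds the signal from a [tqwt_decompose()] output by running the
#' synthesis filter bank from the coarsest level up. Because the analysis
#' and synthesis transition weights satisfy
#' `theta(w)^2 + theta(pi - w)^2 = 1`, reconstruction is exact up to
#' floating-point rounding.
#'
#' @param subbands A `"tqwt_subbands"` object.
#' @return Numeric vector of length `subbands$original_length`.
#' @examples
#' x <- rnorm(300)
#' max(abs(tqwt_reconstruct(tqwt_decompose(x, tqwt_params(2, 3, 5))) - x))
#' @export
tqwt_reconstruct <- function(subbands) {
  if (!inherits(subbands, "tqwt_subbands")) {
    stop("`subbands` must be a \"tqwt_subbands\" object", call. = FALSE)
  }
  params <- subbands$params
  jn <- params$levels
  n <- subbands$original_length + as.integer(subbands$padded)
  if (length(subbands$bands) != jn + 1L) {
    stop("expected ", jn + 1L, " sub-bands, got ", length(subbands$bands),
         call. = FALSE)
  }
  for (j in seq_len(jn)) {
    want <- tqwt_sizes(n, params, j)$n1
    if (length(subbands$bands[[j]]) != want) {
      stop("sub-band ", j, " has length ", length(subbands$bands[[j]]),
           " but the parameters imply ", want, call. = FALSE)
    }
  }
  X <- udft(subbands$bands[[jn + 1L]])
  for (j in jn:1) {
    nup <- if (j > 1L) tqwt_sizes(n, params, j - 1L)$n0 else n
    V1 <- udft(subbands$bands[[j]])
    X <- tqwt_sfb(X, V1, nup)
  }
  y <- iudft(X)
  if (subbands$padded) y <- y[-length(y)]
  y
}

#' @export
print.tqwt_subbands <- function(x, ...) {
  lens <- vapply(x$bands, length, 0L)
  cat(sprintf("TQWT decomposition: %d sub-bands of a length-%d signal (Q = %g, r = %g, J = %d)\n",
              length(x$bands), x$original_length, x$params$q_factor,
              x$params$redundancy, x$params$levels))
  cat("  band lengths:", paste(lens, collapse = " "), "\n")
  invisible(x)
}
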