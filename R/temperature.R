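#' Proportional (geometric) cooling schedule
#'
#' Fifteen temperatures T0..T14.  T14 is room temperature (300 K); T0 is
#' defined so that the Metropolis acceptance probability of a 10 kcal/mol
#' energy increase is 0.5, i.e. T0 = dE_ref / (kB ln 2) ~ 7260 K.
#' Intermediate temperatures follow the proportional schedule
#' T_k = T0 (T14/T0)^(k/14), the geometric interpolation standard in
#' simulated annealing.
#'
#' @param n_steps Number of temperatures (default 15, indices 0..14).
#' @param t_final Final temperature in Kelvin (default 300).
#' @param dE_ref Reference uphill step in kcal/mol (default 10).
#' @param p0 Target acceptance probability of \code{dE_ref} at T0
#'   (default 0.5).
#' @param kB Boltzmann constant in kcal/(mol K).
#' @return Object of class \code{temperature_schedule}: numeric vector
#'   \code{temps} (Kelvin, strictly decreasing) plus the defining constants.
#' @examples
#' s <- temperature_schedule()
#' s$temps[1]    # ~7260 K
#' s$temps[15]   # 300 K
#' @export
temperature_schedule <- function(n_steps = 15, t_final = 300, dE_ref = 10,
                                 p0 = 0.5, kB = KB_KCAL) {
  t0 <- dE_ref / (kB * (-log(p0)))
  k <- seq_len(n_steps) - 1
  temps <- t0 * (t_final / t0)^(k / (n_steps - 1))
  temps[n_steps] <- t_final  # exact endpoint
  structure(list(temps = temps, dE_ref = dE_ref, p0 = p0, kB = kB),
            class = "temperature_schedule")
}

#' @export
print.temperature_schedule <- function(x, ...) {
  cat("temperature_schedule:", length(x$temps), "steps,",
      sprintf("T0 = %.1f K .. T%d = %.1f K\n", x$temps[1],
              length(x$temps) - 1, x$temps[length(x$temps)]))
  invisible(x)
}

#' Metropolis acceptance probability
#'
#' 1 for downhill or flat moves; exp(-dE / (kB T)) uphill.
#'
#' @param deltaE Energy difference child - parent, kcal/mol.
#' @param T Temperature in Kelvin, > 0.
#' @param kB Boltzmann constant in kcal/(mol K).
#' @return Probability in (0, 1].
#' @export
acceptance_probability <- function(deltaE, T, kB = KB_KCAL) {
  if (any(T <= 0)) stop("temperature must be positive")
  ifelse(deltaE <= 0, 1, exp(-deltaE / (kB * T)))
}

#' Metropolis acceptance decision
#'
#' Draws one uniform variate from the current R RNG stream when the move is
#' uphill; downhill moves never consume randomness.
#'
#' @inheritParams acceptance_probability
#' @return Logical.
#' @export
metropolis_accept <- function(deltaE, T, kB = KB_KCAL) {
  if (T <= 0) stop("temperature must be positive")
  if (deltaE <= 0) return(TRUE)
  stats::runif(1) < exp(-deltaE / (kB * T))
}

#' Reactive temperature controller configuration
#'
#' The planner monitors the lowest lRMSD-to-goal among nodes added during
#' non-overlapping windows of \code{w} iterations.  Improvement below
#' \code{d1} raises the temperature (index moves toward T0); improvement of
#' at least \code{d2} lowers it (index moves toward T14).
#'
#' @param w Window length in tree-growth iterations (default 100).
#' @param d1 Minimum improvement in Angstrom below which the temperature is
#'   raised (default 0.25).
#' @param d2 Improvement in Angstrom at or above which the temperature is
#'   lowered (default 1.5).
#' @param start_index Starting temperature index on the 0..14 schedule
#'   (default 9, the medium temperature).
#' @return Object of class \code{reactive_config}.
#' @export
reactive_config <- function(w = 100, d1 = 0.25, d2 = 1.5, start_index = 9) {
  if (w < 1) stop("window length must be >= 1")
  if (!(0 < d1 && d1 < d2)) stop("require 0 < d1 < d2")
  if (start_index < 0 || start_index > 14) stop("start index must be in 0..14")
  structure(list(w = w, d1 = d1, d2 = d2, start_index = as.integer(start_index)),
            class = "reactive_config")
}

#' One reactive temperature update
#'
#' Pure function of the window statistics.  Improvement is
#' \code{prev_best - window_best}; improvement < d1 decrements the index
#' (hotter, toward T0), improvement >= d2 increments it (cooler, toward
#' T14), otherwise the index is unchanged.  The result is clamped to
#' [0, 14].  Note the direction: \emph{raising} the temperature means a
#' \emph{lower} schedule index.
#'
#' @param window_best Lowest lRMSD-to-goal among nodes added in the current
#'   window (Angstrom).
#' @param prev_best Lowest lRMSD-to-goal in the previous window (Angstrom).
#' @param index Current temperature index in 0..14.
#' @param cfg A \code{\link{reactive_config}}.
#' @param max_index Highest (coolest) index, default 14.
#' @return New integer index in [0, max_index].
#' @export
reactive_update <- function(window_best, prev_best, index, cfg = reactive_config(),
                            max_index = 14) {
  if (index < 0 || index > max_index) stop("index out of range")
  improvement <- prev_best - window_best
  new <- if (improvement < cfg$d1) index - 1L
         else if (improvement >= cfg$d2) index + 1L
         else as.integer(index)
  max(0L, min(as.integer(max_index), new))
}

#' Acceptance-calibrated medium temperature
#'
#' A fixed "medium" temperature defined so a 10 kcal/mol increase is
#' accepted with probability \code{p}.  With the default p = 0.1 this gives
#' ~2186 K; note the schedule-derived T9 (~936 K) is a different number —
#' both conventions are exposed and the planner defaults to schedule T9.
#'
#' @param dE kcal/mol (default 10).
#' @param p Acceptance probability (default 0.1).
#' @param kB Boltzmann constant.
#' @return Temperature in Kelvin.
#' @export
medium_temperature <- function(dE = 10, p = 0.1, kB = KB_KCAL) {
  dE / (kB * (-log(p)))
}
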