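#' Discounted person-years of exposure over a time interval
#'
#' Integrates the continuous-time discount factor \eqn{(1+r)^{-t}} over
#' \code{[t_start, t_end]} in closed form:
#' \deqn{\int_{t_0}^{t_1} (1+r)^{-t}\,dt =
#'       \frac{(1+r)^{-t_0} - (1+r)^{-t_1}}{\log(1+r)}.}
#' Multiplying the result by a constant utility (or utility difference) gives
#' the discounted QALY contribution of a flat health-state segment. At
#' \code{rate = 0} the integral reduces to the plain duration
#' \code{t_end - t_start}.
#'
#' @param t_start,t_end interval bounds in years from model start;
#'   \code{0 <= t_start <= t_end}.
#' @param rate annual discount rate as a fraction (e.g. \code{0.035});
#'   \code{0 <= rate < 1}.
#' @return Discounted person-years (a non-negative scalar).
#' @examples
#' discounted_exposure(0, 10, 0)      # 10
#' discounted_exposure(0, 10, 0.035)  # < 10
#' @export
discounted_exposure <- function(t_start, t_end, rate) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(rate))
  if (any(!is.finite(c(t_start, t_end, rate)))) {
    stop("discounted_exposure: non-finite input", call. = FALSE)
  }
  if (t_start < 0 || t_start > t_end) {
    stop("discounted_exposure: requires 0 <= t_start <= t_end", call. = FALSE)
  }
  if (rate < 0 || rate >= 1) {
    stop("discounted_exposure: rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) {
    return(t_end - t_start)
  }
  lr <- log1p(rate)
  ((1 + rate)^(-t_start) - (1 + rate)^(-t_end)) / lr
}

#' Present value of a lump-sum cost
#'
#' Discounts a single payment incurred \code{at_time} years from model start:
#' \code{amount * (1 + rate)^(-at_time)}. Costs in this framework are episodic
#' lump sums (a surgery, a block of productivity loss) rather than continuous
#' flows, so each is discounted from its declared incurrence time.
#'
#' @param amount payment in currency units; must be non-negative.
#' @param at_time incurrence time in years from model start; non-negative.
#' @param rate annual discount rate as a fraction in \code{[0, 1)}.
#' @return Present value in the same currency units.
#' @examples
#' discount_lump(1000, 0, 0.035)   # 1000
#' discount_lump(1000, 20, 0.035)  # 1000 * 1.035^-20
#' @export
discount_lump <- function(amount, at_time, rate) {
  stopifnot(is.numeric(amount), is.numeric(at_time), is.numeric(rate))
  if (any(!is.finite(c(amount, at_time, rate)))) {
    stop("discount_lump: non-finite input", call. = FALSE)
  }
  if (amount < 0) stop("discount_lump: amount must be >= 0", call. = FALSE)
  if (at_time < 0) stop("discount_lump: at_time must be >= 0", call. = FALSE)
  if (rate < 0 || rate >= 1) {
    stop("discount_lump: rate must lie in [0, 1)", call. = FALSE)
  }
  amount * (1 + rate)^(-at_time)
}
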