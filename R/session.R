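#' Define the recording-session timeline
#'
#' A session is a 1-h protocol: a 20-min baseline (BL) followed by two
#' intraperitoneal cytokine injections, by default at 20 and 40 min. The
#' cytokine order is counterbalanced across mice, so the first post-injection
#' period (C1) may correspond to either TNF or IL-1beta.
#'
#' All times are seconds; periods are half-open intervals `[start, end)`.
#'
#' @param bl_min Baseline length, minutes.
#' @param inj_min Injection times, minutes (length 2, strictly increasing).
#' @param order Cytokine order, a permutation of `c("TNF", "IL1B")`.
#' @param total_min Session length, minutes.
#' @return A `session_plan` list with period boundaries in seconds.
#' @examples
#' session_plan()
#' session_plan(order = c("IL1B", "TNF"))
#' @export
session_plan <- function(bl_min = 20, inj_min = c(20, 40),
                         order = c("TNF", "IL1B"), total_min = 60) {
  stopifnot(length(inj_min) == 2, inj_min[1] < inj_min[2],
            inj_min[2] < total_min, bl_min <= inj_min[1])
  if (!setequal(order, c("TNF", "IL1B")) || length(order) != 2) {
    stop("`order` must be a permutation of c(\"TNF\", \"IL1B\")")
  }
  structure(list(
    bl_s = bl_min * 60,
    inj_s = inj_min * 60,
    order = order,
    total_s = total_min * 60
  ), class = "session_plan")
}

#' Period label for each time point of a session
#'
#' @param times Numeric vector, seconds.
#' @param plan A [session_plan()].
#' @return Factor with levels `BL`, `C1`, `C2`.
#' @export
period_at <- function(times, plan) {
  lab <- ifelse(times < plan$inj_s[1], "BL",
                ifelse(times < plan$inj_s[2], "C1", "C2"))
  factor(lab, levels = c("BL", "C1", "C2"))
}

#' Cytokine identity of each session period
#'
#' @param plan A [session_plan()].
#' @return Named character vector mapping `C1`/`C2` to `TNF`/`IL1B`.
#' @export
period_cytokine <- function(plan) {
  stats::setNames(plan$order, c("C1", "C2"))
}

# Multiplier applied to a unit's rate in each period: cytokine responses act
# as multiplicative steps at the injection times, and the second response
# compounds on the first.
period_multipliers <- function(response_c1, response_c2) {
  c(BL = 1,
    C1 = 1 + response_c1,
    C2 = (1 + response_c1) * (1 + response_c2))
}

#' @export
print.session_plan <- function(x, ...) {
  cyt <- period_cytokine(x)
  cat(sprintf(
    "<session_plan> %.0f min: BL [0, %.0f) s | C1 = %s [%.0f, %.0f) s | C2 = %s [%.0f, %.0f) s\n",
    x$total_s / 60, x$inj_s[1], cyt[["C1"]], x$inj_s[1], x$inj_s[2],
    cyt[["C2"]], x$inj_s[2], x$total_s))
  invisible(x)
}
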