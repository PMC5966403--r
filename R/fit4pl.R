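# Four-parameter logistic dose-response fitting.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + (EC50/x)^{hill}}}
#' parameterised in log-concentration (`log(EC50)` is the free
#' parameter) and solved by Levenberg-Marquardt damping
#' ([minpack.lm::nls.lm()]).  The Hill slope is constrained positive.
#' Initial values are `top = max(y)`, `bottom = min(y)`, EC50 at the
#' geometric mid-concentration and `hill = 1`.  An EC50 estimate
#' falling outside the tested concentration range extended ten-fold in
#' either direction is not reported (the data cannot support it); the
#' fit is then returned with `converged = FALSE` and a message.
#'
#' @param conc concentrations (> 0), at least 4 distinct values.
#' @param response responses, same length as `conc`, finite.
#' @return a [DoseResponseFit-class] object.
#' @examples
#' x <- c(1, 4, 16, 64, 256); y <- 100 / (1 + 16 / x)
#' fit <- fit4PL(rep(x, 2), rep(y, 2))
#' ec50(fit)  # 16
#' @export
fit4PL <- function(conc, response) {
  if (length(conc) != length(response))
    stop("conc and response must have the same length")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (!all(is.finite(response))) stop("responses must be finite")
  if (length(unique(conc)) < 4)
    stop("InsufficientDoses: need >= 4 distinct concentrations")

  nObs <- length(response)
  fail <- function(msg)
    new("DoseResponseFit", converged = FALSE, nObs = as.integer(nObs),
        message = msg,
        residualSSE = sum((response - mean(response))^2))
  if (stats::var(response) == 0)
    return(fail("constant response across doses; curve unidentifiable"))

  lx <- log(conc)
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (p[3] - lx)))
  start <- c(bottom = min(response), top = max(response),
             lec50 = mean(range(lx)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) response - model(p),
      lower = c(-Inf, -Inf, -Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(fail("optimiser failed to converge"))

  cf <- fit$par
  ec <- exp(cf[["lec50"]])
  lo <- 0.1 * min(conc); hi <- 10 * max(conc)
  if (ec < lo || ec > hi)
    return(fail(sprintf(
      "EC50 estimate %.3g outside supported range [%.3g, %.3g]",
      ec, lo, hi)))
  new("DoseResponseFit",
      bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
      ec50 = unname(ec), hill = unname(cf[["hill"]]),
      residualSSE = sum((response - model(cf))^2),
      converged = TRUE, nObs = as.integer(nObs), message = "")
}
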