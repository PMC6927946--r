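# Recovery of the exponential learning model from an event log.

#' Fit the exponential learning model to a discrimination log
#'
#' Maximum-likelihood fit of the agent learning model to the per-trial
#' lick/no-lick responses of one animal: on S+ trials the lick probability
#' is `h_inf - (h_inf - h0) * exp(-n / tau)`, on S- trials
#' `f_inf + (f0 - f_inf) * exp(-n / tau)`, with `n` the number of completed
#' discrimination trials before the trial. The five parameters are fitted
#' jointly by Bernoulli likelihood (L-BFGS-B on a logit/log scale).
#'
#' @param records Trial-record data frame (completed discrimination trials
#'   of a single animal; aborted entries are dropped).
#' @return List with elements `h0`, `h_inf`, `f0`, `f_inf`, `tau`,
#'   `logLik`, `convergence`.
#' @export
fit_learning_model <- function(records) {
  records <- records[records$outcome != "ABORTED" &
                       records$trial_label %in% c(S_PLUS, S_MINUS), ,
                     drop = FALSE]
  if (nrow(records) < 50L)
    stop("need at least 50 completed discrimination trials to fit", call. = FALSE)
  n <- seq_len(nrow(records)) - 1L
  splus <- records$trial_label == S_PLUS
  licked <- records$outcome %in% c("HIT", "FALSE_ALARM")

  inv_logit <- function(x) 1 / (1 + exp(-x))
  nll <- function(theta) {
    h0 <- inv_logit(theta[1]); h_inf <- inv_logit(theta[2])
    f0 <- inv_logit(theta[3]); f_inf <- inv_logit(theta[4])
    tau <- exp(theta[5])
    e <- exp(-n / tau)
    p <- ifelse(splus, h_inf - (h_inf - h0) * e, f_inf + (f0 - f_inf) * e)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(ifelse(licked, log(p), log(1 - p)))
  }
  start <- c(stats::qlogis(0.8), stats::qlogis(0.95),
             stats::qlogis(0.8), stats::qlogis(0.1), log(100))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(rep(-7, 4), log(1)),
                      upper = c(rep(7, 4), log(5000)))
  list(h0 = inv_logit(fit$par[1]), h_inf = inv_logit(fit$par[2]),
       f0 = inv_logit(fit$par[3]), f_inf = inv_logit(fit$par[4]),
       tau = exp(fit$par[5]), logLik = -fit$value,
       convergence = fit$convergence)
}
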