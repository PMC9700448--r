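# Closed-form queueing results used as independent oracles for the event
# engine (M/M/1 sojourn, Erlang C delay probability, M/M/c waiting time).

#' Erlang C delay probability and M/M/c waiting time
#'
#' `erlang_c` returns the probability an arriving customer must wait in an
#' M/M/c queue with offered load `a = lambda/mu` Erlangs; `mmc_wq` the mean
#' waiting time in queue and `mm1_sojourn` the M/M/1 mean sojourn
#' `1/(mu - lambda)`.  These are test oracles: the event engine must
#' reproduce them within Monte-Carlo tolerance.
#'
#' @param lambda Arrival rate (per minute).
#' @param mu Per-server service rate (per minute).
#' @param c Number of servers.
#' @return A probability (`erlang_c`) or minutes (`mmc_wq`, `mm1_sojourn`).
#' @export
erlang_c <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  if (rho >= 1) return(1)
  # sum a^k/k! computed stably in log space
  lt <- c(0, cumsum(log(a) - log(seq_len(c))))   # log(a^k/k!), k = 0..c
  m <- max(lt)
  s_below <- sum(exp(lt[seq_len(c)] - m))        # k = 0..c-1
  top <- exp(lt[c + 1] - m) / (1 - rho)
  top / (s_below + top)
}

#' @rdname erlang_c
#' @export
mmc_wq <- function(lambda, mu, c) {
  rho <- lambda / (c * mu)
  if (rho >= 1) return(Inf)
  erlang_c(lambda, mu, c) / (c * mu - lambda)
}

#' @rdname erlang_c
#' @export
mm1_sojourn <- function(lambda, mu) {
  if (lambda >= mu) return(Inf)
  1 / (mu - lambda)
}
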