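#' Analytic M/M/1 steady-state metrics
#'
#' @param lambda arrival rate (per hour).
#' @param mu service rate (per hour).
#' @return tibble with `rho = lambda/mu`, mean number in system
#'   `L = rho/(1-rho)` and mean sojourn time `W = 1/(mu-lambda)` hours.
#' @examples
#' analytic_mm1(0.5, 1)  # rho 0.5, L 1, W 2
#' @export
analytic_mm1 <- function(lambda, mu) {
  if (lambda <= 0 || mu <= 0) abort("rates must be > 0")
  if (lambda >= mu) abort("no steady state: lambda must be < mu")
  rho <- lambda / mu
  tibble(rho = rho, L = rho / (1 - rho), W = 1 / (mu - lambda))
}

#' Analytic M/M/c steady-state metrics (Erlang C)
#'
#' @param lambda arrival rate (per hour).
#' @param mu per-server service rate (per hour).
#' @param servers number of servers `c`.
#' @return tibble with utilization `rho`, probability of waiting `p_wait`
#'   (the Erlang-C probability), mean queue length `Lq`, mean number in
#'   system `L`, and mean sojourn `W`.
#' @export
analytic_mmc <- function(lambda, mu, servers) {
  if (lambda <= 0 || mu <= 0) abort("rates must be > 0")
  if (servers < 1 || servers != round(servers)) {
    abort("`servers` must be a positive integer")
  }
  a <- lambda / mu                      # offered load (Erlangs)
  rho <- a / servers
  if (rho >= 1) abort("no steady state: lambda must be < servers * mu")
  k <- 0:(servers - 1)
  p0_inv <- sum(a^k / factorial(k)) + a^servers / (factorial(servers) * (1 - rho))
  p_wait <- (a^servers / (factorial(servers) * (1 - rho))) / p0_inv
  lq <- p_wait * rho / (1 - rho)
  l <- lq + a
  tibble(rho = rho, p_wait = p_wait, Lq = lq, L = l, W = l / lambda)
}

#' Simulate an M/M/c queue by discrete events
#'
#' Patient flow model: Poisson arrivals, exponential service on `servers`
#' parallel servers, FIFO discipline and an infinite waiting room. Returns
#' time-averaged metrics after discarding the first 10% of the horizon as
#' burn-in, plus a queue-length time series used to derive the congestion
#' index that modulates the detector's prior.
#'
#' @param lambda arrival rate (per hour).
#' @param mu per-server service rate (per hour).
#' @param servers number of servers (default 1).
#' @param horizon simulated length in hours.
#' @param seed integer seed.
#' @param series_points number of equally spaced sample points in the
#'   queue-length series.
#' @return an object of class `queue_metrics`: a list with `utilization`,
#'   time-averaged `L`, mean sojourn `W`, `lambda_effective` (post-burn-in
#'   throughput), `congestion_index`, `stable` (FALSE when `rho >= 1`), and
#'   `series` (tibble of `time`, `n_in_system`).
#' @examples
#' m <- simulate_queue(0.5, 1, horizon = 2000, seed = 1)
#' m$L  # close to the analytic value 1.0
#' @export
simulate_queue <- function(lambda, mu, servers = 1, horizon = 10000,
                           seed = 1, series_points = 200) {
  if (lambda <= 0 || mu <= 0) abort("rates must be > 0")
  if (servers < 1) abort("`servers` must be >= 1")
  set.seed(seed)
  rho <- lambda / (servers * mu)
  stable <- rho < 1

  # arrivals on [0, horizon]
  n_exp <- ceiling(lambda * horizon + 6 * sqrt(lambda * horizon) + 10)
  arr <- cumsum(rexp(n_exp, lambda))
  while (arr[length(arr)] < horizon) {
    arr <- c(arr, arr[length(arr)] + cumsum(rexp(n_exp, lambda)))
  }
  arr <- arr[arr <= horizon]
  n <- length(arr)
  if (n == 0) abort("no arrivals within horizon; increase lambda or horizon")
  svc <- rexp(n, mu)

  free <- numeric(servers)          # next-free time per server
  start <- numeric(n)
  for (i in seq_len(n)) {
    j <- which.min(free)
    start[i] <- max(arr[i], free[j])
    free[j] <- start[i] + svc[i]
  }
  depart <- start + svc
  sojourn <- depart - arr

  burn <- 0.1 * horizon
  # time-average number in system over [burn, horizon] from the step function
  times <- c(arr, depart)
  steps <- c(rep(1, n), rep(-1, n))
  ord <- order(times)
  times <- times[ord]; steps <- steps[ord]
  nsys <- cumsum(steps)
  grid_t <- c(burn, times[times > burn & times < horizon], horizon)
  n_at <- function(t) {
    i <- findInterval(t, times)
    ifelse(i == 0, 0, nsys[pmax(i, 1)])
  }
  seg_n <- n_at(grid_t[-length(grid_t)])
  L <- sum(seg_n * diff(grid_t)) / (horizon - burn)

  keep <- arr >= burn
  W <- mean(sojourn[keep])
  lambda_eff <- sum(keep) / (horizon - burn)

  ts_grid <- seq(burn, horizon, length.out = series_points)
  series <- tibble(time = ts_grid, n_in_system = n_at(ts_grid))

  structure(list(
    utilization = rho, L = L, W = W, lambda_effective = lambda_eff,
    congestion_index = min(rho, 1), stable = stable, series = series,
    config = list(lambda = lambda, mu = mu, servers = servers,
                  horizon = horizon, seed = seed)),
    class = "queue_metrics")
}

#' @export
print.queue_metrics <- function(x, ...) {
  cat(sprintf("<queue_metrics> M/M/%d rho=%.3f%s  L=%.3f  W=%.3f h\n",
              x$config$servers, x$utilization,
              if (x$stable) "" else " (unstable)", x$L, x$W))
  invisible(x)
}

#' Congestion index from queue metrics
#'
#' The scalar coupling surface between the patient-flow model and the
#' detector: by default the utilization clamped to `[0, 1]`, optionally a
#' saturating transform of the mean queue length. Monotone in utilization.
#'
#' @param metrics a `queue_metrics` object (or a bare utilization number).
#' @param method `"utilization"` (default, `min(rho, 1)`) or `"occupancy"`
#'   (`L / (1 + L)`).
#' @return congestion index in `[0, 1]`.
#' @export
congestion_index <- function(metrics, method = c("utilization", "occupancy")) {
  method <- match.arg(method)
  if (is.numeric(metrics)) {
    return(pmin(pmax(metrics, 0), 1))
  }
  switch(method,
         utilization = min(max(metrics$utilization, 0), 1),
         occupancy = metrics$L / (1 + metrics$L))
}

#' Plot the simulated queue-length trajectory
#'
#' @param metrics a `queue_metrics` object.
#' @return a ggplot object.
#' @export
plot_queue <- function(metrics) {
  ggplot2::ggplot(metrics$series,
                  ggplot2::aes(x = .data$time, y = .data$n_in_system)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = metrics$L, linetype = 2) +
    ggplot2::labs(x = "time (h)", y = "patients in system",
                  title = sprintf("M/M/%d queue, utilization %.2f",
                                  metrics$config$servers, metrics$utilization)) +
    ggplot2::theme_minimal()
}
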