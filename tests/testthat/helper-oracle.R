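# Independent brute-force oracle for the Cox partial likelihood.
# Deliberately naive (double loop over events and risk sets, no tie
# correction — only used on tie-free data) and maximized by staged grid
# refinement rather than any derivative method, so it shares nothing
# with the Newton implementation it checks.

naive_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(x)) {
    if (!event[i]) next
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_beta <- function(x, time, event, lower = -5, upper = 5) {
  b <- NA_real_
  for (pass in 1:4) {
    grid <- seq(lower, upper, length.out = 1001)
    ll <- vapply(grid, naive_cox_loglik, numeric(1),
                 x = x, time = time, event = event)
    b <- grid[which.max(ll)]
    step <- grid[2] - grid[1]
    lower <- b - step
    upper <- b + step
  }
  b
}

# Small tie-free survival datasets for oracle comparisons.
make_tiefree_dataset <- function(seed, n) {
  set.seed(seed)
  repeat {
    time <- round(runif(n, 1, 100), 3)
    if (!anyDuplicated(time)) break
  }
  x <- if (seed %% 2 == 0) rbinom(n, 1, 0.5) else round(rnorm(n), 2)
  event <- c(TRUE, TRUE, runif(n - 2) < 0.8)  # always >= 2 events
  if (length(unique(x)) < 2) x[1] <- x[1] + 1
  list(x = x, time = time, event = event)
}
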