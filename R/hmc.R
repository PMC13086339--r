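# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation.  Deliberately compact: the posterior it
# targets (standardized covariates, non-centred random effects) is
# well-conditioned, so jittered-path-length HMC with a diagonal metric is
# sufficient and keeps the sampler auditable.
#
# `lp_grad(theta)` must return list(lp = log posterior, grad = gradient).

leapfrog <- function(theta, p, eps, L, lp_grad, inv_mass) {
  g <- lp_grad(theta)
  for (l in seq_len(L)) {
    p <- p + 0.5 * eps * g$grad
    theta <- theta + eps * p * inv_mass
    g <- lp_grad(theta)
    if (!is.finite(g$lp)) return(list(theta = theta, p = p, lp = -Inf))
    p <- p + 0.5 * eps * g$grad
  }
  list(theta = theta, p = p, lp = g$lp)
}

hamiltonian <- function(lp, p, inv_mass) -lp + 0.5 * sum(p^2 * inv_mass)

# Heuristic initial step size: double/halve until the one-step acceptance
# probability crosses 1/2 (standard warm-start heuristic).
find_initial_eps <- function(theta, lp_grad, inv_mass, eps = 0.1) {
  d <- length(theta)
  p <- stats::rnorm(d) / sqrt(inv_mass)
  h0 <- hamiltonian(lp_grad(theta)$lp, p, inv_mass)
  step <- leapfrog(theta, p, eps, 1L, lp_grad, inv_mass)
  h1 <- hamiltonian(step$lp, step$p, inv_mass)
  a <- if (is.finite(h1)) exp(h0 - h1) else 0
  dir <- if (a > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    step <- leapfrog(theta, p, eps, 1L, lp_grad, inv_mass)
    h1 <- hamiltonian(step$lp, step$p, inv_mass)
    a <- if (is.finite(h1)) exp(h0 - h1) else 0
    if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break
  }
  max(eps, 1e-6)
}

hmc_chain <- function(lp_grad, init, iter, warmup, seed,
                      target_accept = 0.8, int_time = 1.6,
                      max_leapfrog = 64L) {
  set.seed(seed)
  d <- length(init)
  theta <- init
  inv_mass <- rep(1, d)

  # dual-averaging state
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  eps <- find_initial_eps(theta, lp_grad, inv_mass)
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0; da_iter <- 0

  # mass-matrix estimation window; the step size re-adapts on the new
  # metric over the remaining 30% of warmup
  win_start <- floor(warmup * 0.35) + 1L
  win_end <- floor(warmup * 0.7)
  win <- matrix(NA_real_, max(win_end - win_start + 1L, 1L), d)

  draws <- matrix(NA_real_, iter, d)
  n_div <- 0L; n_acc <- 0
  total <- warmup + iter

  for (m in seq_len(total)) {
    p <- stats::rnorm(d) / sqrt(inv_mass)
    lp0 <- lp_grad(theta)$lp
    h0 <- hamiltonian(lp0, p, inv_mass)
    # jitter the path length over the upper half of the target range to
    # break resonances without wasting most trajectories on short paths
    l_max <- max(1L, min(max_leapfrog, as.integer(round(int_time / eps))))
    l_min <- max(1L, l_max %/% 2L)
    L <- l_min + sample.int(l_max - l_min + 1L, 1L) - 1L
    prop <- leapfrog(theta, p, eps, L, lp_grad, inv_mass)
    h1 <- hamiltonian(prop$lp, prop$p, inv_mass)
    dh <- h0 - h1
    divergent <- !is.finite(dh) || dh < -1000
    alpha <- if (divergent) 0 else min(1, exp(dh))
    if (stats::runif(1) < alpha) theta <- prop$theta

    if (m <= warmup) {
      # dual averaging towards the target acceptance rate
      da_iter <- da_iter + 1
      frac <- 1 / (da_iter + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - alpha)
      log_eps <- mu - sqrt(da_iter) / gamma * h_bar
      w <- da_iter^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (m >= win_start && m <= win_end) {
        win[m - win_start + 1L, ] <- theta
      }
      if (m == win_end && nrow(win) > 10L) {
        v <- apply(win, 2L, stats::var)
        n_w <- nrow(win)
        inv_mass <- (n_w / (n_w + 5)) * v + (5 / (n_w + 5)) * 1  # shrink to unit
        # restart step-size adaptation around the current value
        eps <- find_initial_eps(theta, lp_grad, inv_mass, eps)
        mu <- log(10 * eps)
        log_eps_bar <- 0; h_bar <- 0; da_iter <- 0
      }
      if (m == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[m - warmup, ] <- theta
      n_acc <- n_acc + alpha
      if (divergent) n_div <- n_div + 1L
    }
  }
  list(draws = draws, accept_rate = n_acc / iter, divergences = n_div,
       eps = eps, inv_mass = inv_mass)
}

#' @keywords internal
hmc_sample <- function(lp_grad, init, chains = 3L, iter = 2000L,
                       warmup = 2000L, seed = 1L, target_accept = 0.8,
                       init_jitter = 0.2) {
  d <- length(init)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_seed <- (as.integer(seed) + 7919L * ch) %% .Machine$integer.max
    set.seed(chain_seed)
    init_ch <- init + stats::rnorm(d, 0, init_jitter)
    res[[ch]] <- hmc_chain(lp_grad, init_ch, iter, warmup,
                           seed = chain_seed, target_accept = target_accept)
  }
  res
}
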