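# In-package No-U-Turn sampler (dynamic Hamiltonian Monte Carlo).
#
# Generic over a log-density-with-gradient callback so the beta regression
# model and the sampler can be tested independently. Implements the
# efficient-NUTS recursion with slice variable, dual-averaging step-size
# adaptation targeting a given acceptance statistic, and windowed diagonal
# mass-matrix adaptation during warmup.

DELTA_MAX <- 1000  # divergence threshold on the joint log density drop

leapfrog <- function(theta, r, grad, eps, inv_mass, lpg) {
  r_half <- r + 0.5 * eps * grad
  theta_new <- theta + eps * inv_mass * r_half
  res <- lpg(theta_new)
  r_new <- r_half + 0.5 * eps * res$grad
  list(theta = theta_new, r = r_new, lp = res$lp, grad = res$grad)
}

joint_lp <- function(lp, r, inv_mass) lp - 0.5 * sum(r * r * inv_mass)

no_uturn <- function(theta_minus, theta_plus, r_minus, r_plus, inv_mass) {
  d <- theta_plus - theta_minus
  sum(d * (inv_mass * r_minus)) >= 0 && sum(d * (inv_mass * r_plus)) >= 0
}

build_tree <- function(theta, r, grad, log_u, v, j, eps, h0, inv_mass, lpg) {
  if (j == 0L) {
    st <- leapfrog(theta, r, grad, v * eps, inv_mass, lpg)
    h <- joint_lp(st$lp, st$r, inv_mass)
    if (!is.finite(h)) h <- -Inf
    n_keep <- as.integer(log_u <= h)
    diverged <- log_u >= h + DELTA_MAX
    list(theta_minus = st$theta, r_minus = st$r, grad_minus = st$grad,
         theta_plus = st$theta, r_plus = st$r, grad_plus = st$grad,
         theta_prop = st$theta, lp_prop = st$lp,
         n = n_keep, s = !diverged, diverged = diverged,
         alpha = min(1, exp(h - h0)), n_alpha = 1L)
  } else {
    left <- build_tree(theta, r, grad, log_u, v, j - 1L, eps, h0,
                       inv_mass, lpg)
    if (!left$s) return(left)
    if (v == -1) {
      right <- build_tree(left$theta_minus, left$r_minus, left$grad_minus,
                          log_u, v, j - 1L, eps, h0, inv_mass, lpg)
      left$theta_minus <- right$theta_minus
      left$r_minus <- right$r_minus
      left$grad_minus <- right$grad_minus
    } else {
      right <- build_tree(left$theta_plus, left$r_plus, left$grad_plus,
                          log_u, v, j - 1L, eps, h0, inv_mass, lpg)
      left$theta_plus <- right$theta_plus
      left$r_plus <- right$r_plus
      left$grad_plus <- right$grad_plus
    }
    total <- left$n + right$n
    if (right$n > 0 && stats::runif(1) < right$n / max(total, 1L)) {
      left$theta_prop <- right$theta_prop
      left$lp_prop <- right$lp_prop
    }
    left$n <- total
    left$alpha <- left$alpha + right$alpha
    left$n_alpha <- left$n_alpha + right$n_alpha
    left$diverged <- left$diverged || right$diverged
    left$s <- right$s &&
      no_uturn(left$theta_minus, left$theta_plus, left$r_minus,
               left$r_plus, inv_mass)
    left
  }
}

find_reasonable_epsilon <- function(theta, lp, grad, inv_mass, lpg) {
  eps <- 1
  d <- length(theta)
  r <- stats::rnorm(d, 0, sqrt(1 / inv_mass))
  h0 <- joint_lp(lp, r, inv_mass)
  st <- leapfrog(theta, r, grad, eps, inv_mass, lpg)
  h1 <- joint_lp(st$lp, st$r, inv_mass)
  if (!is.finite(h1)) h1 <- -Inf
  a <- if (h1 - h0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    if (a * (h1 - h0) <= -a * log(2)) break
    eps <- eps * 2^a
    st <- leapfrog(theta, r, grad, eps, inv_mass, lpg)
    h1 <- joint_lp(st$lp, st$r, inv_mass)
    if (!is.finite(h1)) h1 <- -Inf
  }
  eps
}

# Warmup windows in the style of adaptive HMC implementations: a step-size
# only opening buffer, doubling covariance-estimation windows, and a
# step-size only closing buffer.
adapt_windows <- function(warmup, init_buffer = 75, term_buffer = 50,
                          base_window = 25) {
  if (warmup < init_buffer + term_buffer + base_window) {
    return(integer(0))  # too short for metric adaptation
  }
  ends <- integer(0)
  pos <- init_buffer
  win <- base_window
  repeat {
    nxt <- pos + win
    if (nxt + term_buffer >= warmup ||
        nxt + 2 * win + term_buffer > warmup) {
      ends <- c(ends, warmup - term_buffer)
      break
    }
    ends <- c(ends, nxt)
    pos <- nxt
    win <- win * 2
  }
  unique(ends)
}

nuts_chain <- function(lpg, init, n_iter, warmup, adapt_delta = 0.9,
                       max_treedepth = 10L) {
  d <- length(init)
  theta <- init
  res <- lpg(theta)
  if (!is.finite(res$lp)) stop("initial point has non-finite log density")
  lp <- res$lp
  grad <- res$grad
  inv_mass <- rep(1, d)

  eps <- find_reasonable_epsilon(theta, lp, grad, inv_mass, lpg)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_count <- 0

  windows <- adapt_windows(warmup)
  win_sum <- numeric(d); win_sumsq <- numeric(d); win_n <- 0

  n_keep <- n_iter - warmup
  draws <- matrix(NA_real_, n_keep, d)
  lp_keep <- numeric(n_keep)
  divergences <- 0L
  treedepths <- integer(n_keep)
  accept_sum <- 0

  for (it in seq_len(n_iter)) {
    r0 <- stats::rnorm(d, 0, sqrt(1 / inv_mass))
    h0 <- joint_lp(lp, r0, inv_mass)
    log_u <- h0 - stats::rexp(1)

    theta_minus <- theta; theta_plus <- theta
    r_minus <- r0; r_plus <- r0
    grad_minus <- grad; grad_plus <- grad
    j <- 0L; n <- 1L; s <- TRUE
    alpha <- 0; n_alpha <- 0L
    diverged <- FALSE
    prop_theta <- theta; prop_lp <- lp

    while (s && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tr <- build_tree(theta_minus, r_minus, grad_minus, log_u, v, j,
                         eps, h0, inv_mass, lpg)
        theta_minus <- tr$theta_minus; r_minus <- tr$r_minus
        grad_minus <- tr$grad_minus
      } else {
        tr <- build_tree(theta_plus, r_plus, grad_plus, log_u, v, j,
                         eps, h0, inv_mass, lpg)
        theta_plus <- tr$theta_plus; r_plus <- tr$r_plus
        grad_plus <- tr$grad_plus
      }
      if (tr$s && stats::runif(1) < tr$n / n) {
        prop_theta <- tr$theta_prop
        prop_lp <- tr$lp_prop
      }
      n <- n + tr$n
      alpha <- alpha + tr$alpha
      n_alpha <- n_alpha + tr$n_alpha
      diverged <- diverged || tr$diverged
      s <- tr$s &&
        no_uturn(theta_minus, theta_plus, r_minus, r_plus, inv_mass)
      j <- j + 1L
    }

    if (!identical(prop_theta, theta)) {
      theta <- prop_theta
      lp <- prop_lp
      grad <- lpg(theta)$grad
    }
    a_stat <- if (n_alpha > 0) alpha / n_alpha else 0

    if (it <= warmup) {
      adapt_count <- adapt_count + 1
      h_bar <- (1 - 1 / (adapt_count + t0)) * h_bar +
        (adapt_delta - a_stat) / (adapt_count + t0)
      log_eps <- mu - sqrt(adapt_count) / gamma * h_bar
      w <- adapt_count^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)

      if (length(windows) > 0 && it > 75) {
        win_sum <- win_sum + theta
        win_sumsq <- win_sumsq + theta * theta
        win_n <- win_n + 1
      }
      if (it %in% windows && win_n >= 10) {
        v_est <- (win_sumsq - win_sum^2 / win_n) / (win_n - 1)
        # regularize towards a small constant, as adaptive HMC codes do
        v_reg <- (win_n / (win_n + 5)) * v_est + (5 / (win_n + 5)) * 1e-3
        inv_mass <- pmax(v_reg, 1e-10)
        win_sum <- numeric(d); win_sumsq <- numeric(d); win_n <- 0
        eps <- find_reasonable_epsilon(theta, lp, grad, inv_mass, lpg)
        mu <- log(10 * eps)
        h_bar <- 0; adapt_count <- 0; log_eps_bar <- log(eps)
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      k <- it - warmup
      draws[k, ] <- theta
      lp_keep[k] <- lp
      treedepths[k] <- j
      if (diverged) divergences <- divergences + 1L
      accept_sum <- accept_sum + a_stat
    }
  }

  list(draws = draws, lp = lp_keep, divergences = divergences,
       step_size = eps, inv_mass = inv_mass,
       mean_accept = accept_sum / max(n_keep, 1),
       treedepths = treedepths)
}

#' Sample from a log density with the No-U-Turn sampler
#'
#' Dynamic Hamiltonian Monte Carlo with slice-based trajectory sampling,
#' dual-averaging step-size adaptation and windowed diagonal mass-matrix
#' adaptation. Written for the handful-of-parameters posteriors this
#' package fits; the callback interface keeps it independent of any model.
#'
#' @param lpg Function `theta -> list(lp = , grad = )` returning the log
#'   density (up to a constant) and its gradient at `theta`.
#' @param init Numeric vector or list of vectors (one per chain) of initial
#'   values on the unconstrained scale.
#' @param chains Number of chains.
#' @param iter Total iterations per chain, warmup included.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param adapt_delta Target acceptance statistic for step-size adaptation.
#' @param max_treedepth Cap on trajectory doublings per iteration.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return List with `draws` (pooled post-warmup matrix), `chain_draws`
#'   (list of per-chain matrices), `divergences`, `rhat` and `ess` per
#'   dimension, and per-chain step sizes.
#' @export
nuts_sample <- function(lpg, init, chains = 4L, iter = 6000L,
                        warmup = 2000L, adapt_delta = 0.9,
                        max_treedepth = 10L, seed = 1L) {
  stopifnot(warmup < iter, chains >= 1)
  if (!is.list(init)) init <- rep(list(init), chains)
  stopifnot(length(init) == chains)
  chain_res <- vector("list", chains)
  for (c in seq_len(chains)) {
    set.seed(as.integer(seed) + c - 1L)
    chain_res[[c]] <- nuts_chain(lpg, init[[c]], iter, warmup,
                                 adapt_delta, max_treedepth)
  }
  chain_draws <- lapply(chain_res, `[[`, "draws")
  d <- ncol(chain_draws[[1]])
  rhat <- vapply(seq_len(d), function(k) {
    split_rhat(lapply(chain_draws, function(m) m[, k]))
  }, 0)
  ess <- vapply(seq_len(d), function(k) {
    ess_basic(lapply(chain_draws, function(m) m[, k]))
  }, 0)
  list(
    draws = do.call(rbind, chain_draws),
    chain_draws = chain_draws,
    divergences = sum(vapply(chain_res, `[[`, 0L, "divergences")),
    rhat = rhat,
    ess = ess,
    step_size = vapply(chain_res, `[[`, 0, "step_size"),
    mean_accept = vapply(chain_res, `[[`, 0, "mean_accept")
  )
}

#' Split-chain potential scale reduction factor
#'
#' @param chains List of numeric vectors, one per chain (equal lengths).
#' @return The split-R-hat statistic.
#' @export
split_rhat <- function(chains) {
  half <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }), recursive = FALSE)
  m <- length(half)
  n <- length(half[[1]])
  means <- vapply(half, mean, 0)
  vars <- vapply(half, stats::var, 0)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Effective sample size from multi-chain autocorrelation (variogram
# estimator with Geyer initial-positive-sequence truncation).
ess_basic <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  w <- mean(vars)
  var_plus <- w * (n - 1) / n + if (m > 1) stats::var(means) else 0
  if (var_plus == 0) return(m * n)
  rho_sum <- 0
  max_lag <- min(n - 1, 1000)
  t <- 1
  prev_pair <- Inf
  while (t < max_lag) {
    rho_t <- 1 - mean(vapply(chains, function(x) {
      mean((x[seq_len(n - t)] - x[seq_len(n - t) + t])^2)
    }, 0)) / (2 * var_plus)
    rho_t1 <- if (t + 1 <= max_lag) {
      1 - mean(vapply(chains, function(x) {
        mean((x[seq_len(n - t - 1)] - x[seq_len(n - t - 1) + t + 1])^2)
      }, 0)) / (2 * var_plus)
    } else 0
    pair <- rho_t + rho_t1
    if (pair < 0) break
    pair <- min(pair, prev_pair)  # enforce monotone decrease
    prev_pair <- pair
    rho_sum <- rho_sum + pair
    t <- t + 2
  }
  m * n / (1 + 2 * rho_sum)
}
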