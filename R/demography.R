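# Stairway-style demographic inference: expected SFS under a
# piecewise-constant Ne history via exact epoch-wise integration of the
# lineage-count pure-death chain, and composite-likelihood fitting of
# per-epoch Ne to an observed folded spectrum.

#' Piecewise-constant demographic model
#'
#' @param epoch_boundaries Strictly ascending times (years before present)
#'   separating epochs; `length(Ne_per_epoch) - 1` values. Epoch 1 is the
#'   most recent.
#' @param Ne_per_epoch Diploid effective size per epoch (finite, > 0).
#' @param mu Mutation rate per site per generation (study value 1.1e-8).
#' @param generation_time Years per generation (study value 1).
#' @return Object of class `demographic_model` with derived
#'   `theta_per_site = 4 Ne[1] mu`.
#' @export
demographic_model <- function(epoch_boundaries, Ne_per_epoch, mu = 1.1e-8,
                              generation_time = 1) {
  stopifnot(length(epoch_boundaries) == length(Ne_per_epoch) - 1)
  if (length(epoch_boundaries) &&
      (any(diff(epoch_boundaries) <= 0) || any(epoch_boundaries <= 0))) {
    stop("epoch boundaries must be positive and strictly ascending")
  }
  if (any(!is.finite(Ne_per_epoch)) || any(Ne_per_epoch <= 0)) {
    stop("Ne must be finite and positive in every epoch")
  }
  structure(list(epoch_boundaries = epoch_boundaries,
                 Ne_per_epoch = Ne_per_epoch, mu = mu,
                 generation_time = generation_time,
                 theta_per_site = 4 * Ne_per_epoch[1] * mu),
            class = "demographic_model")
}

#' Probability that a branch with k coalescent-time lineages subtends i
#' of n samples
#'
#' The standard polanski-style combinatorial weight
#' `P(i|k) = C(n-i-1, k-2) / C(n-1, k-1)`; rows sum to 1 over i for each k.
#'
#' @param n Sample size (alleles).
#' @param k Lineage count, 2..n.
#' @return Numeric vector over i = 1..n-1.
#' @export
p_subtend <- function(n, k) {
  i <- seq_len(n - 1)
  choose(n - i - 1, k - 2) / choose(n - 1, k - 1)
}

# Expected time spent with k = n..2 lineages (generations) under a
# piecewise-constant history. Epochs in generations: boundaries_gen
# ascending, sizes diploid. Exact via the matrix exponential of the
# lineage-count chain restricted to states n..2.
expected_coalescent_times <- function(n, boundaries_gen, sizes) {
  states <- n:2
  ns <- length(states)
  lam0 <- states * (states - 1) / 2 # coalescent rates at 2N = 1
  A0 <- matrix(0, ns, ns)
  diag(A0) <- -lam0
  if (ns > 1) A0[cbind(seq_len(ns - 1), seq(2, ns))] <- lam0[seq_len(ns - 1)]
  v <- c(1, rep(0, ns - 1)) # all n lineages present at t = 0
  occ <- numeric(ns)
  bounds <- c(0, boundaries_gen, Inf)
  for (e in seq_along(sizes)) {
    rate_scale <- 1 / (2 * sizes[e])
    tau <- bounds[e + 1] - bounds[e]
    A <- A0 * rate_scale
    if (is.finite(tau)) {
      E <- as.matrix(Matrix::expm(A * tau))
      occ <- occ + as.numeric(v %*% solve(A, E - diag(ns)))
      v <- as.numeric(v %*% E)
    } else {
      occ <- occ + as.numeric(v %*% solve(-A, diag(ns)))
      v <- rep(0, ns)
    }
  }
  setNames(occ, states) # E[T_k], k = n..2
}

#' Expected SFS under a piecewise-constant demography
#'
#' `E[xi_i] = sum_k k E[T_k] P(i|k) mu total_sites`, with `E[T_k]` computed
#' exactly by epoch-wise integration of the lineage-count Markov chain and
#' the combinatorial weights [p_subtend()]. Under constant Ne this reduces
#' to the standard-coalescent `theta / i`.
#'
#' @param model A [demographic_model()].
#' @param n_alleles Sample size in alleles (>= 4).
#' @param total_sites Sites over which mutations accrue.
#' @return List: `unfolded` (i = 1..n-1), `folded` (minor counts
#'   1..floor(n/2)), `expected_segregating`.
#' @export
expected_sfs <- function(model, n_alleles, total_sites) {
  stopifnot(inherits(model, "demographic_model"), n_alleles >= 4)
  n <- n_alleles
  bounds_gen <- model$epoch_boundaries / model$generation_time
  Tk <- expected_coalescent_times(n, bounds_gen, model$Ne_per_epoch)
  xi <- numeric(n - 1)
  for (k in n:2) {
    xi <- xi + k * Tk[as.character(k)] * p_subtend(n, k)
  }
  xi <- xi * model$mu * total_sites
  folded <- fold_spectrum(xi)
  list(unfolded = setNames(xi, seq_len(n - 1)), folded = folded,
       expected_segregating = sum(xi))
}

fold_spectrum <- function(xi) {
  n <- length(xi) + 1
  m <- n %/% 2
  out <- vapply(seq_len(m), function(i) {
    if (i == n - i) xi[i] else xi[i] + xi[n - i]
  }, numeric(1))
  setNames(out, seq_len(m))
}

# Stairway breakpoints: quantiles of the cumulative expected coalescent
# times under a constant-Ne pilot, tau_k = 4N(1/k - 1/n) spread over the
# expected tree depth.
stairway_breakpoints <- function(n, Ne_pilot, n_epochs, generation_time) {
  depth <- 4 * Ne_pilot * (1 - 1 / n)
  q <- seq_len(n_epochs - 1) / n_epochs
  # geometric spread over the expected tree depth: recent epochs get the
  # resolution, matching where the SFS carries information
  tau <- depth * (20^q - 1) / 19
  tau * generation_time
}

#' Fit a stairway-style piecewise-constant Ne trajectory
#'
#' Maximises the multinomial composite log-likelihood of the observed
#' folded SFS bins against [expected_sfs()] over per-epoch Ne on the log
#' scale, with epoch breakpoints fixed at coalescent-quantile times from a
#' constant-Ne (Watterson) pilot fit. Because the conditional-on-S
#' multinomial only constrains the spectrum shape, the overall Ne scale is
#' then set by matching the expected number of segregating sites to the
#' observed count. Bootstrap resamples sites (multinomially over bins, or
#' over loci if a per-locus bin matrix is supplied) and refits; the
#' envelope reports the 12.5/87.5 percentiles.
#'
#' @param observed An `sfs` object ([folded_sfs()] /
#'   [folded_sfs_from_haplotypes()]); fewer than 50 segregating sites
#'   triggers a warning.
#' @param n_epochs Number of epochs (default 4).
#' @param mu,generation_time Mutation rate and generation time.
#' @param n_boot Bootstrap replicates (0 for none).
#' @param seed Integer seed.
#' @param locus_bins Optional loci x bins matrix for locus bootstrap.
#' @return List of class `stairway_fit`: `model` (fitted
#'   [demographic_model()]), `trajectory` (data.frame time_years, Ne, lo,
#'   hi), `converged`, `loglik`, `pilot_Ne`.
#' @export
fit_stairway <- function(observed, n_epochs = 4, mu = 1.1e-8,
                         generation_time = 1, n_boot = 0, seed = 1,
                         locus_bins = NULL) {
  stopifnot(inherits(observed, "sfs"))
  bins <- observed$bins
  S <- sum(bins)
  if (S < 50) warning("only ", S, " segregating sites; the fit will be noisy")
  n <- observed$n_alleles
  total_sites <- observed$total_sites
  a_n <- sum(1 / seq_len(n - 1))
  theta_w <- S / (a_n * total_sites)
  Ne_pilot <- max(1, theta_w / (4 * mu))
  bounds <- stairway_breakpoints(n, Ne_pilot, n_epochs, generation_time)
  m <- length(fold_spectrum(rep(1, n - 1)))
  obs <- as.numeric(bins[seq_len(m)])
  nll <- function(log_ne) {
    mod <- demographic_model(bounds, exp(log_ne), mu, generation_time)
    ef <- expected_sfs(mod, n, total_sites)$folded
    pr <- ef / sum(ef)
    if (any(!is.finite(pr)) || any(pr <= 0)) return(1e10)
    -sum(obs * log(pr))
  }
  fit_once <- function(obs_bins) {
    obs <<- as.numeric(obs_bins[seq_len(m)])
    opt <- optim(rep(log(Ne_pilot), n_epochs), nll, method = "L-BFGS-B",
                 lower = log(1), upper = log(1e9),
                 control = list(maxit = 300))
    ne <- exp(opt$par)
    # scale so expected S matches observed S (shape fixed by the multinomial)
    S_here <- sum(obs_bins)
    f <- function(lsig) {
      mod <- demographic_model(bounds, ne * exp(lsig), mu, generation_time)
      expected_sfs(mod, n, total_sites)$expected_segregating - S_here
    }
    sig <- tryCatch(exp(stats::uniroot(f, c(-10, 10))$root), error = function(e) 1)
    list(ne = ne * sig, conv = opt$convergence == 0, value = -opt$value)
  }
  main <- fit_once(bins)
  if (!main$conv) warning("optimizer did not report convergence")
  boots <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      replicate(n_boot, {
        if (!is.null(locus_bins)) {
          idx <- sample.int(nrow(locus_bins), nrow(locus_bins), replace = TRUE)
          rb <- colSums(locus_bins[idx, , drop = FALSE])
        } else {
          rb <- as.numeric(stats::rmultinom(1, S, bins / S))
        }
        names(rb) <- names(bins)[seq_along(rb)]
        fit_once(rb)$ne
      })
    })
  }
  model <- demographic_model(bounds, main$ne, mu, generation_time)
  tgrid <- c(0, bounds)
  traj <- data.frame(time_years = tgrid, Ne = main$ne)
  if (!is.null(boots)) {
    # envelope always brackets the point estimate
    traj$lo <- pmin(apply(boots, 1, quantile, probs = 0.125), main$ne)
    traj$hi <- pmax(apply(boots, 1, quantile, probs = 0.875), main$ne)
  } else {
    traj$lo <- NA_real_; traj$hi <- NA_real_
  }
  structure(list(model = model, trajectory = traj, converged = main$conv,
                 loglik = main$value, pilot_Ne = Ne_pilot,
                 bootstraps = boots), class = "stairway_fit")
}

#' Evaluate a fitted trajectory at given times
#' @param fit A `stairway_fit` (or `demographic_model`).
#' @param times_years Times before present, in years.
#' @return Ne at each time (step function; epoch 1 covers `[0, b1)`).
#' @export
ne_at <- function(fit, times_years) {
  model <- if (inherits(fit, "stairway_fit")) fit$model else fit
  idx <- findInterval(times_years, model$epoch_boundaries) + 1
  model$Ne_per_epoch[idx]
}

#' Plot a stairway trajectory
#' @param x A `stairway_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.stairway_fit <- function(x, ...) {
  tr <- x$trajectory
  t_plot <- pmax(tr$time_years, min(tr$time_years[tr$time_years > 0], 1))
  graphics::plot(t_plot, tr$Ne, type = "s", log = "xy",
                 xlab = "years before present", ylab = "Ne", ...)
  if (!all(is.na(tr$lo))) {
    graphics::lines(t_plot, tr$lo, type = "s", lty = 2)
    graphics::lines(t_plot, tr$hi, type = "s", lty = 2)
  }
  invisible(x)
}
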