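#' Default hyperparameter search space for the edge-score classifier
#'
#' Each entry names a gradient-boosting hyperparameter and its prior:
#' `uniform`, `loguniform` (sampled uniformly on the log scale) or
#' `quniform` (uniform, rounded to multiples of `q`). Bounds follow common
#' practice for moderately sized tabular problems.
#'
#' @return named list of parameter descriptors.
#' @export
tpe_space <- function() {
  list(
    eta = list(type = "loguniform", low = 0.01, high = 0.3),
    max_depth = list(type = "quniform", low = 2, high = 8, q = 1),
    nrounds = list(type = "quniform", low = 50, high = 300, q = 10),
    subsample = list(type = "uniform", low = 0.6, high = 1),
    colsample_bytree = list(type = "uniform", low = 0.5, high = 1),
    min_child_weight = list(type = "loguniform", low = 1, high = 16),
    alpha = list(type = "loguniform", low = 1e-3, high = 1),
    lambda = list(type = "loguniform", low = 1e-2, high = 10)
  )
}

#' Default hyperparameter setting (seeded as trial 0 of every search)
#' @return named list of hyperparameter values inside [tpe_space()].
#' @export
tpe_default_setting <- function() {
  list(eta = 0.1, max_depth = 4, nrounds = 100, subsample = 0.9,
       colsample_bytree = 0.8, min_child_weight = 1, alpha = 1e-3,
       lambda = 1)
}

tpe_transform <- function(v, par) {
  if (par$type == "loguniform") log(v) else v
}
tpe_untransform <- function(t, par) {
  v <- if (par$type == "loguniform") exp(t) else t
  v <- min(max(v, par$low), par$high)
  if (par$type == "quniform") v <- round(v / par$q) * par$q
  v
}
tpe_sample_prior <- function(par) {
  lo <- tpe_transform(par$low, par)
  hi <- tpe_transform(par$high, par)
  tpe_untransform(runif(1, lo, hi), par)
}

#' Tree of Parzen Estimators hyperparameter search
#'
#' Sequential model-based optimization: after `n_startup` prior-sampled
#' trials (the stated default setting is always trial 0), observed trials
#' are split into a good fraction `gamma` and the rest by objective value;
#' per parameter, Gaussian Parzen densities `l(x)` (good) and `g(x)` (bad)
#' are fit on the transformed scale, candidates are drawn from `l` and the
#' candidate maximizing `sum(log l - log g)` is evaluated next. The
#' objective is maximized. Fully deterministic under `seed`.
#'
#' @param objective function taking a named list of hyperparameters and
#'   returning a scalar to maximize.
#' @param space search space as from [tpe_space()].
#' @param n_trials total number of trials (>= 1).
#' @param seed integer seed.
#' @param n_startup random trials before the Parzen model kicks in.
#' @param gamma fraction of trials treated as "good".
#' @param n_candidates candidates scored per TPE step.
#' @param default setting evaluated as trial 0; `NULL` to start random.
#' @return list with `best` (named list), `best_value`, and `trials` (a
#'   `data.table` log with one row per trial).
#' @export
tpe_optimize <- function(objective, space = tpe_space(), n_trials = 25L,
                         seed = 1L, n_startup = 8L, gamma = 0.25,
                         n_candidates = 24L, default = tpe_default_setting()) {
  if (n_trials < 1L) config_error("n_trials must be >= 1")
  pnames <- names(space)
  trials <- vector("list", n_trials)
  values <- numeric(n_trials)
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      setting <- if (i == 1L && !is.null(default)) {
        default[pnames]
      } else if (i <= n_startup || i <= 2L) {
        setNames(lapply(space, tpe_sample_prior), pnames)
      } else {
        obs <- do.call(rbind, lapply(trials[seq_len(i - 1L)], function(s) {
          unlist(s[pnames])
        }))
        vals <- values[seq_len(i - 1L)]
        n_good <- max(1L, ceiling(gamma * nrow(obs)))
        good_idx <- order(-vals)[seq_len(n_good)]
        cand <- matrix(NA_real_, n_candidates, length(pnames),
                       dimnames = list(NULL, pnames))
        score <- numeric(n_candidates)
        for (p in pnames) {
          par <- space[[p]]
          tt <- vapply(obs[, p], tpe_transform, 0, par = par)
          gt <- tt[good_idx]
          bt <- tt[-good_idx]
          span <- abs(tpe_transform(par$high, par) -
                      tpe_transform(par$low, par))
          # bandwidth follows the spread of all observations (not just the
          # good ones) so the proposal kernel cannot collapse prematurely
          bw_g <- max(sd(tt), span / 10, 1e-6)
          bw_b <- max(if (length(bt) > 1L) sd(bt) else 0, span / 10, 1e-6)
          centers <- sample(gt, n_candidates, replace = TRUE)
          draws <- centers + rnorm(n_candidates, sd = bw_g)
          l_d <- vapply(draws, function(d) mean(dnorm(d, gt, bw_g)), 0)
          g_d <- if (length(bt)) {
            vapply(draws, function(d) mean(dnorm(d, bt, bw_b)), 0)
          } else rep(1e-12, n_candidates)
          score <- score + log(l_d + 1e-12) - log(g_d + 1e-12)
          cand[, p] <- vapply(draws, tpe_untransform, 0, par = par)
        }
        as.list(cand[which.max(score), ])
      }
      trials[[i]] <- setting
      values[i] <- objective(setting)
    }
  })
  log_dt <- cbind(
    data.table(trial = seq_len(n_trials) - 1L, value = values),
    rbindlist(lapply(trials, as.data.table))
  )
  best_i <- which.max(values)
  list(best = trials[[best_i]], best_value = values[best_i], trials = log_dt)
}
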