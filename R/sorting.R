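# Per-electrode spike sorting: PCA features + mixture-of-t EM clustering.

#' Spike-sorting parameters
#'
#' @param n_features Number of principal-component features (default 3).
#' @param dof Degrees of freedom of the t components, held fixed (default 10).
#' @param k_init Initial number of mixture components (default 20); excess
#'   components die out by weight pruning.
#' @param max_iter Maximum EM iterations per run (default 500); each
#'   consolidation restarts a run.
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param min_weight Components below this mixing weight are pruned between
#'   iterations (default `0.5 / k_init`).
#' @param min_unit_spikes Clusters with fewer assigned spikes are dissolved
#'   into the outlier pool (default 10).
#' @param merge_threshold Mahalanobis distance between component means
#'   (on the average scatter) below which two components are consolidated
#'   into one between EM runs (default 4; `Inf` disables consolidation).
#' @param seed Integer seed for the k-means initialization.
#' @return Object of class `sorting_params`.
#' @export
sorting_params <- function(n_features = 3, dof = 10, k_init = 20,
                           max_iter = 500, tol = 1e-6,
                           min_weight = 0.5 / k_init, min_unit_spikes = 10,
                           merge_threshold = 4, seed = 1) {
  check_number(dof, "dof", 2, strict_lower = TRUE)
  check_number(k_init, "k_init", 1)
  check_number(tol, "tol", 0, strict_lower = TRUE)
  structure(list(n_features = as.integer(n_features), dof = dof,
                 k_init = as.integer(k_init), max_iter = as.integer(max_iter),
                 tol = tol, min_weight = min_weight,
                 min_unit_spikes = as.integer(min_unit_spikes),
                 merge_threshold = merge_threshold, seed = seed),
            class = "sorting_params")
}

#' Concatenate spike tables across phases
#'
#' Pools the events of several phases (baseline plus treatments) into one
#' waveform set so that cluster identity persists across phases.  Events are
#' ordered by the given phase order, then time; phase tags are preserved.
#'
#' @param tables A list of `spike_table`s (or a single combined table).
#' @param phase_order Optional character vector fixing the phase order
#'   (default: order of appearance).
#' @return A pooled `spike_table`.
#' @export
concatenate_phases <- function(tables, phase_order = NULL) {
  if (inherits(tables, "spike_table")) tables <- list(tables)
  wlen <- unique(unlist(lapply(tables, function(t) {
    w <- attr(t, "waveforms")
    if (is.null(w) || nrow(w) == 0) NULL else ncol(w)
  })))
  if (length(wlen) > 1)
    stop_schema("mismatched cutout lengths across phases: ",
                paste(wlen, collapse = ", "))
  pooled <- bind_spike_tables(tables)
  phase_order <- phase_order %||% unique(pooled$phase)
  o <- order(match(pooled$phase, phase_order), pooled$time_s)
  wf <- attr(pooled, "waveforms")
  spike_table(as.data.frame(pooled)[o, , drop = FALSE],
              if (!is.null(wf)) wf[o, , drop = FALSE])
}

#' Project waveforms onto principal-component features
#'
#' Maps each waveform cutout to `n_features` coordinates on the leading
#' principal axes of the electrode's waveform set.  The sign of each axis is
#' fixed so its largest-magnitude loading is positive, making the projection
#' deterministic.
#'
#' @param waveforms Matrix of cutouts, one row per event.
#' @param n_features Number of components (default 3).
#' @return Matrix of feature coordinates (rows match `waveforms`).
#' @export
extract_features <- function(waveforms, n_features = 3) {
  if (is.null(dim(waveforms)) || nrow(waveforms) < n_features + 1)
    stop_config("need at least n_features + 1 = ", n_features + 1,
                " waveforms; got ", NROW(waveforms))
  p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  k <- min(n_features, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) -1 else 1
  }, numeric(1))
  sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
}

# log density of a multivariate t; x centered rows, R = chol(scatter)
log_dmvt <- function(xc, R, dof) {
  d <- ncol(xc)
  z <- forwardsolve(t(R), t(xc))
  delta <- colSums(z^2)
  lgamma((dof + d) / 2) - lgamma(dof / 2) - d / 2 * log(dof * pi) -
    sum(log(diag(R))) - (dof + d) / 2 * log1p(delta / dof)
}

#' Fit a mixture of multivariate t-distributions by EM
#'
#' Clusters feature vectors with a mixture of multivariate t-distributions
#' with fixed degrees of freedom.  The E-step computes responsibilities and
#' latent precision scale factors `u = (dof + d) / (dof + Mahalanobis^2)`;
#' the M-step updates mixing weights, u-weighted means, and u-weighted full
#' scatter matrices.  The observed-data log likelihood is non-decreasing
#' along EM iterations; model complexity is reduced by two mechanisms
#' between EM runs: components whose mixing weight falls below `min_weight`
#' are pruned, and pairs of components whose means lie within
#' `merge_threshold` Mahalanobis units of each other (on the average
#' scatter) are consolidated into one, after which EM is re-run to
#' convergence.  Consolidation is what lets an over-specified start
#' (`k_init` components on a single cluster) collapse to the true number of
#' units: redundant fragments and nested outlier-catchers of one cluster
#' lie a couple of units apart while genuinely distinct units at the
#' separations this pipeline sorts lie far beyond the threshold.
#' Initialization is seeded k-means.
#'
#' @param x Numeric feature matrix (rows = events).
#' @param params A [sorting_params()]; `k_init`, `dof`, `max_iter`, `tol`,
#'   `min_weight`, `merge_threshold`, `seed` are used.
#' @return Object of class `t_mixture` with elements `weights`, `mu` (k x d),
#'   `sigma` (list of scatter matrices), `dof`, `responsibilities`, `cluster`
#'   (max-responsibility labels), `loglik` (trace over all EM iterations),
#'   `restarted_at` (iterations after which the component set changed by
#'   pruning or consolidation, restarting the monotone segments), `converged`,
#'   `iterations`.
#' @export
fit_t_mixture <- function(x, params = sorting_params()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_config("feature matrix must be finite")
  n <- nrow(x)
  d <- ncol(x)
  dof <- params$dof
  k <- min(params$k_init, max(1L, nrow(unique(x)) - 1L))
  ridge <- 1e-6 * mean(apply(x, 2, stats::var))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-10
  km <- with_local_seed(params$seed,
                        suppressWarnings(stats::kmeans(x, centers = k,
                                                       nstart = 5,
                                                       iter.max = 100)))
  mu <- km$centers
  sigma <- lapply(seq_len(k), function(j) {
    xj <- x[km$cluster == j, , drop = FALSE]
    s <- if (nrow(xj) > d) stats::cov(xj) else diag(d) * ridge / 1e-6
    s + diag(d) * ridge
  })
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  loglik <- numeric(0)
  restarted_at <- integer(0)
  iter <- 0L
  converged <- FALSE

  # regularize only when a scatter matrix is numerically singular; the
  # affected iteration is recorded as a restart since the exact-EM ascent
  # guarantee does not cover it
  regularized <- FALSE
  safe_chol <- function(s) tryCatch(chol(s), error = function(e) {
    regularized <<- TRUE
    chol(s + diag(d) * max(ridge, 1e-12))
  })
  logdens <- function() {
    ld <- matrix(0, n, length(w))
    for (j in seq_along(w))
      ld[, j] <- log_dmvt(sweep(x, 2, mu[j, ]), safe_chol(sigma[[j]]), dof)
    ld
  }
  # one EM run to convergence (or iteration budget); prunes light components
  em_run <- function() {
    run_iter <- 0L
    while (run_iter < params$max_iter) {
      run_iter <- run_iter + 1L
      iter <<- iter + 1L
      ld <- sweep(logdens(), 2, log(w), "+")
      m <- apply(ld, 1, max)
      ll_i <- m + log(rowSums(exp(ld - m)))
      ll <- sum(ll_i)
      if (!is.finite(ll))
        stop("non-finite mixture log-likelihood at iteration ", iter,
             "; inspect features for degenerate scales")
      r <- exp(ld - ll_i)
      u <- matrix(0, n, length(w))
      for (j in seq_along(w)) {
        z <- forwardsolve(t(safe_chol(sigma[[j]])),
                          t(sweep(x, 2, mu[j, ])))
        u[, j] <- (dof + d) / (dof + colSums(z^2))
      }
      rs <- colSums(r)
      for (j in seq_along(w)) {
        ru <- r[, j] * u[, j]
        mu[j, ] <<- colSums(x * ru) / sum(ru)
        xc <- sweep(x, 2, mu[j, ])
        sigma[[j]] <<- crossprod(xc * sqrt(ru)) / rs[j]
      }
      w <<- rs / n
      loglik <<- c(loglik, ll)
      if (regularized) {
        restarted_at <<- unique(c(restarted_at, iter - 1L, iter))
        regularized <<- FALSE
      }
      if (length(w) > 1 && any(w < params$min_weight)) {
        keep <- w >= params$min_weight
        if (!any(keep)) keep[which.max(w)] <- TRUE
        if (!all(keep)) {
          w <<- w[keep] / sum(w[keep])
          mu <<- mu[keep, , drop = FALSE]
          sigma <<- sigma[keep]
          restarted_at <<- c(restarted_at, iter)
          next
        }
      }
      nl <- length(loglik)
      if (nl > 1 && !((nl - 1) %in% restarted_at) &&
          abs(loglik[nl] - loglik[nl - 1]) <
          params$tol * (abs(loglik[nl - 1]) + params$tol)) {
        return(TRUE)
      }
    }
    FALSE
  }
  # Mahalanobis distance between component means on the average scatter;
  # fragments of one cluster (and nested outlier-catchers) sit near 0 while
  # distinct units at the separations this pipeline sorts sit far above any
  # sensible threshold
  comp_dist <- function(j, l) {
    sm <- (sigma[[j]] + sigma[[l]]) / 2
    dm <- mu[j, ] - mu[l, ]
    sqrt(as.numeric(crossprod(dm, solve(sm, dm))))
  }
  runs <- 0L
  repeat {
    converged <- em_run()
    runs <- runs + 1L
    if (length(w) < 2 || runs > params$k_init) break
    dists <- expand.grid(j = seq_along(w), l = seq_along(w))
    dists <- dists[dists$j < dists$l, ]
    db <- mapply(comp_dist, dists$j, dists$l)
    if (!length(db) || min(db) >= params$merge_threshold) break
    pick <- dists[which.min(db), ]
    j <- pick$j; l <- pick$l
    wt <- w[j] + w[l]
    mu_new <- (w[j] * mu[j, ] + w[l] * mu[l, ]) / wt
    # moment-matched scatter of the pooled pair
    sig_new <- (w[j] * (sigma[[j]] + tcrossprod(mu[j, ] - mu_new)) +
                  w[l] * (sigma[[l]] + tcrossprod(mu[l, ] - mu_new))) / wt
    keep <- setdiff(seq_along(w), c(j, l))
    w <- c(w[keep], wt)
    mu <- rbind(mu[keep, , drop = FALSE], mu_new)
    sigma <- c(sigma[keep], list(sig_new))
    restarted_at <- c(restarted_at, iter)
  }
  ld <- sweep(logdens(), 2, log(w), "+")
  m <- apply(ld, 1, max)
  r <- exp(ld - (m + log(rowSums(exp(ld - m)))))
  structure(list(weights = w, mu = mu, sigma = sigma, dof = dof,
                 responsibilities = r, cluster = max.col(r),
                 loglik = loglik, restarted_at = restarted_at,
                 converged = converged, iterations = iter),
            class = "t_mixture")
}

#' @export
print.t_mixture <- function(x, ...) {
  cat(sprintf("t-mixture: %d component(s), dof %g, %d iteration(s)%s\n",
              length(x$weights), x$dof, x$iterations,
              if (x$converged) " (converged)" else ""))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.t_mixture <- function(object, ...) {
  ll <- object$loglik[length(object$loglik)]
  attr(ll, "df") <- length(object$weights) *
    (1 + ncol(object$mu) + ncol(object$mu) * (ncol(object$mu) + 1) / 2) - 1
  class(ll) <- "logLik"
  ll
}

#' Assign pooled spikes to units from a fitted mixture
#'
#' Each spike goes to its maximum-responsibility component; components with
#' fewer than `min_unit_spikes` spikes are dissolved into the outlier pool
#' (`unit_id` `NA`).  Surviving units are renumbered by descending spike
#' count.
#'
#' @param fit A [fit_t_mixture()] result.
#' @param spikes The pooled `spike_table` the features came from (row order
#'   must match).
#' @param min_unit_spikes Dissolution threshold (default 10).
#' @return The spike table with a `unit_id` column added (`NA` = outlier
#'   pool).
#' @export
assign_units <- function(fit, spikes, min_unit_spikes = 10) {
  stopifnot(length(fit$cluster) == nrow(spikes))
  cl <- fit$cluster
  counts <- table(cl)
  good <- as.integer(names(counts))[counts >= min_unit_spikes]
  good <- good[order(-counts[as.character(good)])]
  map <- rep(NA_integer_, length(fit$weights))
  map[good] <- seq_along(good)
  spikes$unit_id <- map[cl]
  spikes
}

#' Sort detected spikes into units, per electrode
#'
#' For every electrode: extracts principal-component features from the pooled
#' waveforms, fits the t-mixture by EM, assigns spikes to
#' maximum-responsibility components, and dissolves sub-threshold clusters
#' into the outlier pool.  Electrodes with fewer waveforms than
#' `n_features + 1` are left as a single unsorted unit with a warning.
#'
#' @param spikes A pooled `spike_table` with waveforms (see
#'   [concatenate_phases()]).
#' @param params A [sorting_params()].
#' @return Object of class `sorted_units`: list with `spikes` (the input
#'   table plus `unit_id`, `NA` for the outlier pool), `units` (one row per
#'   unit: `well`, `electrode`, `unit_id`, `n_spikes`), and `diagnostics`
#'   (per electrode: final component count, weights, log-likelihood trace).
#' @export
sort_spikes <- function(spikes, params = sorting_params()) {
  wf <- attr(spikes, "waveforms")
  if (is.null(wf)) stop_schema("spike table has no waveform sidecar")
  df <- as.data.frame(spikes)
  df$unit_id <- NA_integer_
  key <- paste(df$well, df$electrode)
  diagnostics <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < params$n_features + 1) {
      warning("electrode ", k, ": only ", length(idx),
              " spikes; kept as one unsorted unit", call. = FALSE)
      df$unit_id[idx] <- 1L
      diagnostics[[k]] <- list(sorted = FALSE, k_final = 1L,
                               n_spikes = length(idx))
      next
    }
    feats <- extract_features(wf[idx, , drop = FALSE], params$n_features)
    fit <- fit_t_mixture(feats, params)
    sub <- assign_units(fit, df[idx, , drop = FALSE],
                        params$min_unit_spikes)
    df$unit_id[idx] <- sub$unit_id
    diagnostics[[k]] <- list(sorted = TRUE, k_final = length(fit$weights),
                             weights = fit$weights, loglik = fit$loglik,
                             restarted_at = fit$restarted_at,
                             converged = fit$converged,
                             n_spikes = length(idx),
                             n_outliers = sum(is.na(sub$unit_id)))
  }
  units <- stats::aggregate(
    list(n_spikes = rep(1L, sum(!is.na(df$unit_id)))),
    by = list(well = df$well[!is.na(df$unit_id)],
              electrode = df$electrode[!is.na(df$unit_id)],
              unit_id = df$unit_id[!is.na(df$unit_id)]),
    FUN = sum)
  units <- units[order(units$well, units$electrode, units$unit_id), ,
                 drop = FALSE]
  rownames(units) <- NULL
  structure(list(spikes = spike_table(df, wf), units = units,
                 diagnostics = diagnostics, params = params),
            class = "sorted_units")
}

#' @export
print.sorted_units <- function(x, ...) {
  cat(sprintf("sorted_units: %d unit(s) on %d electrode(s); %d/%d spikes in outlier pool\n",
              nrow(x$units), length(x$diagnostics),
              sum(is.na(x$spikes$unit_id)), nrow(x$spikes)))
  invisible(x)
}

#' Per-unit firing rates and baseline-activity flags
#'
#' Computes each unit's firing rate (spikes/min) per phase and flags units
#' whose rate during the baseline phase is at least `min_rate` (inclusive);
#' only those units enter the assay statistics.
#'
#' @param sorted A `sorted_units` object, or a data frame with columns
#'   `well`, `electrode`, `unit_id`, `phase`, `time_s`.
#' @param plan A [phase_plan()] providing phase durations.
#' @param baseline Label of the baseline phase (default `"baseline1"`).
#' @param min_rate Activity threshold in spikes/min (default 2).
#' @return Data frame `unit` (well/electrode/unit key), `well`, `electrode`,
#'   `unit_id`, `phase`, `n_spikes`, `rate_per_min`, `active_in_baseline`.
#' @export
unit_rates <- function(sorted, plan, baseline = "baseline1", min_rate = 2) {
  df <- if (inherits(sorted, "sorted_units")) as.data.frame(sorted$spikes)
  else as.data.frame(sorted)
  df <- df[!is.na(df$unit_id), , drop = FALSE]
  df$unit <- paste0("w", df$well, "e", df$electrode, "u", df$unit_id)
  counts <- stats::aggregate(
    list(n_spikes = rep(1L, nrow(df))),
    by = list(unit = df$unit, well = df$well, electrode = df$electrode,
              unit_id = df$unit_id, phase = df$phase),
    FUN = sum)
  # complete the unit x phase grid with zero counts
  grid <- expand.grid(unit = unique(df$unit), phase = plan$phase,
                      stringsAsFactors = FALSE)
  ukey <- unique(counts[, c("unit", "well", "electrode", "unit_id")])
  grid <- merge(grid, ukey, by = "unit")
  out <- merge(grid, counts,
               by = c("unit", "well", "electrode", "unit_id", "phase"),
               all.x = TRUE)
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out$rate_per_min <- out$n_spikes / (phase_duration(plan, out$phase) / 60)
  base <- out[out$phase == baseline, c("unit", "rate_per_min")]
  names(base)[2] <- "baseline_rate"
  out <- merge(out, base, by = "unit", all.x = TRUE)
  out$baseline_rate[is.na(out$baseline_rate)] <- 0
  out$active_in_baseline <- out$baseline_rate >= min_rate
  out$baseline_rate <- NULL
  out <- out[order(out$unit, match(out$phase, plan$phase)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
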