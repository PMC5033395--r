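#' Match observed long steps with random available steps
#'
#' Builds the case-control strata of the step selection design. Pooled
#' empirical distributions of the observed long-step lengths (50 m bins) and
#' turn angles (10 degree bins) are formed; each observed step is matched
#' with `R` random steps sharing its start point, with length and turn drawn
#' from the binned distributions (uniform within a bin) and the endpoint
#' placed at bearing (previous absolute bearing + drawn turn). Endpoints
#' falling outside the landscape (or on nodata) are redrawn up to
#' `max_redraw` times, then dropped with a log message. Covariates are
#' extracted at step endpoints.
#'
#' @param long_steps step data.frame (output of [filter_long_steps()]);
#'   steps without a defined turn angle (track-initial) are skipped.
#' @param stack a `landscape_stack` supplying covariates.
#' @param R random steps per observed step (default 10).
#' @param bin_len length bin width in metres (default 50).
#' @param bin_turn turn-angle bin width in degrees (default 10).
#' @param seed integer seed.
#' @param max_redraw redraw budget per random step (default 20).
#' @return data.frame of class `ssf_strata`: `stratum_id`, `animal_id`,
#'   `used` (1/0), endpoint `x`, `y`, `length`, `turn_angle`, plus one
#'   column per stack layer.
#' @export
sample_random_steps <- function(long_steps, stack, R = 10, bin_len = 50,
                                bin_turn = 10, seed = 1, max_redraw = 20) {
  st <- long_steps[!is.na(long_steps$turn_angle) &
                     !is.na(long_steps$prev_bearing), , drop = FALSE]
  if (nrow(st) < 50)
    stop("need at least 50 long steps to form empirical distributions")
  set.seed(seed)

  len_breaks <- seq(0, max(st$length) + bin_len, by = bin_len)
  len_counts <- hist(st$length, breaks = len_breaks, plot = FALSE)$counts
  turn_breaks <- seq(-180, 180, by = bin_turn)
  turn_counts <- hist(st$turn_angle, breaks = turn_breaks, plot = FALSE)$counts

  draw <- function(n, breaks, counts) {
    bin <- sample.int(length(counts), n, replace = TRUE, prob = counts)
    runif(n, breaks[bin], breaks[bin + 1])
  }

  grid <- stack$layers[[1]]
  ext <- raster_extent(grid)
  n_obs <- nrow(st)
  # draw all R * n_obs random steps at once, then redraw invalid ones
  need <- rep(seq_len(n_obs), each = R)
  rx <- ry <- rl <- rt <- rep(NA_real_, length(need))
  pending <- seq_along(need)
  for (it in seq_len(max_redraw)) {
    if (!length(pending)) break
    i <- need[pending]
    L <- draw(length(pending), len_breaks, len_counts)
    Tn <- draw(length(pending), turn_breaks, turn_counts)
    ang <- (st$prev_bearing[i] + Tn) * pi / 180
    px <- st$x1[i] + L * cos(ang)
    py <- st$y1[i] + L * sin(ang)
    ok <- px >= ext["xmin"] & px <= ext["xmax"] &
      py >= ext["ymin"] & py <= ext["ymax"]
    ok[ok] <- !is.na(raster_extract(grid, px[ok], py[ok]))
    rx[pending[ok]] <- px[ok]; ry[pending[ok]] <- py[ok]
    rl[pending[ok]] <- L[ok]; rt[pending[ok]] <- Tn[ok]
    pending <- pending[!ok]
  }
  if (length(pending))
    message(sprintf("sample_random_steps: dropped %d random step(s) after %d redraws",
                    length(pending), max_redraw))
  ok_rand <- !is.na(rx)

  used_rows <- data.frame(stratum_id = seq_len(n_obs),
                          animal_id = st$animal_id, used = 1,
                          x = st$x2, y = st$y2,
                          length = st$length, turn_angle = st$turn_angle,
                          stringsAsFactors = FALSE)
  rand_rows <- data.frame(stratum_id = need[ok_rand],
                          animal_id = st$animal_id[need[ok_rand]], used = 0,
                          x = rx[ok_rand], y = ry[ok_rand],
                          length = rl[ok_rand], turn_angle = rt[ok_rand],
                          stringsAsFactors = FALSE)
  out <- rbind(used_rows, rand_rows)
  out <- out[order(out$stratum_id, -out$used), ]
  cov <- extract_covariates(out[, c("x", "y")], stack)
  out <- cbind(out, cov[, setdiff(names(cov), ".missing"), drop = FALSE])
  # drop rows whose endpoint sits on nodata in any layer
  out <- out[!cov$.missing, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssf_strata", "data.frame")
  out
}

#' Conditional log-likelihood of a step selection function
#'
#' `sum_s [eta_used(s) - log(sum_j exp(eta_j(s)))]` over strata; the
#' likelihood the matched conditional logistic regression maximises.
#'
#' @param beta coefficient vector aligned with `X` columns.
#' @param X design matrix.
#' @param used 0/1 used indicator.
#' @param stratum stratum id per row.
#' @return log-likelihood value.
#' @export
ssf_loglik <- function(beta, X, used, stratum) {
  eta <- as.vector(X %*% beta)
  num <- tapply(ifelse(used == 1, eta, -Inf), stratum, max)
  den <- tapply(eta, stratum, function(e) {
    m <- max(e); m + log(sum(exp(e - m)))
  })
  sum(num - den)
}

#' Fit a step selection function (matched conditional logit)
#'
#' Conditional logistic regression over 1-used : R-random strata via
#' `survival::clogit`. With a single case per stratum the Breslow, Efron and
#' exact partial likelihoods coincide, so the fast Breslow form is used.
#' A per-animal intercept is stratum-constant and hence unidentifiable in
#' this likelihood; the fixed-effects conditional logit is the estimator.
#'
#' @param strata an `ssf_strata` data.frame from [sample_random_steps()]
#'   (or any data.frame with `used`, `stratum_id` and the spec covariates).
#' @param spec a [design_spec()].
#' @return a `fitted_model` with `model_kind = "ssf_clogit"`; `loglik` is
#'   the fitted conditional log-likelihood, `null_loglik` its value at
#'   `beta = 0`.
#' @export
fit_ssf <- function(strata, spec) {
  if (length(unique(strata$stratum_id)) < 3)
    stop("need at least 3 strata")
  des <- build_design(strata, spec)
  keep <- complete.cases(des$X)
  X <- des$X[keep, , drop = FALSE]
  # a covariate constant within every stratum cancels from the conditional
  # likelihood and is inestimable
  sid0 <- strata$stratum_id[keep]
  for (cn in colnames(X)) {
    wv <- tapply(X[, cn], sid0, function(v) diff(range(v)))
    if (all(wv < 1e-12))
      stop("inestimable term '", cn, "': constant within every stratum")
  }
  df <- data.frame(.y = strata$used[keep], .sid = strata$stratum_id[keep], X,
                   check.names = FALSE)
  rhs <- paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  # conditional logit == Cox partial likelihood with one event per stratum;
  # Breslow/Efron/exact coincide here, so use the fast form directly
  fml <- as.formula(paste("survival::Surv(rep(1, nrow(df)), .y) ~", rhs,
                          "+ survival::strata(.sid)"))
  cl <- survival::coxph(fml, data = df, method = "breslow")
  beta <- coef(cl)
  if (any(is.na(beta))) {
    bad <- names(beta)[is.na(beta)]
    stop("inestimable term(s) (constant within every stratum?): ",
         paste(bad, collapse = ", "))
  }
  V <- as.matrix(vcov(cl))
  structure(list(beta = beta, se = sqrt(diag(V)), vcov = V,
                 loglik = cl$loglik[2], null_loglik = cl$loglik[1],
                 model_kind = "ssf_clogit",
                 random_intercept_variance = NA_real_,
                 spec = spec, learned = des$learned, terms = des$terms),
            class = "fitted_model")
}

#' Case-control k-fold cross-validation for step selection functions
#'
#' Fortin-style validation: per repetition, the SSF is refitted on a random
#' `train_frac` share of strata; on each withheld stratum the used step's
#' score is ranked against its matched random steps (rank 1 = highest score,
#' ties averaged), rank frequencies are tallied, and the Spearman
#' correlation between rank and frequency is recorded. The null repeats the
#' procedure ranking one randomly chosen withheld random step against the
#' remaining random steps. A strongly predictive model concentrates used
#' steps at rank 1, giving a strongly negative rank-frequency correlation
#' under this convention.
#'
#' @param strata an `ssf_strata` data.frame.
#' @param spec a [design_spec()].
#' @param train_frac training share of strata (default 0.8).
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @return list with `mean_rho`, `ci` (percentile 95%), `null_mean_rho`,
#'   `null_ci`, per-rep values, and `rank_convention`.
#' @export
fortin_cv <- function(strata, spec, train_frac = 0.8, reps = 100, seed = 1) {
  sids <- unique(strata$stratum_id)
  if (length(sids) < 50) stop("need at least 50 strata")
  set.seed(seed)
  rho <- rho0 <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    tr <- sample(sids, round(train_frac * length(sids)))
    test <- strata[!(strata$stratum_id %in% tr), , drop = FALSE]
    m <- fit_ssf(strata[strata$stratum_id %in% tr, , drop = FALSE], spec)
    eta <- .model_eta(m, test)
    by_s <- split(seq_len(nrow(test)), test$stratum_id)
    n_rank <- max(lengths(by_s))
    ranks <- vapply(by_s, function(ix) {
      rk <- rank(-eta[ix])
      rk[test$used[ix] == 1][1]
    }, 0)
    freq <- tabulate(floor(ranks), nbins = n_rank)
    rho[r] <- suppressWarnings(
      cor(seq_len(n_rank), freq, method = "spearman"))
    null_ranks <- vapply(by_s, function(ix) {
      rnd <- ix[test$used[ix] == 0]
      if (length(rnd) < 2) return(NA_real_)
      pick <- sample(length(rnd), 1)
      rank(-eta[rnd])[pick]
    }, 0)
    null_ranks <- null_ranks[!is.na(null_ranks)]
    n0 <- max(lengths(by_s)) - 1
    freq0 <- tabulate(floor(null_ranks), nbins = n0)
    rho0[r] <- suppressWarnings(cor(seq_len(n0), freq0, method = "spearman"))
  }
  list(mean_rho = mean(rho, na.rm = TRUE),
       ci = quantile(rho, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       null_mean_rho = mean(rho0, na.rm = TRUE),
       null_ci = quantile(rho0, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       rho = rho, null_rho = rho0,
       rank_convention = "rank 1 = highest SSF score")
}
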