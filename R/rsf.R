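#' Sample availability locations within the MCP
#'
#' The used-available design contrasts each telemetry fix with `ratio`
#' random locations drawn uniformly within the study-area minimum convex
#' polygon.
#'
#' @param used_points data.frame/matrix of used (x, y).
#' @param mcp closed-ring polygon delimiting availability.
#' @param ratio available points per used point (default 10).
#' @param seed integer seed.
#' @return data.frame with columns x, y (`ratio * n_used` rows).
#' @export
sample_availability <- function(used_points, mcp, ratio = 10, seed = 1) {
  n <- nrow(as.data.frame(used_points))
  sample_points_in_polygon(mcp, ratio * n, seed = seed)
}

# per-animal cluster-robust (CR0-with-df-correction) covariance for a
# binomial glm: bread %*% meat %*% bread on cluster-summed scores
.cluster_robust_vcov <- function(fit, cluster, X) {
  res <- fit$y - fit$fitted.values
  U <- X * res
  Us <- rowsum(U, cluster)
  m <- nrow(Us)
  meat <- crossprod(Us) * m / max(m - 1, 1)
  bread <- vcov(fit)
  bread %*% meat %*% bread
}

#' Fit a used-available resource selection function
#'
#' Binomial GLMM (logit link) of used vs available with a per-animal random
#' intercept, estimated by Laplace approximation via `lme4::glmer`. When the
#' random-intercept variance estimate is singular (zero) or
#' `random_intercept = FALSE`, falls back to plain logistic regression with
#' per-animal cluster-robust standard errors (flagged in the result).
#'
#' @param data data.frame holding the response, animal ids and all spec
#'   covariates (used and available rows stacked).
#' @param spec a [design_spec()].
#' @param response name of the 0/1 used column.
#' @param animal name of the animal-id column (available rows may carry any
#'   id; they are treated as their own cluster per assigned id).
#' @param random_intercept fit the GLMM (default) or the fixed-effects
#'   fallback directly.
#' @return a `fitted_model` with `beta` (incl. `(Intercept)`), `se`, `vcov`,
#'   `loglik`, `random_intercept_variance`, `model_kind = "rsf_glmm"`,
#'   the spec, learned design constants and term table.
#' @export
fit_rsf <- function(data, spec, response = "used", animal = "animal_id",
                    random_intercept = TRUE) {
  y <- data[[response]]
  if (is.null(y) || length(unique(y)) < 2)
    stop("response must contain both used and available rows")
  des <- build_design(data, spec)
  X <- des$X
  keep <- if (ncol(X) == 0) !is.na(y) else complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  cluster <- as.character(data[[animal]])[keep]
  df <- data.frame(.y = y, X, check.names = FALSE)
  df$.animal <- cluster
  rhs <- if (ncol(X) == 0) "1" else
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")

  fallback <- FALSE; ri_var <- NA_real_
  fit <- NULL
  if (random_intercept && length(unique(cluster)) > 1) {
    fml <- as.formula(paste(".y ~", rhs, "+ (1 | .animal)"))
    gm <- tryCatch(
      suppressMessages(lme4::glmer(fml, data = df, family = binomial())),
      error = function(e) NULL)
    if (!is.null(gm) && !lme4::isSingular(gm, tol = 1e-5)) {
      beta <- lme4::fixef(gm)
      V <- as.matrix(vcov(gm))
      ri_var <- unname(lme4::VarCorr(gm)$.animal[1])
      fit <- list(beta = beta, vcov = V, loglik = as.numeric(stats::logLik(gm)))
    }
  }
  if (is.null(fit)) {
    fallback <- TRUE
    gl <- glm(as.formula(paste(".y ~", rhs)), data = df, family = binomial())
    if (!gl$converged || any(abs(coef(gl)[-1]) > 15)) {
      worst <- names(which.max(abs(coef(gl)[-1])))
      stop("RSF did not converge (possible complete separation in term '",
           worst, "')")
    }
    beta <- coef(gl)
    Xi <- cbind(`(Intercept)` = 1, X)
    # animals are the clusters; availability rows are an iid background
    # sample and enter as singletons
    cl2 <- ifelse(y == 1, cluster, paste0(".avail", seq_along(y)))
    V <- if (length(unique(cl2)) > 1)
      .cluster_robust_vcov(gl, cl2, Xi) else as.matrix(vcov(gl))
    ri_var <- 0
    fit <- list(beta = beta, vcov = V, loglik = as.numeric(stats::logLik(gl)))
  }
  names(fit$beta)[1] <- "(Intercept)"
  dimnames(fit$vcov) <- list(names(fit$beta), names(fit$beta))
  structure(list(beta = fit$beta, se = sqrt(diag(fit$vcov)),
                 vcov = fit$vcov, loglik = fit$loglik,
                 model_kind = "rsf_glmm",
                 random_intercept_variance = ri_var,
                 fallback_glm = fallback,
                 spec = spec, learned = des$learned, terms = des$terms),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s, logLik %.2f%s\n", x$model_kind, x$loglik,
              if (isTRUE(x$fallback_glm)) " (glm fallback, robust se)" else ""))
  tab <- data.frame(beta = round(x$beta, 4), se = round(x$se, 4),
                    p = signif(2 * pnorm(-abs(x$beta / x$se)), 3))
  print(tab)
  invisible(x)
}

#' Coefficient table of a fitted model
#' @param model a `fitted_model`.
#' @return data.frame with term, beta, se, p.
#' @export
coef_table <- function(model) {
  data.frame(term = names(model$beta), beta = unname(model$beta),
             se = unname(model$se),
             p = 2 * pnorm(-abs(model$beta / model$se)),
             stringsAsFactors = FALSE)
}

# droppable term groups for backward elimination, honouring the hierarchy:
# a quadratic column drops before its linear column; a categorical variable
# drops as one block
.wald_groups <- function(model) {
  tm <- model$terms
  groups <- list()
  for (nm in unique(tm$base[tm$kind == "dummy"]))
    groups[[nm]] <- tm$column[tm$base == nm & tm$kind == "dummy"]
  for (i in which(tm$kind == "quadratic"))
    groups[[tm$column[i]]] <- tm$column[i]
  for (i in which(tm$kind == "linear")) {
    nm <- tm$base[i]
    if (!any(tm$kind == "quadratic" & tm$base == nm))  # hierarchy
      groups[[tm$column[i]]] <- tm$column[i]
  }
  groups
}

.group_p <- function(model, cols) {
  cols <- intersect(cols, names(model$beta))
  if (length(cols) == 0) return(NA_real_)
  b <- model$beta[cols]
  V <- model$vcov[cols, cols, drop = FALSE]
  w <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) NA)
  if (!is.finite(w)) return(NA_real_)
  stats::pchisq(w, df = length(cols), lower.tail = FALSE)
}

#' Backward elimination on Wald statistics
#'
#' Repeatedly refits after dropping the least-significant droppable term
#' group with p > `alpha`: quadratic columns drop before their linear
#' columns, categorical variables drop as a block, ties go to the larger
#' standard error. Standard model-building step for both RSF and SSF.
#'
#' @param model a `fitted_model` from [fit_rsf()] or [fit_ssf()].
#' @param data the data the model was fitted on (rows for RSF, strata rows
#'   for SSF).
#' @param alpha retention threshold (default 0.05).
#' @param ... passed on to the refitting function.
#' @return the final `fitted_model`, with an `elimination` data.frame
#'   attribute recording each drop.
#' @export
eliminate_by_wald <- function(model, data, alpha = 0.05, ...) {
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0))
  step <- 0
  repeat {
    groups <- .wald_groups(model)
    if (length(groups) == 0) break
    ps <- vapply(groups, function(g) .group_p(model, g), 0)
    ps <- ps[is.finite(ps)]
    if (length(ps) == 0 || max(ps) <= alpha) break
    worst <- max(ps)
    cand <- names(ps)[ps == worst]
    if (length(cand) > 1) {  # ties: larger se drops first
      ses <- vapply(cand, function(g)
        max(model$se[intersect(groups[[g]], names(model$se))]), 0)
      cand <- cand[which.max(ses)]
    }
    victim <- cand[1]
    spec2 <- .drop_term(model$spec, model$terms, victim)
    empty <- length(spec2$continuous) == 0 && length(spec2$categorical) == 0
    if (empty && model$model_kind == "ssf_clogit")
      break  # a conditional logit needs at least one term; keep the last fit
    step <- step + 1
    trace <- rbind(trace, data.frame(step = step, dropped = victim,
                                     p = worst))
    model <- if (model$model_kind == "ssf_clogit")
      fit_ssf(data, spec2, ...) else fit_rsf(data, spec2, ...)
  }
  attr(model, "elimination") <- trace
  model
}

# remove one droppable group (column name or categorical base) from a spec
.drop_term <- function(spec, terms, victim) {
  if (victim %in% spec$categorical) {
    spec$categorical <- setdiff(spec$categorical, victim)
  } else {
    row <- terms[terms$column == victim, ]
    if (row$kind == "quadratic") {
      spec$quadratic[[row$base]] <- FALSE
    } else {
      spec$continuous <- setdiff(spec$continuous, row$base)
      spec$quadratic <- spec$quadratic[names(spec$quadratic) != row$base]
    }
  }
  spec
}

#' Relative selection scores from a fitted model
#'
#' `w(x) = exp(beta . x)` without the intercept, rescaled by the maximum
#' over the scored rows so the best unit scores exactly 1.
#'
#' @param model a `fitted_model`.
#' @param rows data.frame of covariates (model terms required).
#' @return numeric vector of scores in (0, 1], `NA` for incomplete rows.
#' @export
rsf_score <- function(model, rows) {
  eta <- .model_eta(model, rows)
  exp(eta - max(eta, na.rm = TRUE))  # max rescale, overflow-safe
}

# linear predictor without intercept (scores up to a multiplicative
# constant); shared by scoring, cross-validation and surface prediction
.model_eta <- function(model, rows) {
  des <- build_design(rows, model$spec, learned = model$learned)
  b <- model$beta[setdiff(names(model$beta), "(Intercept)")]
  if (length(b) == 0) return(rep(0, nrow(rows)))  # intercept-only model
  as.vector(des$X[, names(b), drop = FALSE] %*% b)
}

#' Boyce-style 5-fold cross-validation of an RSF
#'
#' Used points are split into `k` folds; for each fold the model is refitted
#' on the remaining used points (with the full availability sample), the
#' withheld used points and the availability sample are scored, scores are
#' cut into `n_bins` quantile bins of the availability scores, and the
#' Spearman rank correlation between bin rank and area-adjusted frequency
#' (withheld-used frequency / available frequency per bin) is returned per
#' fold. Empty availability bins are merged with their lower neighbour.
#'
#' @param used data.frame of used rows (covariates + animal ids).
#' @param available data.frame of availability rows.
#' @param spec a [design_spec()].
#' @param k folds (default 5).
#' @param n_bins score bins (default 10).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [fit_rsf()] (e.g. `random_intercept = FALSE`).
#' @return list with `rho` (per-fold Spearman), `mean_rho`, and the per-fold
#'   bin tables.
#' @export
boyce_cv <- function(used, available, spec, k = 5, n_bins = 10, seed = 1,
                     ...) {
  n <- nrow(used)
  if (n < k * n_bins) stop("need at least k*n_bins used points")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  if (is.null(available$animal_id)) available$animal_id <- "available"
  if (is.null(used$animal_id)) used$animal_id <- "used"
  used$used <- 1; available$used <- 0
  rho <- numeric(k); tables <- vector("list", k)
  for (f in seq_len(k)) {
    train <- rbind(used[fold != f, , drop = FALSE], available)
    m <- fit_rsf(train, spec, ...)
    eta_test <- .model_eta(m, used[fold == f, , drop = FALSE])
    eta_av <- .model_eta(m, available)
    top <- max(c(eta_test, eta_av), na.rm = TRUE)  # one shared rescaling
    s_test <- exp(eta_test - top)
    s_av <- exp(eta_av - top)
    edges <- unique(quantile(s_av, probs = seq(0, 1, length.out = n_bins + 1),
                             na.rm = TRUE))
    if (length(edges) < 3) {  # degenerate scores (e.g. intercept-only fit)
      message("boyce_cv: degenerate score distribution in fold ", f)
      rho[f] <- NA_real_
      next
    }
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    bu <- table(cut(s_test, edges))
    ba <- table(cut(s_av, edges))
    # merge empty availability bins downward
    while (any(ba == 0) && length(ba) > 2) {
      i <- which(ba == 0)[1]; j <- if (i == 1) 2 else i - 1
      ba[j] <- ba[j] + ba[i]; bu[j] <- bu[j] + bu[i]
      ba <- ba[-i]; bu <- bu[-i]
      message("boyce_cv: merged empty score bin")
    }
    adj <- (as.numeric(bu) / sum(bu)) / (as.numeric(ba) / sum(ba))
    rho[f] <- suppressWarnings(
      cor(seq_along(adj), adj, method = "spearman"))
    tables[[f]] <- data.frame(bin = seq_along(adj), used = as.numeric(bu),
                              available = as.numeric(ba), adjusted = adj)
  }
  list(rho = rho, mean_rho = mean(rho), tables = tables)
}
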