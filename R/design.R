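#' Screen covariates for collinearity
#'
#' Two-stage screen used before every model fit: (1) for each pair of
#' continuous covariates with |Pearson r| above `r_max`, drop the
#' lower-priority member (later in the supplied column order); (2) refit
#' variance inflation factors and drop the worst covariate until all
#' VIF <= `vif_max`. Constant columns are dropped with a warning.
#'
#' @param tab data.frame of continuous covariates (columns in priority
#'   order).
#' @param r_max pairwise correlation limit (default 0.7).
#' @param vif_max variance-inflation limit (default 3).
#' @return list with `retained` (character) and `dropped` (data.frame of
#'   variable, reason, detail).
#' @export
screen_collinearity <- function(tab, r_max = 0.7, vif_max = 3) {
  tab <- as.data.frame(tab)
  if (nrow(tab) < 10) stop("need at least 10 rows")
  drops <- data.frame(variable = character(0), reason = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  keep <- names(tab)
  for (nm in names(tab)) {
    if (sd(tab[[nm]], na.rm = TRUE) == 0 || all(is.na(tab[[nm]]))) {
      warning("dropping constant column '", nm, "'")
      keep <- setdiff(keep, nm)
      drops <- rbind(drops, data.frame(variable = nm, reason = "constant",
                                       detail = ""))
    }
  }
  if (length(keep) < 2) stop("need at least 2 non-constant covariates")

  repeat {
    cm <- abs(cor(tab[keep], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    # drop the later (lower-priority) member of the worst pair
    victim <- keep[max(ij)]
    partner <- keep[min(ij)]
    drops <- rbind(drops, data.frame(
      variable = victim, reason = "pairwise_r",
      detail = sprintf("r=%.3f with %s", max(cm), partner)))
    keep <- setdiff(keep, victim)
    if (length(keep) < 2) break
  }

  vif_of <- function(nms) {
    vapply(nms, function(nm) {
      f <- lm.fit(cbind(1, as.matrix(tab[setdiff(nms, nm)])), tab[[nm]])
      r2 <- 1 - sum(f$residuals^2) / sum((tab[[nm]] - mean(tab[[nm]]))^2)
      1 / max(1 - r2, 1e-12)
    }, 0)
  }
  while (length(keep) > 2) {
    v <- vif_of(keep)
    if (max(v) <= vif_max) break
    victim <- names(v)[which.max(v)]
    drops <- rbind(drops, data.frame(variable = victim, reason = "vif",
                                     detail = sprintf("vif=%.2f", max(v))))
    keep <- setdiff(keep, victim)
  }
  list(retained = keep, dropped = drops)
}

#' Model design specification
#'
#' Declares how covariates enter a selection model: continuous terms are
#' optionally capped (road distances held flat beyond the distance at which
#' they influence behaviour: 2 km for highways, 1 km for gravel roads),
#' standardized, and optionally expanded with a quadratic; categorical terms
#' are dummy-coded against a stated reference class.
#'
#' @param continuous character vector of continuous term names.
#' @param quadratic logical scalar or named logical per term: include a
#'   squared term (computed after standardization).
#' @param caps named numeric caps in metres, applied before standardization.
#' @param categorical character vector of categorical term names.
#' @param reference named character: reference level per categorical term.
#' @param levels named list of full level sets per categorical term
#'   (optional; learned from data otherwise).
#' @param standardize centre/scale continuous terms (constants learned on
#'   the training data of each fit).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(continuous = character(0), quadratic = TRUE,
                        caps = c(dist_highway = 2000, dist_gravel = 1000),
                        categorical = character(0),
                        reference = c(landcover = "conifer"),
                        levels = list(), standardize = TRUE) {
  if (length(quadratic) == 1)
    quadratic <- setNames(rep(quadratic, length(continuous)), continuous)
  stopifnot(all(caps > 0))
  structure(list(continuous = continuous, quadratic = quadratic,
                 caps = caps, categorical = categorical,
                 reference = reference, levels = levels,
                 standardize = standardize),
            class = "design_spec")
}

#' Build a model design matrix from covariate rows
#'
#' Applies the caps, standardization, quadratic expansion and reference
#' dummy coding declared in the [design_spec()]. When `learned` (from a
#' previous call on training data) is supplied, its centring/scaling
#' constants and level sets are reused, and an unseen categorical level is
#' an error.
#'
#' @param rows data.frame containing every spec term.
#' @param spec a `design_spec`.
#' @param learned optional learned constants from a training-set call.
#' @return list with `X` (matrix, no intercept column), `learned`, and
#'   `terms` (data.frame describing each column: term, base variable, kind).
#' @export
build_design <- function(rows, spec, learned = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  cols <- list(); terms <- list()
  if (is.null(learned)) learned <- list(center = c(), scale = c(), levels = list())
  for (nm in spec$continuous) {
    if (is.null(rows[[nm]])) stop("missing covariate '", nm, "'")
    v <- rows[[nm]]
    if (nm %in% names(spec$caps)) v <- pmin(v, spec$caps[[nm]])
    if (spec$standardize) {
      if (is.null(learned$center[nm]) || is.na(learned$center[nm])) {
        learned$center[nm] <- mean(v, na.rm = TRUE)
        s <- sd(v, na.rm = TRUE)
        learned$scale[nm] <- if (is.finite(s) && s > 0) s else 1
      }
      v <- (v - learned$center[[nm]]) / learned$scale[[nm]]
    }
    cols[[nm]] <- v
    terms[[nm]] <- data.frame(column = nm, base = nm, kind = "linear")
    if (isTRUE(spec$quadratic[[nm]])) {
      cn <- paste0(nm, "_sq")
      cols[[cn]] <- v^2
      terms[[cn]] <- data.frame(column = cn, base = nm, kind = "quadratic")
    }
  }
  for (nm in spec$categorical) {
    if (is.null(rows[[nm]])) stop("missing covariate '", nm, "'")
    v <- as.character(rows[[nm]])
    levs <- learned$levels[[nm]]
    if (is.null(levs)) {
      levs <- spec$levels[[nm]]
      if (is.null(levs)) levs <- sort(unique(v))
      ref <- spec$reference[[nm]]
      if (!is.null(ref) && ref %in% levs) levs <- c(ref, setdiff(levs, ref))
      learned$levels[[nm]] <- levs
    }
    unseen <- setdiff(unique(v), levs)
    if (length(unseen))
      stop("unseen level(s) in '", nm, "': ", paste(unseen, collapse = ", "))
    for (cl in levs[-1]) {  # first level is the reference
      cn <- paste0(nm, "_", cl)
      cols[[cn]] <- as.numeric(v == cl)
      terms[[cn]] <- data.frame(column = cn, base = nm, kind = "dummy")
    }
  }
  if (length(cols) == 0) {
    # intercept-only model (e.g. after backward elimination removed all)
    return(list(X = matrix(numeric(0), nrow = nrow(rows), ncol = 0),
                learned = learned,
                terms = data.frame(column = character(0),
                                   base = character(0),
                                   kind = character(0))))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, learned = learned,
       terms = do.call(rbind, unname(terms)))
}
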