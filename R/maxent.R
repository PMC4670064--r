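#' Feature expansion for maximum-entropy models
#'
#' Builds the feature dictionary used by [maxent_sdm()]. Raw variables are
#' min-max scaled to `[0, 1]` using bounds computed over the background
#' sample only (the bounds double as clamping limits at prediction time).
#' Feature classes, applied to the scaled variable `z`:
#' \describe{
#'   \item{linear}{`z`}
#'   \item{quadratic}{`z^2`}
#'   \item{product}{`z_i * z_j` for every variable pair}
#'   \item{hinge}{forward `max(0, (z - k)/(1 - k))` and reverse
#'     `max(0, (k - z)/k)` at `n_hinge_knots` evenly spaced interior knots}
#' }
#' Background-constant variables are dropped with a warning; a single
#' variable with the product class yields no product features (warning).
#'
#' @param background matrix or data frame of raw background environment.
#' @param classes subset of `c("linear","quadratic","product","hinge")`, or
#'   a compact string such as `"lqh"`.
#' @param n_hinge_knots number of interior hinge knots per variable and
#'   direction (default 50).
#' @return Object of class `maxent_features`: the scaling bounds and a
#'   feature table (`kind`, variables, knot, direction, name).
#' @export
maxent_features <- function(background, classes = "lqh", n_hinge_knots = 50) {
  classes <- parse_feature_classes(classes)
  bg <- as.matrix(background)
  vars <- colnames(bg)
  if (is.null(vars)) stop_named("background must have column names")
  lo <- apply(bg, 2L, min)
  hi <- apply(bg, 2L, max)
  const <- vars[hi - lo <= 0]
  if (length(const)) {
    warn_named("dropping background-constant variable(s): %s",
               paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
    if (!length(vars)) stop_named("no non-constant variables left")
  }
  meta <- data.frame(kind = character(), var1 = character(),
                     var2 = character(), knot = numeric(),
                     name = character(), stringsAsFactors = FALSE)
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_, name) {
    rbind(meta, data.frame(kind = kind, var1 = var1, var2 = var2,
                           knot = knot, name = name))
  }
  if ("linear" %in% classes) {
    for (v in vars) meta <- add("linear", v, name = paste0("l_", v))
  }
  if ("quadratic" %in% classes) {
    for (v in vars) meta <- add("quadratic", v, name = paste0("q_", v))
  }
  if ("product" %in% classes) {
    if (length(vars) < 2L) {
      warn_named("product class requested with a single variable; skipped")
    } else {
      for (i in seq_len(length(vars) - 1L)) for (j in (i + 1L):length(vars)) {
        meta <- add("product", vars[i], vars[j],
                    name = paste0("p_", vars[i], ":", vars[j]))
      }
    }
  }
  if ("hinge" %in% classes) {
    knots <- seq(0, 1, length.out = n_hinge_knots + 2L)
    knots <- knots[-c(1L, length(knots))]
    for (v in vars) for (k in knots) {
      meta <- add("hinge_fwd", v, knot = k,
                  name = sprintf("hf_%s_%.4f", v, k))
      meta <- add("hinge_rev", v, knot = k,
                  name = sprintf("hr_%s_%.4f", v, k))
    }
  }
  structure(list(vars = vars, lower = lo[vars], upper = hi[vars],
                 classes = classes, n_hinge_knots = n_hinge_knots,
                 meta = meta),
            class = "maxent_features")
}

parse_feature_classes <- function(classes) {
  full <- c(l = "linear", q = "quadratic", p = "product", h = "hinge")
  if (length(classes) == 1L && !classes %in% full) {
    classes <- unname(full[strsplit(tolower(classes), "")[[1L]]])
    if (anyNA(classes)) stop_named("unknown feature class letter")
  }
  bad <- setdiff(classes, full)
  if (length(bad)) {
    stop_named("unknown feature class(es): %s", paste(bad, collapse = ", "))
  }
  unique(classes)
}

#' Evaluate a feature dictionary on raw environment data
#'
#' @param spec a [maxent_features()] object.
#' @param env raw environment matrix/data frame containing `spec$vars`.
#' @param clamp clip scaled variables into `[0, 1]` (i.e. hold raw values
#'   at the training bounds) before evaluating features.
#' @return Numeric design matrix, one column per feature.
#' @export
feature_design <- function(spec, env, clamp = TRUE) {
  env <- as.matrix(env)
  miss <- setdiff(spec$vars, colnames(env))
  if (length(miss)) {
    stop_named("environment is missing variable(s): %s",
               paste(miss, collapse = ", "))
  }
  z <- sweep(env[, spec$vars, drop = FALSE], 2L, spec$lower, `-`)
  z <- sweep(z, 2L, spec$upper - spec$lower, `/`)
  if (clamp) z <- pmin(pmax(z, 0), 1)
  m <- spec$meta
  out <- matrix(0, nrow(z), nrow(m), dimnames = list(NULL, m$name))
  for (f in seq_len(nrow(m))) {
    x <- z[, m$var1[f]]
    out[, f] <- switch(m$kind[f],
      linear = x,
      quadratic = x^2,
      product = x * z[, m$var2[f]],
      hinge_fwd = pmax(0, (x - m$knot[f]) / (1 - m$knot[f])),
      hinge_rev = pmax(0, (m$knot[f] - x) / m$knot[f]))
  }
  out
}

# Per-feature L1 penalty scales, following the published MaxEnt default
# tables: a class-specific multiplier interpolated at the presence sample
# size m (rule-2 linear interpolation), divided by sqrt(m), times the
# feature's standard deviation over the presences (floored at 1/sqrt(m)).
#   linear:    m = (0,10,30,100)    -> (1.0, 1.0, 0.2, 0.05)
#   quadratic: m = (0,10,17,30,100) -> (1.3, 0.8, 0.5, 0.25, 0.05)
#   product:   m = (0,10,17,30,100) -> (2.6, 1.6, 1.0, 0.5, 0.05)
#   hinge:     0.5 at every sample size
regularization_scales <- function(meta, presence_dm) {
  m <- nrow(presence_dm)
  tabs <- list(
    linear = list(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    quadratic = list(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product = list(c(0, 10, 17, 30, 100), c(2.6, 1.6, 1, 0.5, 0.05)),
    hinge = list(c(0, 1), c(0.5, 0.5)))
  cls <- sub("hinge_(fwd|rev)", "hinge", meta$kind)
  mult <- vapply(cls, function(k) {
    t <- tabs[[k]]
    stats::approx(t[[1L]], t[[2L]], m, rule = 2L)$y
  }, numeric(1L))
  sds <- pmax(apply(presence_dm, 2L, stats::sd), 1 / sqrt(m))
  unname(mult * sds / sqrt(m))
}

#' Penalized maximum-entropy presence-background model
#'
#' Fits a Gibbs (log-linear) distribution over the background by maximizing
#' the L1-penalized presence log-likelihood
#' \deqn{\frac{1}{m}\sum_{presences} \eta(x) - \log Z_w -
#'       \beta \sum_j s_j |\lambda_j|,}
#' where \eqn{\eta(x) = \sum_j \lambda_j f_j(x)} is the linear predictor
#' over the feature expansion, \eqn{Z_w = \sum_{background} w(x) e^{\eta(x)}}
#' is the weighted normalizer, and \eqn{s_j} are the feature-class
#' regularization scales of the published MaxEnt defaults (see
#' `regularization_scales` in the source; `beta` multiplies them
#' uniformly). Optimization is monotone proximal-gradient descent with
#' Barzilai-Borwein steps and backtracking; the penalized objective is
#' non-decreasing across iterations by construction.
#'
#' @param presence,background raw environment tables (same columns);
#'   at least 2 presence rows, and at least as many background rows.
#' @param classes feature classes, e.g. `"lqh"` (see [maxent_features()]).
#' @param beta regularization multiplier (default 1; the source study
#'   sweeps 1 to 3).
#' @param bg_weights optional background weights (e.g. a sampling-bias
#'   correction); normalized internally to sum to 1.
#' @param n_hinge_knots hinge knots per variable and direction.
#' @param features optionally a pre-built [maxent_features()] object.
#' @param control list: `tol` (objective-change convergence threshold,
#'   default `1e-7`), `maxit` (default 5000), `gtol` (additional
#'   proximal-gradient residual threshold, default `Inf`), `init`
#'   (optional warm-start coefficient vector, e.g. from a fit on a
#'   superset of the presences). Failure to meet `tol` within `maxit`
#'   iterations is an error carrying the objective trace.
#' @return Object of class `maxent_sdm` with components `features`,
#'   `lambda`, `beta`, `reg_scales`, normalizers `Zw` and `Z` (weighted /
#'   unweighted, over the training background), `entropy` of the fitted
#'   raw distribution, the objective `trace`, and training metadata.
#' @seealso [predict.maxent_sdm()], [variable_importance()],
#'   [response_curve()], [rank_candidates()]
#' @export
maxent_sdm <- function(presence, background, classes = "lqh", beta = 1,
                       bg_weights = NULL, n_hinge_knots = 50,
                       features = NULL, control = list()) {
  ctl <- utils::modifyList(list(tol = 1e-7, maxit = 5000, gtol = Inf,
                                init = NULL), control)
  presence <- as.matrix(presence); background <- as.matrix(background)
  if (nrow(presence) < 2L) stop_named("need at least 2 presence rows")
  if (nrow(background) < nrow(presence)) {
    stop_named("background must have at least as many rows as presences")
  }
  spec <- features %||% maxent_features(background, classes, n_hinge_knots)
  Xp <- feature_design(spec, presence)
  Xb <- feature_design(spec, background)
  w <- bg_weights %||% rep(1, nrow(Xb))
  if (length(w) != nrow(Xb) || any(w < 0) || sum(w) <= 0) {
    stop_named("invalid background weights")
  }
  w <- w / sum(w)
  s <- regularization_scales(spec$meta, Xp)
  pbar <- colMeans(Xp)
  logw <- log(w)

  # negative penalized log-likelihood and its smooth part / gradient
  smooth_parts <- function(lam) {
    eta <- as.vector(Xb %*% lam)
    a <- logw + eta
    amax <- max(a)
    lse <- amax + log(sum(exp(a - amax)))
    q <- exp(a - lse)
    list(f = -sum(pbar * lam) + lse, q = q)
  }
  obj <- function(lam, f_smooth) f_smooth + beta * sum(s * abs(lam))
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lam <- rep(0, ncol(Xb))
  if (!is.null(ctl$init)) {
    if (length(ctl$init) != ncol(Xb)) stop_named("init has the wrong length")
    lam <- as.numeric(ctl$init)
  }
  sp <- smooth_parts(lam)
  Fcur <- obj(lam, sp$f)
  g <- -pbar + as.vector(crossprod(Xb, sp$q))
  t_step <- 1
  trace <- Fcur
  converged <- FALSE
  for (it in seq_len(ctl$maxit)) {
    repeat {
      lam_new <- soft(lam - t_step * g, t_step * beta * s)
      d <- lam_new - lam
      sp_new <- smooth_parts(lam_new)
      if (sp_new$f <= sp$f + sum(g * d) + sum(d * d) / (2 * t_step) + 1e-12) {
        break
      }
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    Fnew <- obj(lam_new, sp_new$f)
    g_new <- -pbar + as.vector(crossprod(Xb, sp_new$q))
    dF <- Fcur - Fnew
    resid <- if (t_step > 0) max(abs(d)) / t_step else 0
    # Barzilai-Borwein step for the next iteration
    dg <- g_new - g
    denom <- sum(d * dg)
    if (denom > 0) t_step <- min(max(sum(d * d) / denom, 1e-10), 1e6)
    lam <- lam_new; sp <- sp_new; g <- g_new; Fcur <- Fnew
    trace <- c(trace, Fcur)
    if (dF >= 0 && dF < ctl$tol && resid < ctl$gtol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "maxent fit did not converge in %d iterations (last objective %.8g)",
      ctl$maxit, Fcur))
    cond$trace <- trace
    stop(cond)
  }
  names(lam) <- spec$meta$name
  eta_b <- as.vector(Xb %*% lam)
  amax <- max(eta_b)
  Z <- sum(exp(eta_b - amax)) * exp(amax)           # unweighted normalizer
  aw <- logw + eta_b
  awmax <- max(aw)
  Zw <- sum(exp(aw - awmax)) * exp(awmax)           # weighted normalizer
  qt <- exp(eta_b - amax) / sum(exp(eta_b - amax))  # unweighted raw dist
  H <- -sum(ifelse(qt > 0, qt * log(qt), 0))
  structure(list(features = spec, lambda = lam, beta = beta, reg_scales = s,
                 Z = Z, Zw = Zw, entropy = H,
                 env_means = colMeans(background[, spec$vars, drop = FALSE]),
                 n_presence = nrow(presence), n_background = nrow(Xb),
                 bg_weights = w, objective = -Fcur, trace = -trace,
                 iterations = length(trace) - 1L, converged = converged,
                 call = match.call()),
            class = "maxent_sdm")
}

#' @export
print.maxent_sdm <- function(x, ...) {
  cat("Maximum-entropy presence-background model\n")
  cat(sprintf("  features: %s (%d total, %d with nonzero coefficient)\n",
              paste(x$features$classes, collapse = "+"),
              length(x$lambda), sum(x$lambda != 0)))
  cat(sprintf("  beta = %g, presences = %d, background = %d\n",
              x$beta, x$n_presence, x$n_background))
  cat(sprintf("  penalized log-likelihood = %.4f, entropy = %.4f (%d iter)\n",
              x$objective, x$entropy, x$iterations))
  invisible(x)
}

#' @export
summary.maxent_sdm <- function(object, ...) {
  nz <- object$lambda[object$lambda != 0]
  out <- list(model = object,
              coefficients = data.frame(feature = names(nz), lambda = nz,
                                        row.names = NULL))
  class(out) <- "summary.maxent_sdm"
  out
}

#' @export
print.summary.maxent_sdm <- function(x, ...) {
  print(x$model)
  cat("nonzero coefficients:\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
coef.maxent_sdm <- function(object, ...) object$lambda

#' Predict from a fitted maximum-entropy model
#'
#' @param object a [maxent_sdm()] fit.
#' @param newdata raw environment table, or a [raster_stack()] containing
#'   every model variable (nodata propagates and a `raster_grid` is
#'   returned).
#' @param type `"logistic"` (default) gives the suitability
#'   \eqn{s = e^H \tilde q / (1 + e^H \tilde q)} in (0, 1), with
#'   \eqn{\tilde q = e^\eta / Z} the raw probability normalized over the
#'   training background and `H` the entropy of the fitted raw
#'   distribution; `"raw"` gives \eqn{\tilde q} itself (or the
#'   weighted version \eqn{w e^\eta / Z_w} when `weights` are supplied,
#'   which sums to 1 over the training background with its training
#'   weights); `"link"` gives \eqn{\eta}. Both outputs are rank-equivalent.
#' @param clamp hold variables outside the training bounds at the bounds.
#' @param weights optional per-row weights for the weighted raw output.
#' @param ... unused.
#' @return Numeric vector, or a `raster_grid` for stack input.
#' @export
predict.maxent_sdm <- function(object, newdata,
                               type = c("logistic", "raw", "link"),
                               clamp = TRUE, weights = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raster_stack")) {
    miss <- setdiff(object$features$vars, names(newdata))
    if (length(miss)) {
      stop_named("raster stack missing model variable(s): %s",
                 paste(miss, collapse = ", "))
    }
    tab <- stack_table(newdata)
    ok <- !stack_nodata(newdata)
    out <- newdata[[1L]]
    out$values[] <- NA_real_
    out$values[ok] <- predict(object, tab[as.vector(ok), , drop = FALSE],
                              type = type, clamp = clamp)
    return(out)
  }
  X <- feature_design(object$features, newdata, clamp = clamp)
  eta <- as.vector(X %*% object$lambda)
  switch(type,
    link = eta,
    raw = if (is.null(weights)) {
      exp(eta) / object$Z
    } else {
      (weights / sum(weights)) * exp(eta) / object$Zw
    },
    logistic = {
      v <- exp(object$entropy) * exp(eta) / object$Z
      v / (1 + v)
    })
}

#' Permutation variable importance and jackknife gains
#'
#' Percent contribution is permutation importance: each variable's values
#' are permuted jointly across the presence and background tables (seeded),
#' features are re-evaluated, and the drop in training gain is recorded;
#' drops are floored at zero and normalized to sum to 100. The jackknife
#' refits the model with only / without each variable and reports the
#' training gains. Training gain of a model here is
#' `mean(eta at presences) - log(mean(exp(eta) over background))`, the
#' improvement in presence log-likelihood over a uniform distribution.
#'
#' @param model a [maxent_sdm()] fit.
#' @param presence,background the raw environment tables used in fitting.
#' @param nperm permutation replicates averaged per variable.
#' @param seed integer seed for the permutations.
#' @param jackknife also refit only-variable / without-variable models.
#' @return Data frame with `variable`, `contribution` (percent), and when
#'   `jackknife = TRUE`, `gain_only` and `gain_without`.
#' @export
variable_importance <- function(model, presence, background, nperm = 5,
                                seed = 1L, jackknife = TRUE) {
  stopifnot(inherits(model, "maxent_sdm"))
  presence <- as.matrix(presence); background <- as.matrix(background)
  vars <- model$features$vars
  gain <- function(Xp, Xb, lam) {
    mean(Xp %*% lam) - log(mean(exp(Xb %*% lam)))
  }
  Xp <- feature_design(model$features, presence)
  Xb <- feature_design(model$features, background)
  g0 <- gain(Xp, Xb, model$lambda)
  np <- nrow(presence)
  drops <- with_seed(seed, vapply(vars, function(v) {
    mean(vapply(seq_len(nperm), function(r) {
      comb <- c(presence[, v], background[, v])
      comb <- sample(comb)
      p2 <- presence; b2 <- background
      p2[, v] <- comb[seq_len(np)]
      b2[, v] <- comb[-seq_len(np)]
      g0 - gain(feature_design(model$features, p2),
                feature_design(model$features, b2), model$lambda)
    }, numeric(1L)))
  }, numeric(1L)))
  drops <- pmax(drops, 0)
  contribution <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(100 / length(vars), length(vars))
  out <- data.frame(variable = vars, contribution = unname(contribution))
  if (jackknife) {
    refit_gain <- function(keep) {
      m <- maxent_sdm(presence[, keep, drop = FALSE],
                      background[, keep, drop = FALSE],
                      classes = model$features$classes, beta = model$beta,
                      n_hinge_knots = model$features$n_hinge_knots,
                      control = list(tol = 1e-6, maxit = 5000))
      gain(feature_design(m$features, presence[, keep, drop = FALSE]),
           feature_design(m$features, background[, keep, drop = FALSE]),
           m$lambda)
    }
    out$gain_only <- vapply(vars, function(v) refit_gain(v), numeric(1L))
    out$gain_without <- if (length(vars) > 1L) {
      vapply(vars, function(v) refit_gain(setdiff(vars, v)), numeric(1L))
    } else NA_real_
  }
  out[order(-out$contribution), , drop = FALSE]
}

#' Marginal response curve of one variable
#'
#' Suitability as a function of one variable over its training range, all
#' other variables held at their background means, plus the number of
#' interior local maxima of the sampled curve (used to screen biologically
#' implausible, highly multimodal candidates).
#'
#' @param model a [maxent_sdm()] fit.
#' @param variable variable name.
#' @param n number of evaluation points (default 100).
#' @return Data frame `value`, `suitability`, with attribute
#'   `"interior_modes"`.
#' @export
response_curve <- function(model, variable, n = 100) {
  stopifnot(inherits(model, "maxent_sdm"))
  if (!variable %in% model$features$vars) {
    stop_named("unknown model variable '%s'", variable)
  }
  lo <- model$features$lower[variable]; hi <- model$features$upper[variable]
  grid <- seq(lo, hi, length.out = n)
  env <- matrix(rep(model$env_means, each = n), nrow = n,
                dimnames = list(NULL, model$features$vars))
  env[, variable] <- grid
  y <- predict(model, env, type = "logistic")
  out <- data.frame(value = grid, suitability = y)
  attr(out, "interior_modes") <- count_interior_modes(y)
  out
}

# number of interior local maxima of a sampled curve; flat runs collapse
# to a single point so plateaus count once
count_interior_modes <- function(y) {
  s <- sign(diff(y))
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-length(s)] == 1 & s[-1L] == -1)
}

#' @export
plot.maxent_sdm <- function(x, n = 100, ...) {
  vars <- x$features$vars
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    rc <- response_curve(x, v, n = n)
    graphics::plot(rc$value, rc$suitability, type = "l", xlab = v,
                   ylab = "suitability", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' AICc of a maximum-entropy model
#'
#' The log-likelihood is the sum over presences of the log raw probability
#' renormalized over the full landscape,
#' `lnL = sum(log(exp(eta_presence) / sum(exp(eta_landscape))))`, and the
#' parameter count `k` is the number of nonzero coefficients:
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `n` presences. Undefined
#' (`NA`) when `k >= n - 1`.
#'
#' @param model a [maxent_sdm()] fit.
#' @param presence raw presence environment table.
#' @param landscape raw environment table of the full landscape (all valid
#'   cells of the calibration extent).
#' @return List with `aicc`, `k`, `lnL`, `n`.
#' @export
aicc <- function(model, presence, landscape) {
  eta_l <- predict(model, landscape, type = "link")
  eta_p <- predict(model, presence, type = "link")
  amax <- max(eta_l)
  logZ <- amax + log(sum(exp(eta_l - amax)))
  lnL <- sum(eta_p - logZ)
  k <- sum(model$lambda != 0)
  n <- nrow(as.matrix(presence))
  val <- if (k >= n - 1L) NA_real_ else
    2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  list(aicc = val, k = k, lnL = lnL, n = n)
}

#' Rank candidate models by AICc
#'
#' Computes AICc for every candidate, drops candidates whose AICc is
#' undefined (`k >= n - 1`) or whose response curves exceed
#' `max_modes` interior local maxima on any variable (the multimodal-curve
#' sanity screen), and orders the rest by ascending AICc.
#'
#' @param models named list of [maxent_sdm()] fits.
#' @param presence,landscape as in [aicc()].
#' @param max_modes maximum allowed interior modes (default `Inf`).
#' @return Data frame with one row per candidate (`model`, `k`, `lnL`,
#'   `aicc`, `max_modes`, `excluded`, `rank`), ranked candidates first.
#' @export
rank_candidates <- function(models, presence, landscape, max_modes = Inf) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    a <- aicc(m, presence, landscape)
    modes <- max(vapply(m$features$vars, function(v) {
      attr(response_curve(m, v), "interior_modes")
    }, integer(1L)))
    data.frame(model = nm, k = a$k, lnL = a$lnL, aicc = a$aicc,
               max_modes = modes,
               excluded = is.na(a$aicc) || modes > max_modes)
  })
  out <- do.call(rbind, rows)
  if (all(out$excluded)) stop_named("all candidate models were excluded")
  out$rank <- NA_integer_
  ok <- which(!out$excluded)
  out$rank[ok][order(out$aicc[ok])] <- seq_along(ok)
  out[order(out$excluded, out$rank), , drop = FALSE]
}

#' Default candidate model grid
#'
#' Feature-class / regularization combinations used as the default
#' candidate set: linear+quadratic+hinge at beta 1.5,
#' linear+quadratic+product at beta 2.5, and all four classes at beta 2.5.
#'
#' @return Named list of `list(classes, beta)` settings.
#' @export
default_candidate_grid <- function() {
  list(lqh_b1.5 = list(classes = "lqh", beta = 1.5),
       lqp_b2.5 = list(classes = "lqp", beta = 2.5),
       lqph_b2.5 = list(classes = "lqph", beta = 2.5))
}

#' Fit a set of candidate models
#'
#' @param presence,background raw environment tables.
#' @param grid named list of `list(classes, beta)` (default
#'   [default_candidate_grid()]).
#' @param ... passed on to [maxent_sdm()].
#' @return Named list of `maxent_sdm` fits.
#' @export
maxent_candidates <- function(presence, background,
                              grid = default_candidate_grid(), ...) {
  out <- lapply(grid, function(g) {
    maxent_sdm(presence, background, classes = g$classes, beta = g$beta, ...)
  })
  names(out) <- names(grid)
  out
}
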