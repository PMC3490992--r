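## Statistical machinery: Mann-Whitney U, Pearson association, maximum-
## likelihood OLS and GLS with a Gaussian (squared-exponential) residual
## correlation, AICc ranking, Akaike weights, confidence sets and model
## averaging.

#' Mann-Whitney U test for two samples
#'
#' `U` is reported for the first sample: the number of pairs `(i, j)` with
#' `x[i] > y[j]` plus half the ties. The two-sided p-value uses the exact
#' null distribution (by the standard counting recursion) when there are no
#' ties and both samples have at most `exact_max` observations, otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples; `x` is the group whose U is reported.
#' @param exact_max largest per-group size for which the exact distribution
#'   is enumerated.
#' @return List with `U`, `p`, `method` (`"exact"` or `"normal"`), and the
#'   group sizes `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U  # complete separation: 0
#' @export
mann_whitney_u <- function(x, y, exact_max = 25L) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y)
  gt <- sum(outer(x, y, ">"))
  eq <- sum(outer(x, y, "=="))
  U <- gt + eq / 2
  pooled <- c(x, y)
  has_ties <- any(duplicated(pooled))
  if (!has_ties && nx <= exact_max && ny <= exact_max) {
    freq <- u_count_distribution(nx, ny)   # counts for U = 0..nx*ny
    tot <- sum(freq)
    lo <- sum(freq[seq_len(U + 1)]) / tot          # P(U <= u)
    hi <- sum(freq[(U + 1):length(freq)]) / tot    # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    N <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    if (U == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = p, method = method, n_x = nx, n_y = ny)
}

## Number of arrangements with each U value, by the counting recursion
## f(m, n, u) = f(m - 1, n, u - n) + f(m, n - 1, u); returned as the vector
## over u = 0..m*n for the requested (m, n).
u_count_distribution <- function(m, n) {
  umax <- m * n
  ## dp[[j]] holds counts for (i, j) as i grows
  prev <- matrix(0, nrow = umax + 1, ncol = n + 1)
  prev[1, ] <- 1                       # m = 0: only U = 0
  for (i in seq_len(m)) {
    cur <- matrix(0, nrow = umax + 1, ncol = n + 1)
    cur[1, 1] <- 1                     # n = 0: only U = 0
    for (j in seq_len(n)) {
      shifted <- c(rep(0, j), prev[seq_len(umax + 1 - j), j + 1])
      cur[, j + 1] <- shifted + cur[, j]
    }
    prev <- cur
  }
  prev[, n + 1]
}

#' Pearson correlation with domain checks
#'
#' @param x,y numeric vectors of equal length, n >= 3, nonzero variance.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Ordinary least squares fit by maximum likelihood
#'
#' Gaussian ML estimates: coefficients as in OLS, residual SD with
#' denominator `n` (so `loglik` is the maximized likelihood used in AICc).
#' Coefficient standard errors and p-values use the usual `n - p` residual
#' variance.
#'
#' @param y response vector.
#' @param X predictor matrix (columns named); an intercept is added.
#' @return A `fit_result`: coefficients, `sigma` (ML), `loglik`, `K`
#'   (coefficients + sigma), `n`, `aicc`, `r_squared`, `se`, `p_values`,
#'   `rho = NA`, `method = "ols"`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  if (n <= p + 1) stop("too few observations for the design", call. = FALSE)
  qrX <- qr(Xd)
  if (qrX$rank < p) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - Xd %*% beta
  rss <- sum(res^2)
  s2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi) + log(s2) + 1)
  K <- p + 1
  tss <- sum((y - mean(y))^2)
  s2_u <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- stats::setNames(sqrt(diag(XtXinv) * s2_u), colnames(Xd))
  tval <- beta / se
  pvals <- 2 * stats::pt(-abs(tval), df = n - p)
  structure(list(coefficients = beta, sigma = sqrt(s2), loglik = loglik,
                 K = K, n = n, aicc = aicc(loglik, K, n),
                 r_squared = 1 - rss / tss, se = se, p_values = pvals,
                 rho = NA_real_, converged = TRUE, method = "ols"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s> logLik %.4f, K %d, AICc %.4f%s\n", x$method,
              x$loglik, x$K, x$aicc,
              if (!is.na(x$rho)) sprintf(", rho %.4g", x$rho) else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

## Profile log-likelihood of the GLS model at correlation range rho:
## beta and sigma maximized analytically given the correlation matrix
## C_ij = exp(-(s_ij / rho)^2). Returns NA where C is not numerically PD.
gls_profile_loglik <- function(y, Xd, D, rho) {
  n <- length(y)
  C <- exp(-(D / rho)^2)
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = NA_real_))
  Ci <- chol2inv(L)
  XtCi <- crossprod(Xd, Ci)
  beta <- tryCatch(solve(XtCi %*% Xd, XtCi %*% y), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = NA_real_))
  res <- y - Xd %*% beta
  s2 <- as.numeric(crossprod(res, Ci %*% res)) / n
  if (!is.finite(s2) || s2 <= 0) return(list(loglik = NA_real_))
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(s2) - sum(log(diag(L))) - n / 2
  list(loglik = ll, beta = drop(beta), sigma = sqrt(s2))
}

#' Generalized least squares with Gaussian residual correlation, by ML
#'
#' Residuals of observations `i`, `j` are correlated as
#' `exp(-(s_ij / rho)^2)` where `s_ij` is the distance between their
#' `positions` (no nugget). `beta` and `sigma` are profiled analytically;
#' the range `rho` is maximized over a log-spaced multistart grid spanning
#' `[1e-4, 1e3] x` median pairwise distance, refined by golden-section
#' search, and compared against the `rho -> 0` (independent-errors) limit,
#' which equals the OLS fit.
#'
#' @param y response vector.
#' @param X predictor matrix (columns named); intercept added.
#' @param positions numeric matrix of coordinates over which the correlation
#'   decays, one row per observation.
#' @param metric distance between positions: `"euclidean"`, `"manhattan"` or
#'   `"maximum"` (Chebyshev).
#' @param rho fix the range instead of estimating it (used for limits and
#'   cross-checks).
#' @param n_grid multistart grid size for the range search.
#' @return A `fit_result` with `rho` (0 when the independent-errors limit
#'   wins), `K = coefficients + sigma + rho`, and `bound_warning = TRUE` when
#'   the optimum sits at the search boundary.
#' @export
gls_fit <- function(y, X, positions,
                    metric = c("euclidean", "manhattan", "maximum"),
                    rho = NULL, n_grid = 150L) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  K <- p + 2
  if (n <= K + 1) stop("too few observations for the design", call. = FALSE)
  positions <- as.matrix(positions)
  if (nrow(positions) != n)
    stop("`positions` must have one row per observation", call. = FALSE)
  D <- as.matrix(stats::dist(positions, method = metric))
  ols <- ols_fit(y, X)
  finish <- function(fit, rho_hat, bound) {
    structure(list(coefficients = fit$beta, sigma = fit$sigma,
                   loglik = fit$loglik, K = K, n = n,
                   aicc = aicc(fit$loglik, K, n), r_squared = ols$r_squared,
                   se = NULL, p_values = NULL, rho = rho_hat,
                   converged = TRUE, bound_warning = bound, method = "gls"),
              class = "fit_result")
  }
  if (!is.null(rho)) {
    fit <- gls_profile_loglik(y, Xd, D, rho)
    if (is.na(fit$loglik))
      stop("correlation matrix not positive definite at the given rho",
           call. = FALSE)
    return(finish(fit, rho, FALSE))
  }
  md <- stats::median(D[upper.tri(D)])
  if (!is.finite(md) || md <= 0)
    stop("degenerate positions: zero median pairwise distance", call. = FALSE)
  rhos <- md * 10^seq(-4, 3, length.out = n_grid)
  lls <- vapply(rhos, function(r) gls_profile_loglik(y, Xd, D, r)$loglik, 0.0)
  best <- if (all(is.na(lls))) NA_integer_ else which.max(lls)
  cand_ll <- ols$loglik
  cand_rho <- 0
  if (!is.na(best) && is.finite(lls[best])) {
    lo <- rhos[max(1L, best - 1L)]
    hi <- rhos[min(n_grid, best + 1L)]
    opt <- stats::optimize(function(lr) {
      v <- gls_profile_loglik(y, Xd, D, exp(lr))$loglik
      if (is.na(v)) -1e10 else v
    }, interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-10)
    if (opt$objective > lls[best]) {
      cand2_ll <- opt$objective; cand2_rho <- exp(opt$maximum)
    } else {
      cand2_ll <- lls[best]; cand2_rho <- rhos[best]
    }
    ## adopt the correlation only if it genuinely beats the independent-
    ## errors limit; a flat plateau at tiny rho IS that limit numerically
    if (cand2_ll > cand_ll + 1e-7) { cand_ll <- cand2_ll; cand_rho <- cand2_rho }
  }
  if (cand_rho == 0) {
    fit <- list(loglik = ols$loglik, beta = ols$coefficients, sigma = ols$sigma)
    return(finish(fit, 0, FALSE))
  }
  fit <- gls_profile_loglik(y, Xd, D, cand_rho)
  bound <- cand_rho >= rhos[n_grid] * 0.9999
  if (bound)
    warning("GLS range parameter at upper search boundary", call. = FALSE)
  finish(fit, cand_rho, bound)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param K parameter count (coefficients + residual SD + range parameter
#'   when a correlation structure is estimated).
#' @param n observations.
#' @return AICc value(s).
#' @examples
#' aicc(19.43, 3, 34)   # -32.06
#' @export
aicc <- function(loglik, K, n) {
  if (any(n - K - 1 <= 0))
    stop("AICc undefined: need n > K + 1", call. = FALSE)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`; interpretable as approximate model
#' selection probabilities.
#'
#' @param aiccs vector of AICc values.
#' @return Weights summing to 1, in the input order.
#' @export
akaike_weights <- function(aiccs) {
  if (!length(aiccs)) stop("need at least one AICc value", call. = FALSE)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' The five candidate models of tooth-row complexity
#'
#' Every candidate regresses one tooth row's log OPCR on the opposing row's
#' log OPCR; models 2-5 add measures of mandibular motion: (2) relative
#' lateral translation `rt`, (3) relative ventral rotational distance `rd`,
#' (4) both, (5) log sagittal occlusal angle `ln_a`.
#'
#' @param response `"upper"` or `"lower"`: which tooth row's complexity is
#'   modelled.
#' @return List of five model specs: `model` (number), `response`,
#'   `predictors` (character), `use_correlation` (TRUE for >= 2 predictors).
#' @export
candidate_models <- function(response = c("upper", "lower")) {
  response <- match.arg(response)
  resp_var <- if (response == "upper") "ln_upper" else "ln_lower"
  opp <- if (response == "upper") "ln_lower" else "ln_upper"
  extras <- list(character(0), "rt", "rd", c("rt", "rd"), "ln_a")
  lapply(seq_along(extras), function(i) {
    preds <- c(opp, extras[[i]])
    list(model = i, response = resp_var, predictors = preds,
         use_correlation = length(preds) >= 2)
  })
}

#' Fit and rank the candidate models of tooth-row complexity
#'
#' Fits the five candidates of [candidate_models()] — ML OLS for the single-
#' predictor model, ML GLS with Gaussian residual correlation for the rest —
#' ranks them by AICc and attaches delta AICc, Akaike weights and membership
#' of the smallest cumulative-weight >= `conf_level` confidence set.
#'
#' The correlation distance is measured, for every candidate of a response,
#' over one shared covariate space. The default (`"candidate_covariates"`)
#' uses all covariates appearing anywhere in the candidate set — opposing
#' log OPCR, `rt`, `rd`, `ln_a` — under the Chebyshev metric, so that AICc
#' differences between candidates reflect their mean structure rather than
#' differing error models. `"own_predictors"` instead uses each model's own
#' predictor space (Euclidean by default unless `metric` says otherwise).
#'
#' @param specimens a `specimen_table`; derived measures are added if absent.
#' @param response `"upper"` or `"lower"`.
#' @param correlation_space `"candidate_covariates"` (shared; default) or
#'   `"own_predictors"` (per-model).
#' @param metric distance metric for the Gaussian correlation; defaults to
#'   `"maximum"` for the shared space and `"euclidean"` for per-model spaces.
#' @param conf_level cumulative Akaike weight defining the confidence set.
#' @param n_grid multistart grid size for the GLS range search.
#' @return A `data.frame` of class `selection_table`, one row per model,
#'   sorted by AICc, with columns `model`, `intercept`, `opp_opcr`, `rt`,
#'   `rd`, `ln_a`, `df`, `logLik`, `AICc`, `delta_AICc`, `weight`,
#'   `in_conf_set`, `rho`. The full `fit_result`s are in `attr(, "fits")`.
#' @export
build_selection_table <- function(specimens, response = c("upper", "lower"),
                                  correlation_space = c("candidate_covariates",
                                                        "own_predictors"),
                                  metric = NULL, conf_level = 0.95,
                                  n_grid = 150L) {
  response <- match.arg(response)
  correlation_space <- match.arg(correlation_space)
  if (is.null(metric))
    metric <- if (correlation_space == "candidate_covariates") "maximum"
              else "euclidean"
  df <- as.data.frame(specimens)
  if (is.null(df$ln_upper)) df <- derive_measures(df)
  specs <- candidate_models(response)
  opp <- specs[[1]]$predictors[1]
  shared_pos <- as.matrix(df[, c(opp, "rt", "rd", "ln_a")])
  fits <- vector("list", length(specs))
  notes <- character(length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    y <- df[[sp$response]]
    X <- as.matrix(df[, sp$predictors, drop = FALSE])
    fits[[i]] <- tryCatch({
      if (!sp$use_correlation) ols_fit(y, X)
      else {
        pos <- if (correlation_space == "candidate_covariates") shared_pos
               else X
        gls_fit(y, X, positions = pos, metric = metric, n_grid = n_grid)
      }
    }, error = function(e) {
      notes[i] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no candidate model could be fitted", call. = FALSE)
  if (!all(ok))
    warning(sprintf("model(s) %s failed to fit and were dropped: %s",
                    paste(which(!ok), collapse = ", "),
                    paste(notes[!ok], collapse = "; ")), call. = FALSE)
  coef_of <- function(fit, name) {
    cf <- fit$coefficients
    if (name %in% names(cf)) unname(cf[name]) else NA_real_
  }
  rows <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    data.frame(model = specs[[i]]$model,
               intercept = unname(f$coefficients["(Intercept)"]),
               opp_opcr = coef_of(f, opp),
               rt = coef_of(f, "rt"), rd = coef_of(f, "rd"),
               ln_a = coef_of(f, "ln_a"),
               df = f$K, logLik = f$loglik, AICc = f$aicc,
               rho = f$rho)
  }))
  o <- order(rows$AICc)
  rows <- rows[o, ]
  rows$delta_AICc <- rows$AICc - min(rows$AICc)
  rows$weight <- akaike_weights(rows$AICc)
  cum <- cumsum(rows$weight)
  k <- which(cum >= conf_level)[1]
  rows$in_conf_set <- seq_len(nrow(rows)) <= k
  rownames(rows) <- NULL
  structure(rows,
            class = c("selection_table", "data.frame"),
            response = response, metric = metric,
            correlation_space = correlation_space,
            conf_level = conf_level, fits = fits[ok][o])
}

#' @export
print.selection_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model selection for %s tooth-row ln OPCR (correlation: %s over %s)\n",
              attr(x, "response"), attr(x, "metric"),
              attr(x, "correlation_space")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Model-averaged coefficients
#'
#' Akaike-weight-averaged coefficients over a scope of models, with weights
#' renormalized within the scope. Two conventions: `"natural"` averages each
#' term only over the models that contain it (renormalizing again per term);
#' `"zero"` substitutes 0 for a term absent from a model.
#'
#' @param table a `selection_table`.
#' @param scope `"confidence_set"` (default) or `"all"`.
#' @param method `"natural"` (default) or `"zero"`.
#' @return Named numeric vector of averaged coefficients.
#' @export
model_average <- function(table, scope = c("confidence_set", "all"),
                          method = c("natural", "zero")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  stopifnot(inherits(table, "selection_table"))
  rows <- as.data.frame(table)
  if (scope == "confidence_set") rows <- rows[rows$in_conf_set, ]
  if (!nrow(rows)) stop("empty model-averaging scope", call. = FALSE)
  w <- rows$weight / sum(rows$weight)
  terms <- c("intercept", "opp_opcr", "rt", "rd", "ln_a")
  out <- vapply(terms, function(tm) {
    cf <- rows[[tm]]
    if (all(is.na(cf))) return(NA_real_)
    if (method == "zero") {
      cf[is.na(cf)] <- 0
      sum(w * cf)
    } else {
      keep <- !is.na(cf)
      sum(w[keep] * cf[keep]) / sum(w[keep])
    }
  }, 0.0)
  out
}
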