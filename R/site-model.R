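#' Build the visit-duration modelling records
#'
#' Prepares the per-visit records for the site-preference mixed model:
#' response = visit duration transformed to log hours (default) or identity
#' hours, `site` as a factor (reference level first; default alphabetical,
#' which puts Alcyone first in the Cocos array), `tag_id` as the grouping
#' factor.
#'
#' @param visits Visit tibble (corrected tracks recommended; see
#'   [correct_cohort()]).
#' @param response `"log_hours"` (natural log of duration in hours) or
#'   `"hours"`.
#' @param include_transits Keep events shorter than the transit threshold
#'   (default `TRUE`: all residence events enter the model).
#' @param reference Reference site level; default the alphabetically first.
#' @return Tibble `tag_id`, `site` (factor), `response`.
#' @export
visit_records <- function(visits, response = c("log_hours", "hours"),
                          include_transits = TRUE, reference = NULL) {
  response <- match.arg(response)
  v <- visits
  if (!include_transits && "is_transit" %in% names(v)) {
    v <- v[!v$is_transit, , drop = FALSE]
  }
  hours <- v$duration_s / 3600
  y <- switch(response, log_hours = log(hours), hours = hours)
  if (response == "log_hours" && any(!is.finite(y))) {
    abort("zero-duration events cannot be log-transformed; drop them or use response = \"hours\"")
  }
  lev <- sort(unique(v$station_id))
  if (!is.null(reference)) lev <- c(reference, setdiff(lev, reference))
  tibble::tibble(tag_id = v$tag_id,
                 site = factor(v$station_id, levels = lev),
                 response = y)
}

#' Fit a random-intercept linear mixed model
#'
#' Fits y = X beta + Z b + e with b ~ N(0, sigma2_g I) per group (one random
#' intercept per animal) and e ~ N(0, sigma2_r I), by profiling: for a given
#' variance ratio lambda = sigma2_g / sigma2_r the GLS estimate of beta and
#' the residual variance have closed forms (the marginal covariance is block
#' diagonal, V_i = I + lambda J), so the (restricted) log-likelihood is
#' maximized by a one-dimensional bounded search over lambda >= 0. The
#' boundary lambda = 0 (no between-animal variance) reduces to ordinary
#' least squares and is always compared against the interior optimum.
#'
#' @param records Tibble with `response` (numeric), `site` (factor fixed
#'   effect; an intercept-only model is fitted when `site` is absent or has
#'   one level) and `tag_id` (grouping factor).
#' @param criterion `"REML"` (default; reported variance components) or
#'   `"ML"` (required for likelihood-ratio tests between fixed-effect
#'   structures).
#' @return An object of class `lmm_fit`: coefficients (reference-level
#'   coding), variance components, standard errors, Satterthwaite degrees
#'   of freedom, log-likelihood.
#' @seealso [lrt_site_effect()], [pairwise_site_contrasts()],
#'   [tidy.lmm_fit()], [glance.lmm_fit()]
#' @export
fit_lmm <- function(records, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  y <- records$response
  g <- factor(records$tag_id)
  if (nlevels(g) < 2) abort("need >= 2 groups (tags)")
  has_site <- "site" %in% names(records) && nlevels(droplevels(factor(records$site))) > 1
  X <- if (has_site) {
    stats::model.matrix(~ site, data = data.frame(site = droplevels(factor(records$site))))
  } else {
    matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  if (qr(X)$rank < ncol(X)) abort("singular fixed-effect design")

  prof <- make_profiler(y, X, g, criterion)
  ## optimum over lambda >= 0: log-scale interior search + explicit boundary
  opt <- optimize(function(u) -prof(exp(u))$loglik, interval = c(-12, 12),
                  tol = 1e-9)
  interior <- prof(exp(opt$minimum))
  boundary <- prof(0)
  ## prefer the boundary under a flat or boundary-optimal likelihood
  fit <- if (boundary$loglik >= interior$loglik - 1e-8) boundary else interior

  vb <- fit$sigma2_r * fit$XtViX_inv
  se <- sqrt(diag(vb))
  sat <- satterthwaite_df(y, X, g, fit$sigma2_g, fit$sigma2_r, criterion,
                          diag(ncol(X)))

  structure(list(
    beta = stats::setNames(drop(fit$beta), colnames(X)),
    se_beta = stats::setNames(se, colnames(X)),
    satterthwaite_df = stats::setNames(sat, colnames(X)),
    sigma2_group = fit$sigma2_g, sigma2_resid = fit$sigma2_r,
    lambda = fit$lambda, loglik = fit$loglik, criterion = criterion,
    vcov_beta = vb, n = length(y), n_groups = nlevels(g), p = ncol(X),
    site_levels = if (has_site) levels(droplevels(factor(records$site))) else NULL,
    y = y, X = X, group = g
  ), class = "lmm_fit")
}

## Profiled (restricted) log-likelihood machinery. For V = I + lambda Z Z'
## with Z the group indicator, V is block diagonal with
## V_i^{-1} = I - (lambda / (1 + lambda n_i)) J, so all GLS quantities
## reduce to per-group sums.
make_profiler <- function(y, X, g, criterion) {
  n <- length(y); p <- ncol(X)
  idx <- split(seq_len(n), g)
  ni <- lengths(idx)
  Xg <- lapply(idx, function(i) colSums(X[i, , drop = FALSE]))  # X_i' 1
  yg <- vapply(idx, function(i) sum(y[i]), numeric(1))          # y_i' 1
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  XgM <- do.call(rbind, Xg)

  function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    XtViX <- XtX - crossprod(XgM * sqrt(ci))
    XtViy <- Xty - colSums(XgM * (ci * yg))
    ytViy <- yty - sum(ci * yg^2)
    XtViX_inv <- solve(XtViX)
    beta <- XtViX_inv %*% XtViy
    rss <- ytViy - 2 * sum(beta * XtViy) + drop(crossprod(beta, XtViX %*% beta))
    rss <- max(rss, .Machine$double.eps)
    logdetV <- sum(log1p(lambda * ni))
    if (criterion == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + logdetV + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetV +
                      determinant(XtViX, logarithm = TRUE)$modulus + (n - p))
    }
    list(lambda = lambda, beta = beta, sigma2_r = s2, sigma2_g = lambda * s2,
         loglik = as.numeric(ll), XtViX_inv = XtViX_inv)
  }
}

## Satterthwaite df for contrasts L beta (rows of L): df = 2 v^2 / (grad' A grad)
## with v = Var(l' beta_hat) as a function of theta = (sigma2_g, sigma2_r),
## grad its numeric gradient at theta_hat, and A the inverse observed
## information of the REML/ML log-likelihood in theta.
satterthwaite_df <- function(y, X, g, sigma2_g, sigma2_r, criterion, L) {
  theta <- c(sigma2_g, sigma2_r)
  idx <- split(seq_along(y), g)
  ni <- lengths(idx)
  XgM <- do.call(rbind, lapply(idx, function(i) colSums(X[i, , drop = FALSE])))
  XtX <- crossprod(X)

  covbeta <- function(th) {
    lam <- th[1] / th[2]
    ci <- lam / (1 + lam * ni)
    th[2] * solve(XtX - crossprod(XgM * sqrt(ci)))
  }
  prof <- make_profiler(y, X, g, criterion)
  ll_theta <- function(th) {
    ## exact (restricted) loglik at arbitrary theta, beta profiled/removed
    lam <- th[1] / th[2]
    pr <- prof(lam)
    n <- length(y); p <- ncol(X)
    ## residual sum of squares under V_lambda at the GLS beta for lam
    rss <- if (criterion == "ML") pr$sigma2_r * n else pr$sigma2_r * (n - p)
    logdetV <- sum(log1p(lam * ni))
    if (criterion == "ML") {
      -0.5 * (n * log(2 * pi * th[2]) + logdetV + rss / th[2])
    } else {
      XtViX <- XtX - crossprod(XgM * sqrt(lam / (1 + lam * ni)))
      -0.5 * ((n - p) * log(2 * pi * th[2]) + logdetV + rss / th[2] +
                as.numeric(determinant(XtViX, logarithm = TRUE)$modulus))
    }
  }

  h <- pmax(1e-5, abs(theta) * 1e-4)
  grad_v <- function(lvec) {
    vapply(1:2, function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], 1e-10)
      vp <- drop(lvec %*% covbeta(tp) %*% lvec)
      vm <- drop(lvec %*% covbeta(tm) %*% lvec)
      (vp - vm) / (tp[k] - tm[k])
    }, numeric(1))
  }
  H <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    ta <- theta; ta[a] <- ta[a] + h[a]; ta[b] <- ta[b] + h[b]
    tb <- theta; tb[a] <- tb[a] + h[a]; tb[b] <- max(tb[b] - h[b], 1e-10)
    tc <- theta; tc[a] <- max(tc[a] - h[a], 1e-10); tc[b] <- tc[b] + h[b]
    td <- theta; td[a] <- max(td[a] - h[a], 1e-10); td[b] <- max(td[b] - h[b], 1e-10)
    H[a, b] <- (ll_theta(ta) - ll_theta(tb) - ll_theta(tc) + ll_theta(td)) /
      ((ta[a] - tc[a]) * (ta[b] - tb[b]))
  }
  A <- tryCatch(solve(-H), error = function(e) NULL)
  apply(L, 1, function(lvec) {
    v <- drop(lvec %*% covbeta(theta) %*% lvec)
    if (is.null(A)) return(NA_real_)  # normal-approximation fallback
    gr <- grad_v(lvec)
    den <- drop(t(gr) %*% A %*% gr)
    if (!is.finite(den) || den <= 0) return(NA_real_)
    2 * v^2 / den
  })
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (", x$criterion, ")\n", sep = "")
  cat(sprintf("  groups: %d   observations: %d\n", x$n_groups, x$n))
  cat(sprintf("  Random effects: group (intercept) var %.4f (sd %.4f); residual var %.4f (sd %.4f)\n",
              x$sigma2_group, sqrt(x$sigma2_group),
              x$sigma2_resid, sqrt(x$sigma2_resid)))
  cat("  Fixed effects:\n")
  print(tidy(x, effects = "fixed"), ...)
  invisible(x)
}

#' Tidy a random-intercept mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param effects `"fixed"`, `"ran_pars"` or both (default).
#' @param ... Unused.
#' @return Tibble in broom.mixed layout: `effect`, `term`, `estimate`,
#'   and for fixed effects `std.error`, `df` (Satterthwaite), `statistic`,
#'   `p.value`.
#' @export
tidy.lmm_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    tval <- x$beta / x$se_beta
    out$fixed <- tibble::tibble(
      effect = "fixed", term = names(x$beta), estimate = unname(x$beta),
      std.error = unname(x$se_beta), df = unname(x$satterthwaite_df),
      statistic = unname(tval),
      p.value = ifelse(is.na(x$satterthwaite_df),
                       2 * stats::pnorm(-abs(tval)),
                       2 * pt(-abs(tval), x$satterthwaite_df)))
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble::tibble(
      effect = "ran_pars",
      term = c("var__(Intercept)|group", "var__Residual"),
      estimate = c(x$sigma2_group, x$sigma2_resid),
      std.error = NA_real_, df = NA_real_, statistic = NA_real_,
      p.value = NA_real_)
  }
  dplyr::bind_rows(out)
}

#' One-row summary of an `lmm_fit`
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return Tibble: `nobs`, `n_groups`, `sigma2_group`, `sigma2_resid`,
#'   `logLik`, `criterion`, `df` (number of fixed effects).
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_groups = x$n_groups,
                 sigma2_group = x$sigma2_group, sigma2_resid = x$sigma2_resid,
                 logLik = x$loglik, criterion = x$criterion, df = x$p)
}

#' Likelihood-ratio test for the site effect
#'
#' Compares the intercept-only null against the model with site fixed
#' effects. Both fits must use maximum likelihood on identical records:
#' REML log-likelihoods are not comparable across fixed-effect structures.
#'
#' @param null_fit,full_fit `lmm_fit` objects fitted with
#'   `criterion = "ML"` on the same records.
#' @return Tibble `chi2`, `df`, `p.value`.
#' @export
lrt_site_effect <- function(null_fit, full_fit) {
  if (null_fit$criterion != "ML" || full_fit$criterion != "ML") {
    abort("both fits must use criterion = \"ML\" for a likelihood-ratio test")
  }
  if (null_fit$n != full_fit$n) abort("fits must use identical records")
  chi2 <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  df <- full_fit$p - null_fit$p
  tibble::tibble(chi2 = chi2, df = df,
                 p.value = if (df == 0) 1 else
                   pchisq(chi2, df, lower.tail = FALSE))
}

#' Pairwise site contrasts
#'
#' Wald tests of all unordered pairs of site means, using the fixed-effect
#' covariance of the fit, Satterthwaite degrees of freedom per contrast and
#' a Holm adjustment over the family of pairs.
#'
#' @param fit Full `lmm_fit` with site effects.
#' @return Tibble: `site_i`, `site_j`, `estimate` (mean_i - mean_j), `se`,
#'   `df`, `statistic`, `p.value`, `p.adjusted`.
#' @export
pairwise_site_contrasts <- function(fit) {
  if (is.null(fit$site_levels)) abort("fit has no site fixed effect")
  lev <- fit$site_levels
  k <- length(lev); p <- fit$p
  ## site mean vector in coefficient space: reference mean = intercept,
  ## others = intercept + beta_site; contrast i-j removes the intercept.
  coef_of <- function(site) {
    v <- numeric(p)
    j <- match(site, lev)
    if (j > 1) v[j] <- 1  # model.matrix ordering: (Intercept), site2..siteK
    v
  }
  pairs <- utils::combn(lev, 2)
  L <- t(apply(pairs, 2, function(pr) coef_of(pr[1]) - coef_of(pr[2])))
  est <- drop(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov_beta %*% t(L)))
  df <- satterthwaite_df(fit$y, fit$X, fit$group, fit$sigma2_group,
                         fit$sigma2_resid, fit$criterion, L)
  stat <- est / se
  pval <- ifelse(is.na(df), 2 * stats::pnorm(-abs(stat)),
                 2 * pt(-abs(stat), df))
  tibble::tibble(site_i = pairs[1, ], site_j = pairs[2, ], estimate = est,
                 se = se, df = df, statistic = stat, p.value = pval,
                 p.adjusted = p.adjust(pval, method = "holm"))
}
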