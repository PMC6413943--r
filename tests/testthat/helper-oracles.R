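# Independent reference implementations used as oracles. These replay the
# rule definitions with different bookkeeping from the package code
# (history recomputation instead of carried state), so agreement is a
# genuine dual-route check.

# Brute-force residence-event segmentation. Membership-based recomputation:
# a station's candidate run at step j is the gap-valid suffix of its
# non-member detections since the most recent event-member detection at a
# different station.
oracle_segment <- function(det, min_pings = 2L, timeout = 900,
                           other = 2L) {
  t <- as.numeric(det$timestamp)
  s <- det$station_id
  n <- length(t)
  member <- logical(n)
  open <- NULL
  res <- list()
  close_ev <- function(reason) {
    res[[length(res) + 1L]] <<- data.frame(
      station_id = open$st, start = t[open$first], end = t[open$last],
      n_detections = open$n, termination_reason = reason,
      stringsAsFactors = FALSE)
    open <<- NULL
  }
  run_of <- function(x, j) {
    pre <- seq_len(j)
    mem <- which(member[pre] & s[pre] != x)
    rx <- if (length(mem)) max(mem) else 0L
    xs <- which(s[pre] == x)
    xs <- xs[xs > rx & !member[xs]]
    if (length(xs) == 0) return(integer(0))
    br <- which(diff(t[xs]) > timeout)
    if (length(br)) xs <- xs[(max(br) + 1L):length(xs)]
    xs
  }
  for (j in seq_len(n)) {
    if (!is.null(open) && t[j] - t[open$last] > timeout) close_ev("timeout")
    if (!is.null(open) && s[j] == open$st) {
      open$last <- j
      open$n <- open$n + 1L
      member[j] <- TRUE
      next
    }
    r <- run_of(s[j], j)
    if (!is.null(open)) {
      if (length(r) >= other) {
        close_ev("other_station")
        if (length(r) >= min_pings) {
          open <- list(st = s[j], first = r[1], last = j, n = length(r))
          member[r] <- TRUE
        }
      }
    } else if (length(r) >= min_pings) {
      open <- list(st = s[j], first = r[1], last = j, n = length(r))
      member[r] <- TRUE
    }
  }
  if (!is.null(open)) close_ev("stream_end")
  if (length(res) == 0) {
    return(data.frame(station_id = character(), start = numeric(),
                      end = numeric(), n_detections = integer(),
                      termination_reason = character()))
  }
  do.call(rbind, res)
}

# Brute-force tagging-bias correction: evaluate both trigger rules on every
# visit and take the earliest.
oracle_bias_correction <- function(visits, tag_station, absence_h = 24) {
  n <- nrow(visits)
  trigger <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (visits$station_id[k] != tag_station) {
      trigger[k] <- as.numeric(visits$start[k])   # rule (a)
    } else {
      prev <- which(visits$station_id[seq_len(k - 1)] == tag_station)
      if (length(prev) > 0) {
        gap <- as.numeric(visits$start[k]) - as.numeric(visits$end[max(prev)])
        if (gap >= absence_h * 3600) trigger[k] <- as.numeric(visits$start[k])
      }
    }
  }
  if (all(is.na(trigger))) {
    return(list(rule = "none_applicable", start = NA_real_,
                kept = visits[0, , drop = FALSE]))
  }
  k0 <- which.min(trigger)
  rule <- if (visits$station_id[k0] != tag_station) "other_site_first"
          else "absent_24h"
  start <- trigger[k0]
  list(rule = rule, start = start,
       kept = visits[as.numeric(visits$start) >= start, , drop = FALSE])
}

# Exact marginal log-likelihood of the random-intercept model via dense
# per-group covariance matrices (no profiling): the oracle for fit_lmm.
oracle_lmm_loglik <- function(beta, s2g, s2r, y, X, g) {
  ll <- 0
  for (gr in split(seq_along(y), g)) {
    ni <- length(gr)
    V <- diag(s2r, ni) + matrix(s2g, ni, ni)
    r <- y[gr] - X[gr, , drop = FALSE] %*% beta
    ll <- ll - 0.5 * (ni * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        drop(t(r) %*% solve(V, r)))
  }
  ll
}

# Direct numerical maximization of the exact likelihood over
# (beta, log s2g, log s2r), multi-start.
oracle_lmm_ml <- function(y, X, g) {
  nll <- function(par) {
    p <- ncol(X)
    -oracle_lmm_loglik(par[1:p], exp(par[p + 1]), exp(par[p + 2]), y, X, g)
  }
  ols <- qr.solve(X, y)
  s2 <- mean((y - X %*% ols)^2)
  best <- NULL
  for (start_g in c(0.05, 0.3, 1)) {
    par0 <- c(ols, log(start_g * s2), log(s2))
    o <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- ncol(X)
  list(beta = best$par[1:p], sigma2_group = exp(best$par[p + 1]),
       sigma2_resid = exp(best$par[p + 2]), loglik = -best$value)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm), degrees.
rvonmises_deg <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  ((out * 180 / pi) + mu_deg) %% 360
}

# Random detection stream generator for fuzzing the segmentation.
random_stream <- function(n_det, n_stations = 3, mean_gap = 400,
                          t0 = as.POSIXct("2012-06-01", tz = "UTC")) {
  gaps <- rexp(n_det, 1 / mean_gap)
  tibble::tibble(
    tag_id = "tag1",
    station_id = sample(LETTERS[seq_len(n_stations)], n_det, replace = TRUE),
    timestamp = t0 + cumsum(gaps))
}

# Visit-records generator for the dwell-time mixed model (the generator's
# lognormal dwell submodel, producing records directly).
simulate_visit_records <- function(n_groups = 17, site_mu, sigma2_g, sigma2_r,
                                   records_per_group = 120) {
  sites <- names(site_mu)
  recs <- lapply(seq_len(n_groups), function(k) {
    b <- rnorm(1, 0, sqrt(sigma2_g))
    s <- sample(sites, records_per_group, replace = TRUE)
    tibble::tibble(tag_id = sprintf("g%02d", k),
                   site = s,
                   response = site_mu[s] + b +
                     rnorm(records_per_group, 0, sqrt(sigma2_r)))
  })
  out <- dplyr::bind_rows(recs)
  out$site <- factor(out$site, levels = sites)
  out
}

# Cocos site means on the log-hour scale (intercept + site offsets).
table1_site_mu <- function() {
  c(alcyone = 1.22804,
    canal = 1.22804 - 1.46012,
    dos_amigos = 1.22804 - 0.48049,
    lobster = 1.22804 - 2.15042,
    manuelita = 1.22804 - 0.77533,
    roca_sucia = 1.22804 - 0.46899)
}

# Quick builder for canonical detection tibbles in tests.
make_det <- function(stations_vec, offsets_s, tag = "t1",
                     t0 = as.POSIXct("2012-01-01 12:00:00", tz = "UTC")) {
  tibble::tibble(tag_id = tag, station_id = stations_vec,
                 timestamp = t0 + offsets_s)
}

# Builder for visit tibbles (start/end in hours from an origin).
make_visits <- function(stations_vec, start_h, dur_h, tag = "t1",
                        t0 = as.POSIXct("2012-01-01", tz = "UTC")) {
  tibble::tibble(tag_id = tag, station_id = stations_vec,
                 start = t0 + start_h * 3600,
                 end = t0 + (start_h + dur_h) * 3600,
                 duration_s = dur_h * 3600,
                 is_transit = dur_h * 3600 < 900)
}
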