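## DFE fitting engine: Poisson maximum likelihood on synonymous and
## nonsynonymous site frequency spectra under a parametric distribution of
## fitness effects (DFE), model comparison by AIC, and decomposition of the
## substitution rate omega = (Dn/Ln)/(Ds/Ls) into its non-adaptive
## (omega_na) and adaptive (omega_a = omega - omega_na) components.
##
## Families: Neutral (all nonsynonymous mutations neutral), Gamma (deleterious
## scaled coefficients -S ~ Gamma), GammaExpo (Gamma deleterious component
## mixed with an exponential distribution of beneficial coefficients with
## weight p_b).  Scaled coefficients are S = 4 Ne s.

DFE_FAMILIES <- c("Neutral", "Gamma", "GammaExpo")

.adaptrate_cache <- new.env(parent = emptyenv())

#' DFE model parameters
#'
#' @param family one of `"Neutral"`, `"Gamma"`, `"GammaExpo"`.
#' @param theta population mutation rate per site (scales the SFS).
#' @param shape Gamma shape of the deleterious component (> 0).
#' @param mean_del mean magnitude of the deleterious scaled coefficient,
#'   `E[-S] > 0`.
#' @param p_b proportion of new nonsynonymous mutations that are beneficial
#'   (in `[0, 0.5]`; forced to 0 for the Gamma family).
#' @param mean_ben mean beneficial scaled coefficient (> 0).
#' @param eps ancestral misidentification probability in `[0, 0.5]`; 0
#'   disables polarization-error mixing.
#' @param r optional nuisance multipliers for frequency classes `2..n-1`
#'   (`r_1` is fixed to 1); `NULL` disables them.
#' @return An object of class `dfe_params`.
#' @export
#' @examples
#' dfe_params("GammaExpo", theta = 0.01, shape = 0.3, mean_del = 2000,
#'            p_b = 0.005, mean_ben = 10)
dfe_params <- function(family = c("GammaExpo", "Gamma", "Neutral"),
                       theta = NA_real_, shape = NA_real_,
                       mean_del = NA_real_, p_b = 0, mean_ben = NA_real_,
                       eps = 0, r = NULL) {
  family <- match.arg(family)
  if (family == "Neutral") {
    shape <- NA_real_; mean_del <- NA_real_; p_b <- 0; mean_ben <- NA_real_
  }
  if (family == "Gamma") { p_b <- 0; mean_ben <- NA_real_ }
  if (family %in% c("Gamma", "GammaExpo")) {
    if (!is.na(shape) && shape <= 0) stop("'shape' must be > 0")
    if (!is.na(mean_del) && mean_del <= 0) stop("'mean_del' must be > 0")
  }
  if (p_b < 0 || p_b > 0.5) stop("'p_b' must lie in [0, 0.5]")
  if (eps < 0 || eps > 0.5) stop("'eps' must lie in [0, 0.5]")
  if (family == "GammaExpo" && p_b > 0 && !is.na(mean_ben) && mean_ben <= 0)
    stop("'mean_ben' must be > 0")
  structure(list(family = family, theta = theta, shape = shape,
                 mean_del = mean_del, p_b = p_b, mean_ben = mean_ben,
                 eps = eps, r = r),
            class = "dfe_params")
}

#' @export
print.dfe_params <- function(x, ...) {
  cat(sprintf("DFE parameters [%s]\n", x$family))
  flds <- c("theta", "shape", "mean_del", "p_b", "mean_ben", "eps")
  for (f in flds)
    if (!is.na(x[[f]]) && !(f %in% c("p_b", "eps") && x[[f]] == 0))
      cat(sprintf("  %-9s %g\n", f, x[[f]]))
  if (!is.null(x$r)) cat("  r multipliers enabled\n")
  invisible(x)
}

#' Relative fixation probability of a mutation with scaled coefficient S
#'
#' `Q(S) = S / (1 - exp(-S))`, the fixation probability relative to a
#' neutral mutation; `Q(0) = 1` by continuity.  Evaluated stably for large
#' `|S|` (`Q -> 0` as `S -> -Inf`, `Q -> S` as `S -> +Inf`).
#'
#' @param S numeric vector of scaled selection coefficients (`4 Ne s`).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' fixation_ratio(c(-10, 0, 2))
fixation_ratio <- function(S) {
  out <- numeric(length(S))
  tiny <- abs(S) < 1e-8
  out[tiny] <- 1
  pos <- !tiny & S > 0
  out[pos] <- S[pos] / (-expm1(-S[pos]))
  neg <- !tiny & S < 0
  ## S/(1-e^{-S}) with S = -T:  T/(e^T - 1)
  Tn <- -S[neg]
  out[neg] <- Tn / expm1(Tn)
  out[!is.finite(out)] <- 0      # expm1 overflow at very negative S
  out
}

#' Diffusion sojourn density weight
#'
#' Expected time a new semidominant mutation with scaled coefficient `S`
#' spends at population frequency `x`, relative to the mutational influx:
#' `h(x; S) = (1 - exp(-S (1 - x))) / ((1 - exp(-S)) x (1 - x))`, with the
#' neutral limit `h(x; 0) = 1/x`.  Evaluated in expm1/log form, stable for
#' `|S|` up to 1e4.
#'
#' @param x population frequency, in the open interval (0, 1); vectorized.
#' @param S scalar scaled selection coefficient.
#' @return Numeric vector of weights.
#' @export
#' @examples
#' sojourn_weight(0.5, 0)   # 2
#' sojourn_weight(0.5, 1)   # about 2.4899
sojourn_weight <- function(x, S) {
  if (any(x <= 0 | x >= 1)) stop("'x' must lie strictly inside (0, 1)")
  if (length(S) != 1L) stop("'S' must be a scalar")
  if (abs(S) < 1e-8) return(1 / x)
  if (S > 0) {
    (-expm1(-S * (1 - x))) / ((-expm1(-S)) * x * (1 - x))
  } else {
    Tn <- -S
    exp(-Tn * x) * (-expm1(-Tn * (1 - x))) /
      ((-expm1(-Tn)) * x * (1 - x))
  }
}

## Gauss-Legendre nodes/weights on (0, 1), cached.
gl_nodes <- function(nquad = 128L) {
  key <- paste0("gl", nquad)
  if (is.null(.adaptrate_cache[[key]])) {
    g <- pracma::gaussLegendre(nquad, 0, 1)
    .adaptrate_cache[[key]] <- list(x = g$x, w = g$w)
  }
  .adaptrate_cache[[key]]
}

#' Expected SFS contribution of selection class S at derived count i
#'
#' `G(S, i, n) = integral over x of C(n,i) x^i (1-x)^(n-i) h(x; S) dx`,
#' the binomial-sampling weight of the sojourn density: the expected number
#' of polymorphic sites (per unit mutational influx) observed with `i`
#' derived copies in a sample of `n` chromosomes.  `G(0, i, n) = 1/i`.
#' Evaluated by fixed-node Gauss-Legendre quadrature.
#'
#' @param S scalar scaled selection coefficient.
#' @param i derived-count class, `1 <= i <= n-1`; vectorized.
#' @param n sample size.
#' @param nquad number of quadrature nodes.
#' @return Numeric vector over `i`.
#' @export
#' @examples
#' sfs_weight(0, 1:9, 10)   # 1/(1:9)
sfs_weight <- function(S, i, n, nquad = 128L) {
  if (any(i < 1L | i > n - 1L)) stop("'i' must lie in 1..n-1")
  g <- gl_nodes(nquad)
  h <- sojourn_weight(g$x, S)
  out <- vapply(i, function(ii) {
    sum(exp(lchoose(n, ii) + ii * log(g$x) + (n - ii) * log1p(-g$x)) *
          h * g$w)
  }, numeric(1))
  if (any(!is.finite(out)))
    stop(sprintf("non-finite SFS weight at S=%g, n=%d", S, n))
  out
}

## Precomputed quadrature tables for a sample size n:
##  - X: log-spaced grid of coefficient magnitudes, tw: integration weights
##  - Gdel/Gben: (n-1) x ngrid matrices of G(-X, i, n) / G(+X, i, n)
##  - Qdel/Qben: fixation ratios Q(-X) / Q(+X)
## The grid is fixed, so these are computed once per n and reused across all
## likelihood evaluations; only the DFE density weights change during a fit.
dfe_tables <- function(n, nquad = 128L, ngrid = 400L,
                       smin = 1e-4, smax = 1e5) {
  key <- sprintf("tab_%d_%d_%d", n, nquad, ngrid)
  tab <- .adaptrate_cache[[key]]
  if (!is.null(tab)) return(tab)
  g <- gl_nodes(nquad)
  u <- seq(log(smin), log(smax), length.out = ngrid)
  X <- exp(u)
  tw <- X * (u[2L] - u[1L])            # du-substitution trapezoid weights
  tw[c(1L, ngrid)] <- tw[c(1L, ngrid)] / 2
  i <- seq_len(n - 1L)
  B <- exp(outer(i, log(g$x)) + outer(n - i, log1p(-g$x)) + lchoose(n, i))
  B <- sweep(B, 2L, g$w, `*`)          # (n-1) x nquad binomial-sampling weights
  Hdel <- t(vapply(X, function(s) sojourn_weight(g$x, -s), numeric(nquad)))
  Hben <- t(vapply(X, function(s) sojourn_weight(g$x, s), numeric(nquad)))
  tab <- list(X = X, tw = tw, logX = log(X), log_tw = log(tw),
              Gdel = B %*% t(Hdel), Gben = B %*% t(Hben),
              Qdel = fixation_ratio(-X), Qben = fixation_ratio(X))
  .adaptrate_cache[[key]] <- tab
  tab
}

## Normalized integration weights of the deleterious Gamma component over the
## magnitude grid (a proper expectation: below/above-grid mass, if any, is
## redistributed proportionally).
gamma_weights <- function(tab, shape, mean_del) {
  ## Gamma log-density expanded over the fixed grid (log X precomputed)
  rate <- shape / mean_del
  lw <- shape * log(rate) - lgamma(shape) + (shape - 1) * tab$logX -
    rate * tab$X + tab$log_tw
  w <- exp(lw - max(lw))
  s <- sum(w)
  if (!is.finite(s) || s <= 0) return(NULL)
  w / s
}

expo_weights <- function(tab, mean_ben) {
  w <- exp(-tab$X / mean_ben + tab$log_tw)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) return(NULL)
  w / s
}

## Mean G(S, i, n) over the DFE of params, as a vector over i = 1..n-1.
## Returns NULL on degenerate parameter values.
mean_sfs_weight <- function(params, tab) {
  n1 <- nrow(tab$Gdel)
  if (params$family == "Neutral") return(1 / seq_len(n1))
  wd <- gamma_weights(tab, params$shape, params$mean_del)
  if (is.null(wd)) return(NULL)
  I <- drop(tab$Gdel %*% wd)
  if (params$family == "GammaExpo" && params$p_b > 0) {
    wb <- expo_weights(tab, params$mean_ben)
    if (is.null(wb)) return(NULL)
    I <- (1 - params$p_b) * I + params$p_b * drop(tab$Gben %*% wb)
  }
  I
}

apply_eps <- function(e, eps) {
  if (eps <= 0) return(e)
  (1 - eps) * e + eps * rev(e)   # class i mixed with class n-i
}

fold_vector <- function(u) {
  n <- length(u) + 1L
  f <- numeric(n - 1L)
  half <- floor(n / 2)
  for (i in seq_len(half)) f[i] <- if (i < n - i) u[i] + u[n - i] else u[i]
  f
}

#' Expected site frequency spectra under a DFE model
#'
#' Expected Poisson means of the synonymous and nonsynonymous SFS:
#' `E[s_i] = r_i theta Ls / i` and
#' `E[x_i] = r_i theta Ln * E_f[G(S, i, n)]`, where the expectation is over
#' the family's density of scaled coefficients (Gamma on `-S`, mixed with an
#' exponential on `+S` with weight `p_b` for GammaExpo).  With `eps > 0`,
#' class `i` is mixed with class `n - i`.
#'
#' @param params a [dfe_params()] with `theta` set.
#' @param n sample size in chromosomes.
#' @param Ls,Ln synonymous / nonsynonymous site opportunities.
#' @param folded if `TRUE`, expected spectra are folded.
#' @return A list with components `e_syn` and `e_nonsyn` (length `n - 1`).
#' @export
#' @examples
#' expected_spectrum(dfe_params("Neutral", theta = 0.01), 10, 1000, 3000)
expected_spectrum <- function(params, n, Ls, Ln, folded = FALSE) {
  stopifnot(inherits(params, "dfe_params"), !is.na(params$theta))
  tab <- dfe_tables(n)
  i <- seq_len(n - 1L)
  I <- mean_sfs_weight(params, tab)
  if (is.null(I)) stop("degenerate DFE parameters (divergent density)")
  r <- if (is.null(params$r)) rep(1, n - 1L) else c(1, params$r)
  e_syn <- r * params$theta * Ls / i
  e_nonsyn <- r * params$theta * Ln * I
  e_syn <- apply_eps(e_syn, params$eps)
  e_nonsyn <- apply_eps(e_nonsyn, params$eps)
  if (folded) { e_syn <- fold_vector(e_syn); e_nonsyn <- fold_vector(e_nonsyn) }
  list(e_syn = e_syn, e_nonsyn = e_nonsyn)
}

## Indices of SFS classes that enter the likelihood (folded spectra only use
## classes up to floor(n/2)).
active_classes <- function(n, folded) {
  if (folded) seq_len(floor(n / 2)) else seq_len(n - 1L)
}

#' Poisson log-likelihood of an observed spectrum set under a DFE model
#'
#' Sum over synonymous and nonsynonymous frequency classes of the Poisson
#' log-pmf of the observed counts given the expected spectrum.  Divergence
#' counts do not enter the likelihood; they enter the analysis only through
#' `omega` in [alpha_decompose()].  A zero expectation facing a positive
#' observed count yields `-Inf` (returned, not thrown).
#'
#' @param params a [dfe_params()] with `theta` set.
#' @param observed a [spectrum_set()].
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(params, observed) {
  stopifnot(inherits(observed, "spectrum_set"))
  e <- expected_spectrum(params, observed$n, observed$Ls, observed$Ln,
                         folded = observed$folded)
  idx <- active_classes(observed$n, observed$folded)
  obs <- c(observed$sfs_syn[idx], observed$sfs_nonsyn[idx])
  lam <- c(e$e_syn[idx], e$e_nonsyn[idx])
  if (any(lam <= 0 & obs > 0)) return(-Inf)
  ok <- lam > 0
  sum(pois_lpmf(obs[ok], lam[ok]))
}

## Poisson log-pmf valid for fractional counts (expected-mode projection
## produces non-integer SFS entries); equals dpois(log = TRUE) on integers.
pois_lpmf <- function(x, lam) {
  out <- x * log(lam) - lam - lgamma(x + 1)
  out[x == 0] <- -lam[x == 0]
  out
}

## Negative profiled log-likelihood: theta (and, with use_r, all r_i) are
## maximized in closed form given the shape of the expected spectrum.
## Returns list(nll, theta, r) or NULL on degenerate parameters.
profiled_nll <- function(I, observed, eps = 0, use_r = FALSE) {
  n <- observed$n
  i <- seq_len(n - 1L)
  a0 <- observed$Ls / i            # syn shape at theta = 1
  b0 <- observed$Ln * I            # nonsyn shape at theta = 1
  a <- apply_eps(a0, eps); b <- apply_eps(b0, eps)
  if (observed$folded) { a <- fold_vector(a); b <- fold_vector(b) }
  idx <- active_classes(n, observed$folded)
  s <- observed$sfs_syn[idx]; x <- observed$sfs_nonsyn[idx]
  a <- a[idx]; b <- b[idx]
  if (use_r) {
    ## lambda_i = theta r_i profiled per class; r_1 = 1 anchors theta
    lam <- (s + x) / (a + b)
    theta <- lam[1L]
    if (!is.finite(theta) || theta <= 0) return(NULL)
    ok <- lam > 0
    if (any(!ok & (s > 0 | x > 0))) return(NULL)
    ll <- sum(pois_lpmf(s[ok], (lam * a)[ok])) +
      sum(pois_lpmf(x[ok], (lam * b)[ok]))
    r <- (lam / theta)[-1L]
  } else {
    theta <- sum(s + x) / sum(a + b)
    if (!is.finite(theta) || theta <= 0) return(NULL)
    es <- theta * a; ex <- theta * b
    if (any(es <= 0 & s > 0) || any(ex <= 0 & x > 0)) return(NULL)
    ll <- sum(pois_lpmf(s[es > 0], es[es > 0])) +
      sum(pois_lpmf(x[ex > 0], ex[ex > 0]))
    r <- NULL
  }
  if (!is.finite(ll)) return(NULL)
  list(nll = -ll, theta = theta, r = r)
}

## Deterministic multi-start grids (log/linear scales as optimized).
dfe_starts <- function(family, n_starts = 5L) {
  base <- list(
    c(shape = 0.3, mean_del = 2000, p_b = 0.02,  mean_ben = 10),
    c(shape = 0.1, mean_del = 100,  p_b = 0.05,  mean_ben = 1),
    c(shape = 1.0, mean_del = 1e4,  p_b = 0.005, mean_ben = 100),
    c(shape = 0.5, mean_del = 10,   p_b = 0.10,  mean_ben = 5),
    c(shape = 0.2, mean_del = 1e5,  p_b = 0.20,  mean_ben = 50))
  base[seq_len(min(n_starts, length(base)))]
}

#' Fit a DFE model to a spectrum set by Poisson maximum likelihood
#'
#' Bounded multi-start maximum likelihood in log-parameter space.  The
#' population mutation rate `theta` (and the nuisance `r_i` multipliers when
#' enabled) are profiled out in closed form at every evaluation, so the
#' numerical optimization runs only over the DFE shape parameters.  Returns
#' the fitted parameters together with the AIC and the
#' omega/omega_na/omega_a/alpha decomposition (see [alpha_decompose()]).
#'
#' @param observed a [spectrum_set()] with at least one positive entry in
#'   each of the synonymous and nonsynonymous SFS.
#' @param family DFE family to fit.
#' @param n_starts number of deterministic starting points (max 5).
#' @param use_r free per-class nuisance multipliers `r_2..r_{n-1}` shared
#'   between synonymous and nonsynonymous spectra.
#' @param use_eps free ancestral misidentification probability.
#' @param init optional [dfe_params()] used as an additional (first)
#'   starting point, e.g. a point estimate warm-starting bootstrap refits.
#' @param control passed to [stats::optim()] (method `L-BFGS-B`).
#' @return An object of class `dfe_fit`: list with `params`, `loglik`,
#'   `n_params`, `aic`, `omega`, `omega_na`, `omega_a`, `alpha`,
#'   `convergence`.
#' @export
fit_dfe <- function(observed, family = c("GammaExpo", "Gamma", "Neutral"),
                    n_starts = 5L, use_r = FALSE, use_eps = FALSE,
                    init = NULL, control = list()) {
  family <- match.arg(family)
  stopifnot(inherits(observed, "spectrum_set"))
  idx <- active_classes(observed$n, observed$folded)
  if (sum(observed$sfs_syn[idx]) <= 0 || sum(observed$sfs_nonsyn[idx]) <= 0)
    stop("need at least one positive SFS entry in each mutation class")
  tab <- dfe_tables(observed$n)
  n1 <- observed$n - 1L
  control <- utils::modifyList(list(factr = 1e8, maxit = 200L), control)

  eps_bounds <- if (use_eps) c(0, 0.5) else NULL

  I_neutral <- 1 / seq_len(n1)
  make_obj <- function(family) {
    function(par) {
      eps <- if (use_eps) par[length(par)] else 0
      core <- if (use_eps) par[-length(par)] else par
      I <- if (family == "Neutral") I_neutral else {
        wd <- gamma_weights(tab, exp(core[1L]), exp(core[2L]))
        if (is.null(wd)) return(1e10)
        Id <- drop(tab$Gdel %*% wd)
        pb <- if (family == "GammaExpo") min(max(core[3L], 0), 0.5) else 0
        if (pb > 0) {
          wb <- expo_weights(tab, exp(core[4L]))
          if (is.null(wb)) return(1e10)
          (1 - pb) * Id + pb * drop(tab$Gben %*% wb)
        } else Id
      }
      pr <- profiled_nll(I, observed, eps = eps, use_r = use_r)
      if (is.null(pr)) return(1e10)
      pr$nll
    }
  }

  obj <- make_obj(family)
  starts <- list(); lower <- numeric(0); upper <- numeric(0)
  if (family != "Neutral") {
    raw <- dfe_starts(family)
    if (!is.null(init) && inherits(init, "dfe_params") &&
        init$family == family && !is.na(init$shape)) {
      ini <- c(shape = unname(init$shape), mean_del = unname(init$mean_del),
               p_b = unname(max(init$p_b, 1e-4)),
               mean_ben = unname(init$mean_ben))
      if (is.na(ini[["mean_ben"]])) ini[["mean_ben"]] <- 10
      raw <- c(list(ini), raw)
    }
    raw <- raw[seq_len(min(n_starts, length(raw)))]
    if (family == "Gamma") {
      starts <- lapply(raw, function(s) log(s[c("shape", "mean_del")]))
      lower <- log(c(0.01, 0.01)); upper <- log(c(10, 1e6))
    } else {
      starts <- lapply(raw, function(s)
        c(log(s[["shape"]]), log(s[["mean_del"]]), s[["p_b"]],
          log(s[["mean_ben"]])))
      lower <- c(log(0.01), log(0.01), 0, log(0.01))
      upper <- c(log(10), log(1e6), 0.5, log(1e3))
    }
  }
  if (use_eps) {
    starts <- lapply(starts, function(s) c(s, 0.01))
    lower <- c(lower, 0); upper <- c(upper, 0.5)
  }

  if (family == "Neutral" && !use_eps) {
    best <- list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
  } else if (family == "Neutral") {
    best <- stats::optim(c(0.01), obj, method = "L-BFGS-B",
                         lower = 0, upper = 0.5, control = control)
  } else {
    best <- NULL
    for (s in starts) {
      res <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = control),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value) &&
          (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best))
      stop("all optimizer starts failed for family ", family)
  }

  ## reconstruct fitted parameters at the optimum
  par <- unname(best$par)
  eps_hat <- if (use_eps) par[length(par)] else 0
  core <- if (use_eps) par[-length(par)] else par
  params <- switch(family,
    Neutral = dfe_params("Neutral", theta = 1, eps = eps_hat),
    Gamma = dfe_params("Gamma", theta = 1, shape = exp(core[1L]),
                       mean_del = exp(core[2L]), eps = eps_hat),
    GammaExpo = dfe_params("GammaExpo", theta = 1, shape = exp(core[1L]),
                           mean_del = exp(core[2L]),
                           p_b = min(max(core[3L], 0), 0.5),
                           mean_ben = exp(core[4L]), eps = eps_hat))
  I <- mean_sfs_weight(params, tab)
  pr <- profiled_nll(I, observed, eps = eps_hat, use_r = use_r)
  params$theta <- pr$theta
  params$r <- pr$r
  loglik <- -pr$nll
  k <- switch(family, Neutral = 1L, Gamma = 3L, GammaExpo = 5L) +
    (if (use_r) observed$n - 2L else 0L) + (if (use_eps) 1L else 0L)

  ## omega decomposition needs synonymous divergence; without it the fit
  ## itself is still valid (SFS-only likelihood), rates are NA
  dec <- if (observed$Ds > 0) alpha_decompose(params, observed)
  else c(omega = NA_real_, omega_na = expected_omega_na(params, observed$n),
         omega_a = NA_real_, alpha = NA_real_)
  structure(list(params = params, loglik = loglik, n_params = k,
                 aic = 2 * k - 2 * loglik,
                 omega = dec[["omega"]], omega_na = dec[["omega_na"]],
                 omega_a = dec[["omega_a"]], alpha = dec[["alpha"]],
                 convergence = best$convergence %||% 0L),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit [%s]: logL = %.3f, k = %d, AIC = %.3f\n",
              x$params$family, x$loglik, x$n_params, x$aic))
  cat(sprintf("  omega = %.4f, omega_na = %.4f, omega_a = %.4f, alpha = %.4f\n",
              x$omega, x$omega_na, x$omega_a, x$alpha))
  invisible(x)
}

#' Decompose omega into adaptive and non-adaptive substitution rates
#'
#' `omega = (Dn/Ln)/(Ds/Ls)` is the observed rate of nonsynonymous relative
#' to synonymous substitution.  The expected non-adaptive component is the
#' mean relative fixation probability over the deleterious DFE,
#' `omega_na = (1 - p_b) * E[Q(S)]` (with `omega_na = 1` under the Neutral
#' family); beneficial fixations, including weakly beneficial ones, are
#' counted as adaptive: `omega_a = omega - omega_na`, `alpha = omega_a /
#' omega`.
#'
#' @param params a [dfe_params()].
#' @param observed a [spectrum_set()] with `Ds > 0`.
#' @return Named numeric vector `c(omega, omega_na, omega_a, alpha)`.
#' @export
#' @examples
#' s <- spectrum_set(4, 1000, 3000, c(5,2,1), c(6,2,1), Ds = 100, Dn = 60)
#' alpha_decompose(dfe_params("Neutral", theta = 0.01), s)
alpha_decompose <- function(params, observed) {
  stopifnot(inherits(params, "dfe_params"), inherits(observed, "spectrum_set"))
  if (observed$Ds <= 0)
    stop("omega is undefined when Ds = 0")
  omega <- (observed$Dn / observed$Ln) / (observed$Ds / observed$Ls)
  omega_na <- expected_omega_na(params, observed$n)
  c(omega = omega, omega_na = omega_na, omega_a = omega - omega_na,
    alpha = (omega - omega_na) / omega)
}

## E[Q(S)] over the deleterious component, scaled by (1 - p_b).
expected_omega_na <- function(params, n = 20L) {
  if (params$family == "Neutral") return(1)
  tab <- dfe_tables(n)
  wd <- gamma_weights(tab, params$shape, params$mean_del)
  if (is.null(wd)) stop("degenerate deleterious DFE")
  (1 - params$p_b) * sum(wd * tab$Qdel)
}

## Full-DFE expected omega (deleterious + beneficial fixations); the
## analytic truth used by the synthetic-data generator.
expected_omega_total <- function(params, n = 20L) {
  if (params$family == "Neutral") return(1)
  tab <- dfe_tables(n)
  om <- expected_omega_na(params, n)
  if (params$family == "GammaExpo" && params$p_b > 0) {
    wb <- expo_weights(tab, params$mean_ben)
    om <- om + params$p_b * sum(wb * tab$Qben)
  }
  om
}

#' Fit and rank several DFE families by AIC
#'
#' @param observed a [spectrum_set()].
#' @param families character vector of families to fit.
#' @param ... passed to [fit_dfe()].
#' @return A data frame ranked by ascending AIC (ties broken by fewer
#'   parameters) with one row per family; the fits themselves are attached
#'   as attribute `"fits"`.
#' @export
compare_models <- function(observed, families = DFE_FAMILIES, ...) {
  stopifnot(length(families) >= 2L)
  fits <- lapply(families, function(f) fit_dfe(observed, family = f, ...))
  names(fits) <- families
  tab <- data.frame(
    family = families,
    loglik = vapply(fits, `[[`, 1.0, "loglik"),
    n_params = vapply(fits, `[[`, 1L, "n_params"),
    aic = vapply(fits, `[[`, 1.0, "aic"),
    omega = vapply(fits, `[[`, 1.0, "omega"),
    omega_na = vapply(fits, `[[`, 1.0, "omega_na"),
    omega_a = vapply(fits, `[[`, 1.0, "omega_a"),
    alpha = vapply(fits, `[[`, 1.0, "alpha"),
    row.names = NULL)
  ord <- order(tab$aic, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  attr(tab, "fits") <- fits
  tab
}
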