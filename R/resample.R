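## Bootstrap machinery over analysis categories, replicate trimming,
## percentile confidence intervals, Kendall trend tests on category means,
## the pairwise bootstrap statistic k with P = (2k + 1)/(N + 1), FDR
## correction, and sequential-sum-of-squares variance partitioning.

## Internal: fast per-label bootstrap representation.  Unit spectra are
## packed into matrices once so each replicate is a colSums over resampled
## rows rather than a list traversal.
pack_units <- function(spectra) {
  n <- spectra[[1L]]$n
  list(n = n, folded = spectra[[1L]]$folded,
       syn = do.call(rbind, lapply(spectra, `[[`, "sfs_syn")),
       nonsyn = do.call(rbind, lapply(spectra, `[[`, "sfs_nonsyn")),
       Ls = vapply(spectra, `[[`, 1.0, "Ls"),
       Ln = vapply(spectra, `[[`, 1.0, "Ln"),
       Ds = vapply(spectra, `[[`, 1.0, "Ds"),
       Dn = vapply(spectra, `[[`, 1.0, "Dn"))
}

unpack_sum <- function(pk, idx, name = NULL) {
  spectrum_set(pk$n,
               sum(pk$Ls[idx]), sum(pk$Ln[idx]),
               colSums(pk$syn[idx, , drop = FALSE]),
               colSums(pk$nonsyn[idx, , drop = FALSE]),
               sum(pk$Ds[idx]), sum(pk$Dn[idx]),
               folded = pk$folded, name = name)
}

fit_row <- function(fit) {
  p <- fit$params
  data.frame(ok = TRUE, loglik = fit$loglik, aic = fit$aic,
             theta = p$theta, shape = p$shape %||% NA_real_,
             mean_del = p$mean_del %||% NA_real_, p_b = p$p_b,
             mean_ben = p$mean_ben %||% NA_real_,
             omega = fit$omega, omega_na = fit$omega_na,
             omega_a = fit$omega_a, alpha = fit$alpha)
}

failed_row <- function() {
  data.frame(ok = FALSE, loglik = NA_real_, aic = NA_real_, theta = NA_real_,
             shape = NA_real_, mean_del = NA_real_, p_b = NA_real_,
             mean_ben = NA_real_, omega = NA_real_, omega_na = NA_real_,
             omega_a = NA_real_, alpha = NA_real_)
}

#' Bootstrap DFE fits over analysis categories
#'
#' For every category, resamples its units (genes or site sets) with
#' replacement to the original count, aggregates the resampled unit spectra,
#' and refits the chosen DFE family, `B` times.  A point estimate on the
#' un-resampled aggregate is always computed and used to warm-start the
#' replicate fits.  Deterministic given `seed`.  Replicates whose fit fails
#' are recorded as failed, not fatal.
#'
#' @param units_by_label named list: category label -> character vector of
#'   unit ids (each category needs >= 2 units unless `resample = FALSE`).
#' @param spectra named list of [spectrum_set()] objects covering all units.
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param family DFE family to fit.
#' @param resample set `FALSE` to refit the identical aggregate in every
#'   replicate (identity mode, for tests).
#' @param n_starts optimizer starts for the point-estimate fit.
#' @param replicate_control [stats::optim()] control for the warm-started
#'   single-start replicate fits (looser tolerance than the point fit; the
#'   point estimate is the starting value, so few iterations are needed).
#' @param ... passed to [fit_dfe()] for all fits (e.g. `use_r`).
#' @return An object of class `bootstrap_result`: list with `scheme`
#'   (labels in order), `point` (per-label point-estimate rows),
#'   `replicates` (per-label data frame of replicate fits), `B`, `retained`
#'   (initialized to successful replicate counts; updated by
#'   [trim_replicates()]).
#' @export
bootstrap_categories <- function(units_by_label, spectra, B = 100L,
                                 seed = 1L, family = "GammaExpo",
                                 resample = TRUE, n_starts = 5L,
                                 replicate_control = list(factr = 1e9,
                                                          maxit = 60L),
                                 ...) {
  stopifnot(is.list(units_by_label), length(units_by_label) >= 1L)
  labs <- names(units_by_label)
  point <- list(); reps <- list()
  for (lb in labs) {
    ids <- units_by_label[[lb]]
    if (resample && length(ids) < 2L)
      stop("category '", lb, "' has fewer than 2 units")
    pk <- pack_units(spectra[ids])
    full <- unpack_sum(pk, seq_along(ids), name = lb)
    pfit <- fit_dfe(full, family = family, n_starts = n_starts, ...)
    point[[lb]] <- fit_row(pfit)
    rows <- vector("list", B)
    if (B > 0L) {
      with_seed(child_seed(seed, "boot", lb), {
        for (b in seq_len(B)) {
          idx <- if (resample)
            sample.int(length(ids), length(ids), replace = TRUE)
          else seq_along(ids)
          bs <- unpack_sum(pk, idx)
          rows[[b]] <- tryCatch(
            fit_row(fit_dfe(bs, family = family, init = pfit$params,
                            n_starts = 1L, control = replicate_control, ...)),
            error = function(e) failed_row())
        }
      })
    }
    reps[[lb]] <- do.call(rbind, rows) %||% failed_row()[0, ]
  }
  structure(list(scheme = labs, point = do.call(rbind, point),
                 replicates = reps, B = as.integer(B),
                 retained = vapply(reps, function(r) sum(r$ok), 1L)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap result: %d categories, B = %d\n",
              length(x$scheme), x$B))
  cat("  retained replicates:",
      paste(sprintf("%s=%d", x$scheme, x$retained), collapse = ", "), "\n")
  invisible(x)
}

#' Trim extreme bootstrap replicates on the DFE mean and shape
#'
#' Per category, failed replicates are dropped, then replicates whose
#' deleterious-DFE mean or shape lies strictly above the 99th or strictly
#' below the 1st percentile of that category's replicate values are removed
#' (union over the two parameters).  Categories retaining fewer than half of
#' their replicates are flagged with a warning.
#'
#' @param result a [bootstrap_categories()] result.
#' @return The trimmed `bootstrap_result` (the `replicates` data frames are
#'   subset; `retained` is updated).
#' @export
trim_replicates <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  for (lb in result$scheme) {
    r <- result$replicates[[lb]]
    r <- r[r$ok, , drop = FALSE]
    drop <- rep(FALSE, nrow(r))
    for (fld in c("mean_del", "shape")) {
      v <- r[[fld]]
      if (all(is.na(v))) next               # Neutral family has no DFE shape
      q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7,
                           na.rm = TRUE)
      drop <- drop | v < q[1L] | v > q[2L]
    }
    kept <- r[!drop, , drop = FALSE]
    if (nrow(kept) < result$B / 2)
      warning("category '", lb, "' retained fewer than half its replicates")
    result$replicates[[lb]] <- kept
    result$retained[[lb]] <- nrow(kept)
  }
  result
}

#' Bootstrap means and percentile confidence intervals per category
#'
#' Mean and the percentile 95% interval (2.5%, 97.5% quantiles) of the
#' retained replicates for each of omega, omega_na and omega_a.  Categories
#' with fewer than 3 retained replicates are omitted with a warning.
#'
#' @param result a (typically trimmed) [bootstrap_categories()] result.
#' @param stats which estimates to summarize.
#' @return Data frame with columns `label`, `stat`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
summarize_bootstrap <- function(result,
                                stats = c("omega", "omega_na", "omega_a")) {
  stopifnot(inherits(result, "bootstrap_result"))
  rows <- list()
  for (lb in result$scheme) {
    r <- result$replicates[[lb]]
    r <- r[r$ok, , drop = FALSE]
    if (nrow(r) < 3L) {
      warning("category '", lb, "' has < 3 retained replicates; omitted")
      next
    }
    for (st in stats) {
      v <- r[[st]]
      ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <-
        data.frame(label = lb, stat = st, mean = mean(v),
                   ci_low = ci[1L], ci_high = ci[2L])
    }
  }
  do.call(rbind, rows)
}

#' Kendall trend test of category means against category order
#'
#' Kendall's tau between the rank of the ordered category labels and the
#' per-category mean estimate (the mean of the bootstrap replicates), with a
#' two-sided P value (exact for small numbers of categories without ties,
#' normal approximation otherwise, as in [stats::cor.test()]).
#'
#' @param means numeric vector of category means, in label order.
#' @param ranks optional explicit ranks (default `seq_along(means)`).
#' @return A `test_outcome` data frame row: `comparison`, `statistic`
#'   (tau), `p_value`.
#' @export
#' @examples
#' kendall_trend(c(1, 3, 2))   # tau = 1/3
kendall_trend <- function(means, ranks = seq_along(means)) {
  stopifnot(length(means) >= 3L, length(ranks) == length(means))
  if (stats::sd(means) == 0) {
    return(data.frame(comparison = "trend", statistic = NA_real_,
                      p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(ranks, means, method = "kendall",
                    alternative = "two.sided"))
  data.frame(comparison = "trend",
             statistic = unname(ct$estimate), p_value = ct$p.value)
}

#' Pairwise bootstrap test between two categories
#'
#' Pairs the two categories' bootstrap replicates (by a seeded random
#' permutation, or by index), takes the differences `d_b = A_b - B_b`,
#' counts how many are below and above zero, and sets
#' `k = min(#below, #above)` (zero differences split evenly between the two
#' counts).  The two-tailed P value is `P = (2k + 1)/(N + 1)`.  If the lists
#' differ in length the shorter is padded by seeded resampling.
#'
#' @param repsA,repsB numeric vectors of replicate estimates (N >= 10 after
#'   padding).
#' @param seed integer seed for the permutation/padding.
#' @param mode `"permute"` (default) or `"index"` pairing.
#' @return A `test_outcome` data frame row: `comparison`, `statistic` (k),
#'   `p_value`, plus `mean_diff` (difference of category means).
#' @export
#' @examples
#' pairwise_bootstrap_test(rnorm(100, 2), rnorm(100, 0), seed = 1)
pairwise_bootstrap_test <- function(repsA, repsB, seed = 1L,
                                    mode = c("permute", "index")) {
  mode <- match.arg(mode)
  repsA <- repsA[is.finite(repsA)]; repsB <- repsB[is.finite(repsB)]
  N <- max(length(repsA), length(repsB))
  if (N < 10L) stop("need at least 10 replicates")
  with_seed(child_seed(seed, "pair"), {
    if (length(repsA) < N)
      repsA <- c(repsA, sample(repsA, N - length(repsA), replace = TRUE))
    if (length(repsB) < N)
      repsB <- c(repsB, sample(repsB, N - length(repsB), replace = TRUE))
    if (mode == "permute") repsB <- repsB[sample.int(N)]
  })
  d <- repsA - repsB
  nz <- sum(d == 0)
  k <- min(sum(d < 0), sum(d > 0)) + nz / 2
  data.frame(comparison = "pairwise", statistic = k,
             p_value = (2 * k + 1) / (N + 1),
             mean_diff = mean(repsA) - mean(repsB))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR correction with monotonicity enforcement; input order is
#' preserved.  Thin wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of P values in `(0, 1]`.
#' @return Adjusted P values, same order as the input.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
fdr_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Sequential variance partition of rate estimates on RSA and disorder
#'
#' Ordinary least squares of a per-category rate estimate (omega_a or
#' omega_na) on RSA, disorder and their interaction, with sequential
#' (entry-order) sums of squares, RSA entered first.  Reports the fraction
#' of total variance attributed to each term (fractions sum to 1) together
#' with the sequential-ANOVA P values.
#'
#' @param response numeric vector of per-category estimates.
#' @param rsa,disorder numeric covariates (category-level).
#' @param order term order, default RSA first.
#' @return Data frame with columns `term`, `fraction`, `p_value` over
#'   `rsa`, `disorder`, `rsa:disorder`, `residual`.
#' @export
ancova_partition <- function(response, rsa, disorder,
                             order = c("rsa", "disorder")) {
  stopifnot(length(response) >= 8L,
            length(rsa) == length(response),
            length(disorder) == length(response))
  if (abs(stats::cor(rsa, disorder)) > 0.999)
    stop("covariates 'rsa' and 'disorder' are collinear")
  dat <- data.frame(y = response, rsa = rsa, disorder = disorder)
  fml <- stats::reformulate(
    c(order, paste(order, collapse = ":")), response = "y")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear model terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  terms <- rownames(av)
  data.frame(term = sub("Residuals", "residual", terms),
             fraction = ss / sum(ss),
             p_value = av[["Pr(>F)"]])
}
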