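## End-to-end orchestration: bin units into categories per scheme, bootstrap
## DFE fits per category, trim, summarize, and run the trend / pairwise
## significance machinery, producing report tables of the shape used for
## published category analyses (continuous variables: Kendall tau per
## estimator; discrete variables: pairwise mean differences with
## FDR-corrected bootstrap P values).

#' Define a categorization scheme for [run_scan()]
#'
#' @param name scheme label.
#' @param variable column of the unit table to categorize on.
#' @param k number of equal-count categories (continuous variables); `NULL`
#'   treats the variable as discrete, using its levels as categories.
#' @param zero_special give value-zero units a dedicated first category
#'   (RSA = 0 convention).
#' @param unit `"gene"` or `"site"` (bookkeeping).
#' @return A `scan_scheme` list.
#' @export
scan_scheme <- function(name, variable, k = NULL, zero_special = FALSE,
                        unit = "gene") {
  structure(list(name = name, variable = variable, k = k,
                 zero_special = zero_special, unit = unit),
            class = "scan_scheme")
}

assign_scheme <- function(scheme, units) {
  if (!scheme$variable %in% names(units))
    stop("scheme '", scheme$name, "' references missing covariate '",
         scheme$variable, "'")
  v <- units[[scheme$variable]]
  if (!is.null(scheme$k) && is.numeric(v)) {
    equal_count_bins(stats::setNames(v, units$unit_id), scheme$k,
                     zero_special = scheme$zero_special,
                     scheme_name = scheme$name,
                     unit = if (scheme$unit == "site") "site" else "gene")
  } else {
    lab <- if (is.factor(v)) v else factor(v, levels = sort(unique(v)))
    out <- data.frame(unit = units$unit_id,
                      label = factor(as.character(lab),
                                     levels = levels(lab), ordered = TRUE),
                      stringsAsFactors = FALSE)
    structure(out, scheme_name = scheme$name, unit_type = scheme$unit,
              class = c("category_assignment", "data.frame"))
  }
}

scan_one_scheme <- function(scheme, units, spectra, family, B, seed,
                            n_starts, trim) {
  assignment <- assign_scheme(scheme, units)
  assignment <- assignment[!is.na(assignment$label), , drop = FALSE]
  units_by_label <- split(assignment$unit, assignment$label, drop = FALSE)
  units_by_label <- units_by_label[vapply(units_by_label, length, 1L) > 0L]
  boot <- bootstrap_categories(units_by_label, spectra, B = B,
                               seed = child_seed(seed, scheme$name),
                               family = family, n_starts = n_starts)
  if (trim) boot <- trim_replicates(boot)
  summ <- summarize_bootstrap(boot)

  discrete <- is.null(scheme$k)
  ests <- c("omega_a", "omega_na", "omega")
  trend <- NULL; pairwise <- NULL
  if (!discrete) {
    trend <- do.call(rbind, lapply(ests, function(st) {
      means <- vapply(boot$scheme, function(lb) {
        r <- boot$replicates[[lb]]; mean(r[[st]][r$ok])
      }, numeric(1))
      cbind(stat = st, kendall_trend(means))
    }))
  } else {
    labs <- boot$scheme
    prs <- utils::combn(labs, 2L, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(ests, function(st) {
      rows <- do.call(rbind, lapply(prs, function(pr) {
        a <- boot$replicates[[pr[1L]]]; b <- boot$replicates[[pr[2L]]]
        res <- pairwise_bootstrap_test(
          a[[st]][a$ok], b[[st]][b$ok],
          seed = child_seed(seed, scheme$name, st, pr[1L], pr[2L]))
        data.frame(comparison = paste(pr[1L], pr[2L], sep = "-"),
                   stat = st, k = res$statistic, mean_diff = res$mean_diff,
                   p_value = res$p_value)
      }))
      rows$p_adjusted <- if (nrow(rows) > 1L) fdr_adjust(rows$p_value)
      else rows$p_value
      rows$signif <- signif_code(rows$p_adjusted)
      rows
    }))
  }
  list(scheme = scheme, assignment = assignment, bootstrap = boot,
       summary = summ, trend = trend, pairwise = pairwise,
       n_units = nrow(assignment), n_categories = length(units_by_label))
}

#' Run the category-scan analysis end to end
#'
#' For every scheme: assigns units to ordered categories, aggregates unit
#' spectra per category, runs `B` bootstrap DFE fits per category
#' ([bootstrap_categories()]), trims extreme replicates
#' ([trim_replicates()]), summarizes means and 95% CIs, and tests either
#' the across-category trend (continuous schemes; Kendall's tau on category
#' means) or all pairwise category differences (discrete schemes; bootstrap
#' k statistic with BH-FDR correction).  Fully deterministic given `seed`.
#'
#' @param spectra named list of per-unit [spectrum_set()] objects.
#' @param units data frame of per-unit covariates; must contain `unit_id`.
#' @param schemes list of [scan_scheme()] definitions.
#' @param family DFE family fitted throughout (default `"GammaExpo"`).
#' @param B bootstrap replicates per category (default 100).
#' @param seed integer seed.
#' @param n_starts optimizer starts for point-estimate fits.
#' @param trim apply replicate trimming before summaries and tests.
#' @return An object of class `scan_result`: per-scheme result list plus
#'   `table_continuous` (scheme, categories, units, tau and significance per
#'   estimator) and `table_discrete` (pairwise differences with FDR-adjusted
#'   P) report tables.
#' @export
run_scan <- function(spectra, units, schemes, family = "GammaExpo",
                     B = 100L, seed = 1L, n_starts = 5L, trim = TRUE) {
  stopifnot(is.data.frame(units), "unit_id" %in% names(units))
  if (inherits(schemes, "scan_scheme")) schemes <- list(schemes)
  miss <- setdiff(units$unit_id, names(spectra))
  if (length(miss))
    stop(length(miss), " unit(s) lack spectra, e.g. ", miss[1L])
  results <- lapply(schemes, scan_one_scheme, units = units,
                    spectra = spectra, family = family, B = B, seed = seed,
                    n_starts = n_starts, trim = trim)
  names(results) <- vapply(schemes, `[[`, character(1), "name")

  cont <- list(); disc <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    if (!is.null(r$trend)) {
      row <- data.frame(variable = nm, n_categories = r$n_categories,
                        n_units = r$n_units)
      for (st in unique(r$trend$stat)) {
        tr <- r$trend[r$trend$stat == st, ]
        row[[paste0("tau_", st)]] <- tr$statistic
        row[[paste0("p_", st)]] <- tr$p_value
        row[[paste0("signif_", st)]] <- signif_code(tr$p_value)
      }
      cont[[nm]] <- row
    }
    if (!is.null(r$pairwise)) {
      disc[[nm]] <- cbind(variable = nm, n_categories = r$n_categories,
                          n_units = r$n_units, r$pairwise)
    }
  }
  structure(list(schemes = results,
                 table_continuous = do.call(rbind, cont),
                 table_discrete = do.call(rbind, disc),
                 seed = seed, B = B, family = family),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Category scan: %d scheme(s), family %s, B = %d, seed = %d\n",
              length(x$schemes), x$family, x$B, x$seed))
  if (!is.null(x$table_continuous)) {
    cat("\nContinuous variables (Kendall tau on category means):\n")
    print(x$table_continuous, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$table_discrete)) {
    cat("\nDiscrete variables (pairwise bootstrap differences):\n")
    print(x$table_discrete, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Re-run a scheme separately within buried and exposed site strata
#'
#' The confound control: repeats a variable's category analysis within the
#' buried (`RSA < 0.05`) and exposed (`RSA >= 0.05`) unit sets separately,
#' re-binning within each stratum, so an effect that is a by-product of
#' solvent exposure vanishes within strata.
#'
#' @param spectra named list of per-unit spectra.
#' @param units unit covariate table; must contain an `exposure` column
#'   with values `"buried"`/`"exposed"` (see [classify_exposure()]).
#' @param scheme the [scan_scheme()] to stratify; its variable must not be
#'   the exposure classification itself.
#' @param ... passed to [run_scan()].
#' @return Named list of `scan_result` objects (one per stratum) with a
#'   combined `table` attribute.
#' @export
stratified_refit <- function(spectra, units, scheme, ...) {
  stopifnot("exposure" %in% names(units))
  if (scheme$variable == "exposure")
    stop("cannot stratify the exposure classification by itself")
  strata <- c("buried", "exposed")
  out <- lapply(strata, function(st) {
    sub <- units[units$exposure == st, , drop = FALSE]
    if (nrow(sub) < max(scheme$k %||% 2L, 2L)) {
      warning("stratum '", st, "' too small; omitted")
      return(NULL)
    }
    run_scan(spectra, sub, list(scheme), ...)
  })
  names(out) <- strata
  out <- out[!vapply(out, is.null, TRUE)]
  tabs <- lapply(names(out), function(st) {
    tb <- out[[st]]$table_continuous %||% out[[st]]$table_discrete
    if (!is.null(tb)) cbind(stratum = st, tb)
  })
  attr(out, "table") <- do.call(rbind, tabs)
  out
}
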