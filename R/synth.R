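## Synthetic-data generator: emulates, with known ground truth, the products
## the real study pipeline would consume — per-gene covariate tables and
## per-residue structural feature tables with the observed correlation
## structure (zero-inflated RSA, expression negatively rank-correlated with
## length, disorder associated with RSA and secondary structure), per-unit
## spectrum sets drawn from specified DFEs, and small codon-alignment
## fixtures with hand-checkable expected spectra.

#' Simulate gene- and residue-level covariate tables
#'
#' Gene lengths are log-normal; expression is log-normal with a configurable
#' negative rank correlation to length (Gaussian copula); per-residue RSA is
#' zero-inflated Beta (a point mass at exactly 0 emulating totally buried
#' residues); secondary structure follows a 3-state Markov chain along the
#' chain; disorder probability is positively rank-correlated with RSA and
#' elevated in loops.  Remaining covariates (introns, recombination,
#' expression breadth, PPI degree, chaperone binding, localization,
#' functional class, active sites) are drawn independently with realistic
#' marginals.
#'
#' @param G number of genes (>= 10).
#' @param seed integer seed.
#' @param config optional list overriding defaults: `mean_log_len`,
#'   `sd_log_len`, `rho_len_expr` (negative), `rsa_zero` (zero-inflation
#'   weight), `rsa_shape1`, `rsa_shape2`, `rho_rsa_disorder`,
#'   `loop_disorder_boost`, `ss_persist`.
#' @return A list with data frames `genes` (one row per gene) and
#'   `residues` (one row per residue), plus the resolved `config`.
#' @export
simulate_features <- function(G, seed = 1L, config = list()) {
  stopifnot(G >= 10L)
  cfg <- utils::modifyList(list(
    mean_log_len = log(400), sd_log_len = 0.55,
    rho_len_expr = -0.3,
    rsa_zero = 0.11, rsa_shape1 = 1.1, rsa_shape2 = 2.2,
    rho_rsa_disorder = 0.3, loop_disorder_boost = 0.15,
    ss_persist = 0.85), config)
  if (cfg$rho_len_expr > 0)
    stop("expression-length correlation target must be negative")
  if (abs(cfg$rho_len_expr) >= 1 || abs(cfg$rho_rsa_disorder) >= 1)
    stop("infeasible correlation target")

  with_seed(seed, {
    ## gene table: copula between length and expression
    z1 <- stats::rnorm(G)
    z2 <- cfg$rho_len_expr * z1 +
      sqrt(1 - cfg$rho_len_expr^2) * stats::rnorm(G)
    length_codons <- pmax(30L, as.integer(round(
      exp(cfg$mean_log_len + cfg$sd_log_len * z1))))
    expr_mean <- exp(1.5 + 1.2 * z2)
    genes <- data.frame(
      gene_id = sprintf("g%05d", seq_len(G)),
      length_codons = length_codons,
      intron_count = stats::rpois(G, 3),
      recomb_rate = stats::rgamma(G, shape = 2, rate = 0.8),   # cM/Mb
      expr_mean = expr_mean,
      expr_breadth = 1L + stats::rbinom(G, 17L, stats::plogis(z2)),
      ppi_degree = stats::rnbinom(G, size = 1, mu = 8),
      chaperone_binder = stats::runif(G) < 0.3,
      localization = sample(c("cytoplasmic", "endomembrane", "mitochondrial",
                              "nuclear", "plasma_membrane", "secreted"),
                            G, replace = TRUE,
                            prob = c(0.25, 0.15, 0.1, 0.3, 0.12, 0.08)),
      functional_class = sample(paste0("class", 1:12), G, replace = TRUE),
      stringsAsFactors = FALSE)

    ## residue table (built column-wise; one data frame at the end)
    res <- lapply(seq_len(G), function(gi) {
      L <- genes$length_codons[gi]
      ## secondary structure: persistent 3-state chain
      ss <- character(L)
      states <- c("helix", "sheet", "loop")
      others <- list(helix = c("sheet", "loop"), sheet = c("helix", "loop"),
                     loop = c("helix", "sheet"))
      ss[1L] <- sample(states, 1L, prob = c(0.38, 0.2, 0.42))
      switch_ev <- stats::runif(L - 1L) >= cfg$ss_persist
      pick <- 1L + (stats::runif(L - 1L) < 0.5)
      for (j in seq_len(L - 1L)) {
        ss[j + 1L] <- if (switch_ev[j]) others[[ss[j]]][pick[j]] else ss[j]
      }
      ## RSA: zero-inflated Beta, copula-linked to disorder
      zr <- stats::rnorm(L)
      zd <- cfg$rho_rsa_disorder * zr +
        sqrt(1 - cfg$rho_rsa_disorder^2) * stats::rnorm(L)
      rsa <- stats::qbeta(stats::pnorm(zr), cfg$rsa_shape1, cfg$rsa_shape2)
      rsa[stats::runif(L) < cfg$rsa_zero] <- 0
      disorder <- stats::pnorm(zd - 0.5 + cfg$loop_disorder_boost *
                                 (ss == "loop"))
      list(rsa = rsa, ss = ss, disorder = disorder)
    })
    lens <- genes$length_codons
    residues <- data.frame(
      gene_id = rep(genes$gene_id, lens),
      residue_index = unlist(lapply(lens, seq_len), use.names = FALSE) - 1L,
      rsa = unlist(lapply(res, `[[`, "rsa"), use.names = FALSE),
      ss = unlist(lapply(res, `[[`, "ss"), use.names = FALSE),
      disorder_p = unlist(lapply(res, `[[`, "disorder"), use.names = FALSE),
      stringsAsFactors = FALSE)
    residues$codon_index <- residues$residue_index
    residues$active_site <- stats::runif(nrow(residues)) < 0.005

    fl <- flag_disordered(residues$disorder_p, residues$gene_id)
    genes$prop_disordered <-
      unname(fl$prop_disordered[genes$gene_id])

    list(genes = genes, residues = residues, config = cfg)
  })
}

#' Simulate spectrum sets from per-unit DFEs, with analytic ground truth
#'
#' For each analysis unit (a gene, or a gene-by-category cell of residue
#' sites), draws SFS counts independently per frequency class from the
#' Poisson expectation under that unit's generating DFE, and divergence
#' counts `Ds ~ Poisson(div_rate * Ls)` and
#' `Dn ~ Poisson(div_rate * Ln * omega_true)` where `omega_true` is the mean
#' relative fixation probability over the full generating DFE.  The returned
#' truth manifest records the analytic `omega`, `omega_na`, `omega_a` and
#' `alpha` of every unit's generating DFE (`omega_a = omega - omega_na`
#' holds exactly).
#'
#' @param units data frame with columns `unit_id`, `Ls`, `Ln` and optionally
#'   `group` (a generating-DFE label into `dfe_map`; defaults to a single
#'   shared DFE).
#' @param dfe_map named list of [dfe_params()] (with `theta` set), one per
#'   distinct `group`; or a single `dfe_params` used for all units.
#' @param n sample size in chromosomes (default 20).
#' @param seed integer seed.
#' @param div_rate synonymous divergence rate per site (default 0.15).
#' @return A list: `spectra` (named list of `spectrum_set`), `truth` (data
#'   frame per unit with the generating parameters and analytic rates),
#'   `n`, `seed`.
#' @export
simulate_spectra <- function(units, dfe_map, n = 20L, seed = 1L,
                             div_rate = 0.15) {
  stopifnot(is.data.frame(units),
            all(c("unit_id", "Ls", "Ln") %in% names(units)))
  if (inherits(dfe_map, "dfe_params")) dfe_map <- list(all = dfe_map)
  if (is.null(units$group)) units$group <- names(dfe_map)[1L]
  if (!all(units$group %in% names(dfe_map)))
    stop("dfe_map lacks parameters for some unit groups")

  ## per-group expected shapes and analytic rates (computed once)
  groups <- unique(units$group)
  ginfo <- lapply(groups, function(g) {
    p <- dfe_map[[g]]
    list(params = p,
         I = mean_sfs_weight(p, dfe_tables(n)),
         omega = expected_omega_total(p, n),
         omega_na = expected_omega_na(p, n))
  })
  names(ginfo) <- groups

  ## vectorized class-wise Poisson draws across all units
  i <- seq_len(n - 1L)
  U <- nrow(units)
  theta_u <- vapply(ginfo[units$group], function(g) g$params$theta,
                    numeric(1), USE.NAMES = FALSE)
  Imat <- vapply(ginfo[units$group], `[[`, numeric(n - 1L), "I",
                 USE.NAMES = FALSE)                     # (n-1) x U
  om_u <- vapply(ginfo[units$group], `[[`, numeric(1), "omega",
                 USE.NAMES = FALSE)
  spectra <- with_seed(seed, {
    syn <- matrix(stats::rpois(U * (n - 1L),
                               outer(1 / i, theta_u * units$Ls)),
                  nrow = n - 1L)
    nonsyn <- matrix(stats::rpois(U * (n - 1L),
                                  Imat * rep(theta_u * units$Ln,
                                             each = n - 1L)),
                     nrow = n - 1L)
    Ds <- stats::rpois(U, div_rate * units$Ls)
    Dn <- stats::rpois(U, div_rate * units$Ln * om_u)
    lapply(seq_len(U), function(u)
      structure(list(n = as.integer(n), Ls = units$Ls[u], Ln = units$Ln[u],
                     sfs_syn = syn[, u], sfs_nonsyn = nonsyn[, u],
                     Ds = Ds[u], Dn = Dn[u], folded = FALSE,
                     name = units$unit_id[u]),
                class = "spectrum_set"))
  })
  names(spectra) <- units$unit_id

  gfield <- function(f) vapply(ginfo[units$group], function(g)
    g$params[[f]] %||% NA_real_, numeric(1), USE.NAMES = FALSE)
  om <- vapply(ginfo[units$group], `[[`, numeric(1), "omega",
               USE.NAMES = FALSE)
  omna <- vapply(ginfo[units$group], `[[`, numeric(1), "omega_na",
                 USE.NAMES = FALSE)
  truth <- data.frame(
    unit_id = units$unit_id, group = units$group,
    theta = gfield("theta"), shape = gfield("shape"),
    mean_del = gfield("mean_del"), p_b = gfield("p_b"),
    mean_ben = gfield("mean_ben"),
    omega = om, omega_na = omna, omega_a = om - omna,
    alpha = (om - omna) / om, stringsAsFactors = FALSE)
  list(spectra = spectra, truth = truth, n = n, seed = seed)
}

#' Default Drosophila-like generating DFE
#'
#' Gamma-Exponential parameters of realistic magnitude for recovery
#' harnesses: theta 0.01/site, Gamma shape 0.3 with mean deleterious
#' magnitude 2000, 0.5% beneficial mutations of mean scaled advantage 10.
#'
#' @param p_b beneficial proportion override.
#' @param theta mutation rate override.
#' @return A [dfe_params()].
#' @export
default_true_dfe <- function(p_b = 0.005, theta = 0.01) {
  dfe_params("GammaExpo", theta = theta, shape = 0.3, mean_del = 2000,
             p_b = p_b, mean_ben = 10)
}

#' Map RSA categories to generating DFEs with a planted adaptive trend
#'
#' Builds a named list of generating DFEs over ordered RSA categories in
#' which the beneficial proportion `p_b` increases log-linearly from
#' `p_b_range[1]` (most buried) to `p_b_range[2]` (most exposed), so the
#' true omega_a is strictly increasing across categories.  With equal
#' endpoints the trend is flat (null).
#'
#' @param labels ordered category labels.
#' @param p_b_range length-2 numeric, `p_b` at the first and last category.
#' @param theta mutation rate per site.
#' @return Named list of [dfe_params()].
#' @export
planted_rsa_dfes <- function(labels, p_b_range = c(0.001, 0.01),
                             theta = 0.01) {
  k <- length(labels)
  pb <- if (k == 1L) p_b_range[1L]
  else exp(seq(log(p_b_range[1L]), log(p_b_range[2L]), length.out = k))
  out <- lapply(pb, function(p)
    dfe_params("GammaExpo", theta = theta, shape = 0.3, mean_del = 2000,
               p_b = p, mean_ben = 10))
  names(out) <- labels
  out
}

#' Simulate a full site-level RSA study with a planted adaptive trend
#'
#' The synthetic twin of a residue-exposure analysis: simulates covariate
#' tables for `G` genes ([simulate_features()]), bins residues into `k`
#' equal-count RSA categories with a dedicated RSA = 0 category
#' ([equal_count_bins()]), forms gene-by-category cells of codon sites as
#' the resampling units, attaches to each category a generating DFE whose
#' beneficial proportion increases with RSA ([planted_rsa_dfes()]; equal
#' `p_b_range` endpoints give a null study), and draws per-cell spectrum
#' sets ([simulate_spectra()]).  Site opportunities split each codon as 1/4
#' synonymous, 3/4 nonsynonymous.
#'
#' @param G number of genes.
#' @param n sample size in chromosomes.
#' @param seed integer seed.
#' @param k number of RSA categories (including the RSA = 0 category).
#' @param p_b_range beneficial proportion at the most buried and most
#'   exposed category.
#' @param planted shape of the planted effect: `"gradient"` (log-linear
#'   `p_b` across the ordered RSA categories), `"exposure_step"` (`p_b =
#'   p_b_range[1]` for categories whose median RSA is below the 0.05
#'   burial threshold and `p_b_range[2]` above it), or `"null"`
#'   (`p_b_range[1]` everywhere).
#' @param theta mutation rate per site.
#' @param div_rate synonymous divergence rate per site.
#' @param config passed to [simulate_features()].
#' @return A list: `units` (cell table with `unit_id`, `rsa` (cell mean),
#'   `exposure`, `group`, `Ls`, `Ln`), `spectra` (per-cell spectrum sets),
#'   `truth` (per-category analytic rates), `bin_labels` (ordered),
#'   `features`.
#' @export
simulate_rsa_study <- function(G = 2000L, n = 20L, seed = 1L, k = 19L,
                               p_b_range = c(0.001, 0.01),
                               planted = c("gradient", "exposure_step",
                                           "null"),
                               theta = 0.01, div_rate = 0.15,
                               config = list()) {
  planted <- match.arg(planted)
  feats <- simulate_features(G, seed = child_seed(seed, "features"), config)
  res <- feats$residues
  rid <- paste(res$gene_id, res$residue_index, sep = ":")
  bins <- equal_count_bins(stats::setNames(res$rsa, rid), k,
                           zero_special = TRUE, scheme_name = "rsa",
                           unit = "site")
  res$bin <- bins$label[match(rid, bins$unit)]

  ## gene x category cells of codon sites
  key <- paste(res$gene_id, res$bin, sep = ".")
  nsite <- rowsum(rep(1, nrow(res)), key)
  rsa_sum <- rowsum(res$rsa, key)
  ids <- rownames(nsite)
  nsite <- drop(nsite); rsa_mean <- drop(rsa_sum) / nsite
  units <- data.frame(
    unit_id = ids,
    gene_id = sub("\\.[^.]*$", "", ids),
    group = sub("^.*\\.", "", ids),
    rsa = rsa_mean,
    exposure = as.character(classify_exposure(rsa_mean)),
    Ls = 3 * nsite * 0.25, Ln = 3 * nsite * 0.75,
    row.names = NULL, stringsAsFactors = FALSE)
  gi <- match(units$gene_id, feats$genes$gene_id)
  units$length_codons <- feats$genes$length_codons[gi]
  units$expr_mean <- feats$genes$expr_mean[gi]

  labels <- levels(bins$label)
  dfes <- switch(planted,
    gradient = planted_rsa_dfes(labels, p_b_range = p_b_range,
                                theta = theta),
    exposure_step = {
      med <- tapply(res$rsa, res$bin, stats::median)[labels]
      pb <- ifelse(med < 0.05, p_b_range[1L], p_b_range[2L])
      out <- lapply(pb, function(p)
        dfe_params("GammaExpo", theta = theta, shape = 0.3,
                   mean_del = 2000, p_b = p, mean_ben = 10))
      stats::setNames(out, labels)
    },
    null = planted_rsa_dfes(labels,
                            p_b_range = rep(p_b_range[1L], 2L),
                            theta = theta))
  sim <- simulate_spectra(units, dfes, n = n,
                          seed = child_seed(seed, "spectra"),
                          div_rate = div_rate)
  truth <- unique(sim$truth[, c("group", "theta", "shape", "mean_del",
                                "p_b", "mean_ben", "omega", "omega_na",
                                "omega_a", "alpha")])
  truth <- truth[match(labels, truth$group), , drop = FALSE]
  list(units = units, spectra = sim$spectra, truth = truth,
       bin_labels = labels, features = feats, n = n, seed = seed)
}

#' Generate small codon-alignment fixtures with known expected spectra
#'
#' Builds a set of small alignments (<= 50 codons, <= 6 chromosomes) with
#' planted synonymous/nonsynonymous polymorphisms and fixed differences, and
#' emits the exact spectrum set each alignment must produce, computed by
#' independent rule-following enumeration (opportunities enumerated directly
#' from the genetic code within this generator, planted events tallied by
#' construction).
#'
#' @param seed integer seed (selects codon backgrounds).
#' @return A list of cases; each case has `alignment` (a
#'   [codon_alignment()]) and `expected` (a [spectrum_set()]).
#' @export
simulate_alignment_fixture <- function(seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  safe <- names(code)[code != "*"]
  ## fourfold-degenerate codons for clean synonymous edits
  four <- c("GGT", "GCT", "GTT", "CCT", "ACT", "TCT", "CGT", "CTT")

  ## independent opportunity enumeration (mirrors the counting rule from
  ## the genetic code directly; no shared code path with build_spectrum)
  opp <- function(codon) {
    b <- strsplit(codon, "")[[1L]]
    syn <- 0; non <- 0
    for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
      cb <- b; cb[p] <- alt
      aa <- code[[paste(cb, collapse = "")]]
      if (aa == "*") next
      if (aa == code[[codon]]) syn <- syn + 1 / 3 else non <- non + 1 / 3
    }
    c(syn, non)
  }

  mutate_at <- function(codon, pos, base) {
    b <- strsplit(codon, "")[[1L]]; b[pos] <- base
    paste(b, collapse = "")
  }

  with_seed(seed, {
    m <- 4L                      # ingroup chromosomes
    ncod <- 12L
    bg <- sample(setdiff(safe, "ATG"), ncod, replace = TRUE)

    build_case <- function(events, gene_id) {
      ## events: list of list(type, codon_index, ...) applied to bg
      cols <- lapply(seq_len(ncod), function(j)
        list(ingroup = rep(bg[j], m), outgroup = bg[j]))
      Ls <- 0; Ln <- 0; Ds <- 0; Dn <- 0
      sfs_syn <- numeric(m - 1L); sfs_non <- numeric(m - 1L)
      for (ev in events) {
        j <- ev$codon_index
        cols[[j]]$ingroup <- ev$ingroup
        cols[[j]]$outgroup <- ev$outgroup
      }
      for (j in seq_len(ncod)) {
        cl <- cols[[j]]
        o <- rowMeans(vapply(cl$ingroup, opp, numeric(2)))
        Ls <- Ls + o[1L]; Ln <- Ln + o[2L]
        ev <- Filter(function(e) e$codon_index == j, events)
        if (length(ev)) {
          e <- ev[[1L]]
          switch(e$kind,
                 poly_syn = { sfs_syn[e$derived] <- sfs_syn[e$derived] + 1 },
                 poly_nonsyn = { sfs_non[e$derived] <- sfs_non[e$derived] + 1 },
                 div_syn = { Ds <- Ds + 1 },
                 div_nonsyn = { Dn <- Dn + 1 })
        }
      }
      ing <- vapply(seq_len(m), function(ch)
        paste(vapply(cols, function(cl) cl$ingroup[ch], character(1)),
              collapse = ""), character(1))
      outg <- paste(vapply(cols, `[[`, character(1), "outgroup"),
                    collapse = "")
      list(alignment = codon_alignment(gene_id, ing, outg),
           expected = spectrum_set(m, Ls, Ln, sfs_syn, sfs_non, Ds, Dn,
                                   name = gene_id))
    }

    ## planted events on distinct codon columns
    c4a <- sample(four, 4L)
    ev1 <- list(
      ## syn polymorphism, derived count 1 (third-position fourfold edit)
      local({
        j <- 2L; anc <- c4a[1L]; der <- mutate_at(anc, 3L, "A")
        list(kind = "poly_syn", codon_index = j, derived = 1L,
             ingroup = c(der, rep(anc, 3L)), outgroup = anc)
      }),
      ## nonsyn polymorphism, derived count 2 (first-position edit)
      local({
        j <- 5L; anc <- c4a[2L]
        alt <- setdiff(c("A", "C", "G", "T"),
                       substr(anc, 1L, 1L))
        der <- NULL
        for (b in alt) {
          cand <- mutate_at(anc, 1L, b)
          if (code[[cand]] != "*" && code[[cand]] != code[[anc]]) {
            der <- cand; break
          }
        }
        list(kind = "poly_nonsyn", codon_index = j, derived = 2L,
             ingroup = c(der, der, anc, anc), outgroup = anc)
      }),
      ## fixed synonymous difference
      local({
        j <- 8L; anc <- c4a[3L]; out <- mutate_at(anc, 3L, "C")
        if (out == anc) out <- mutate_at(anc, 3L, "G")
        list(kind = "div_syn", codon_index = j,
             ingroup = rep(anc, 4L), outgroup = out)
      }),
      ## fixed nonsynonymous difference
      local({
        j <- 11L; anc <- c4a[4L]
        alt <- setdiff(c("A", "C", "G", "T"), substr(anc, 2L, 2L))
        out <- NULL
        for (b in alt) {
          cand <- mutate_at(anc, 2L, b)
          if (code[[cand]] != "*" && code[[cand]] != code[[anc]]) {
            out <- cand; break
          }
        }
        list(kind = "div_nonsyn", codon_index = j,
             ingroup = rep(anc, 4L), outgroup = out)
      }))

    list(
      planted = build_case(ev1, "fix_planted"),
      monomorphic = build_case(list(), "fix_mono"),
      single_div_nonsyn = build_case(ev1[4L], "fix_div")
    )
  })
}
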