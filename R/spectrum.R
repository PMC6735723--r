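## SpectrumSet: the unit of data every DFE fit consumes.  Holds the
## synonymous and nonsynonymous site frequency spectra (SFS), the fractional
## site opportunities Ls/Ln, and the divergence counts Ds/Dn, for a sample of
## n chromosomes.

#' Construct a spectrum set
#'
#' A spectrum set bundles everything a McDonald-Kreitman-style DFE fit needs
#' for one unit of analysis (a gene, a category of genes, or a set of residue
#' sites): the synonymous and nonsynonymous site frequency spectra for a
#' sample of `n` chromosomes, the fractional synonymous/nonsynonymous site
#' opportunities `Ls`/`Ln`, and the synonymous/nonsynonymous substitution
#' counts `Ds`/`Dn` relative to an outgroup.
#'
#' The SFS vectors have length `n - 1`; entry `i` counts sites whose derived
#' allele was observed in `i` copies.  For a folded spectrum entries above
#' `floor(n/2)` are zero.
#'
#' @param n sample size in chromosomes (>= 2).
#' @param Ls,Ln synonymous / nonsynonymous site opportunities (fractional
#'   sites, >= 0).
#' @param sfs_syn,sfs_nonsyn numeric vectors of length `n - 1`, entries >= 0.
#' @param Ds,Dn synonymous / nonsynonymous divergence counts (>= 0).
#' @param folded logical; is the SFS folded?
#' @param name optional label.
#' @return An object of class `spectrum_set`.
#' @export
#' @examples
#' spectrum_set(n = 4, Ls = 100, Ln = 300, sfs_syn = c(5, 2, 1),
#'              sfs_nonsyn = c(8, 1, 0), Ds = 10, Dn = 4)
spectrum_set <- function(n, Ls, Ln, sfs_syn, sfs_nonsyn, Ds = 0, Dn = 0,
                         folded = FALSE, name = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  stopifnot_scalar_count(Ls, "Ls"); stopifnot_scalar_count(Ln, "Ln")
  stopifnot_scalar_count(Ds, "Ds"); stopifnot_scalar_count(Dn, "Dn")
  sfs_syn <- as.numeric(sfs_syn); sfs_nonsyn <- as.numeric(sfs_nonsyn)
  if (length(sfs_syn) != n - 1L || length(sfs_nonsyn) != n - 1L)
    stop("SFS vectors must have length n - 1")
  if (any(sfs_syn < 0) || any(sfs_nonsyn < 0))
    stop("SFS entries must be non-negative")
  if (folded && n > 2L) {
    hi <- seq.int(floor(n / 2) + 1L, n - 1L)
    if (length(hi) && (any(sfs_syn[hi] != 0) || any(sfs_nonsyn[hi] != 0)))
      stop("folded SFS must be zero above floor(n/2)")
  }
  structure(list(n = n, Ls = Ls, Ln = Ln, sfs_syn = sfs_syn,
                 sfs_nonsyn = sfs_nonsyn, Ds = Ds, Dn = Dn,
                 folded = isTRUE(folded), name = name),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Spectrum set%s: n = %d chromosomes (%s)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$n, if (x$folded) "folded" else "unfolded"))
  cat(sprintf("  Ls = %.2f, Ln = %.2f; Ds = %g, Dn = %g\n",
              x$Ls, x$Ln, x$Ds, x$Dn))
  cat(sprintf("  polymorphic sites: %g syn, %g nonsyn\n",
              sum(x$sfs_syn), sum(x$sfs_nonsyn)))
  invisible(x)
}

#' Fold an unfolded site frequency spectrum
#'
#' Collapses complementary derived-count classes: `f_i = u_i + u_{n-i}` for
#' `i < n/2` and `f_{n/2} = u_{n/2}` when `n` is even.  Folding conserves the
#' total number of polymorphic sites.
#'
#' @param s an unfolded [spectrum_set()].
#' @return A folded `spectrum_set`.
#' @export
#' @examples
#' s <- spectrum_set(4, 10, 30, c(3, 2, 1), c(0, 0, 0))
#' fold_spectrum(s)$sfs_syn  # 4 2 0
fold_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$folded) stop("spectrum is already folded")
  fold1 <- function(u) {
    n <- length(u) + 1L
    f <- numeric(n - 1L)
    for (i in seq_len(n - 1L)) {
      j <- n - i
      if (i < j) f[i] <- u[i] + u[j]
      else if (i == j) f[i] <- u[i]
    }
    f
  }
  spectrum_set(s$n, s$Ls, s$Ln, fold1(s$sfs_syn), fold1(s$sfs_nonsyn),
               s$Ds, s$Dn, folded = TRUE, name = s$name)
}

#' Aggregate spectrum sets by element-wise summation
#'
#' Pools per-gene (or per-site-set) spectra into a category-level spectrum:
#' SFS vectors, opportunities and divergence counts are summed.  All inputs
#' must share the same sample size and folded flag.
#'
#' @param spectra a list of [spectrum_set()] objects.
#' @param name optional label for the aggregate.
#' @return A single `spectrum_set`.
#' @export
aggregate_spectra <- function(spectra, name = NULL) {
  if (inherits(spectra, "spectrum_set")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "spectrum_set")))
  n <- spectra[[1L]]$n; folded <- spectra[[1L]]$folded
  if (any(vapply(spectra, function(s) s$n, 1L) != n))
    stop("cannot aggregate spectra with different sample sizes")
  if (any(vapply(spectra, function(s) s$folded, TRUE) != folded))
    stop("cannot mix folded and unfolded spectra")
  add <- function(f) Reduce(`+`, lapply(spectra, `[[`, f))
  spectrum_set(n, add("Ls"), add("Ln"), add("sfs_syn"), add("sfs_nonsyn"),
               add("Ds"), add("Dn"), folded = folded, name = name)
}

#' Write spectrum sets in the one-line SFS dialect
#'
#' One tab-separated line per spectrum:
#' `name  n  Ln  x_1 ... x_{n-1}  Ls  s_1 ... s_{n-1}  Ln  Dn  Ls  Ds`
#' where `x_i`/`s_i` are the nonsynonymous/synonymous SFS entries.  A header
#' line starting with `#` records the column layout.  This is the dialect
#' consumed by DoFE/Grapes-style DFE fitting tools.
#'
#' @param spectra a `spectrum_set` or list thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(spectra, path) {
  if (inherits(spectra, "spectrum_set")) spectra <- list(spectra)
  lines <- vapply(spectra, function(s) {
    paste(c(s$name %||% "spectrum", s$n,
            format(c(s$Ln, s$sfs_nonsyn, s$Ls, s$sfs_syn,
                     s$Ln, s$Dn, s$Ls, s$Ds), trim = TRUE, digits = 15)),
          collapse = "\t")
  }, character(1))
  header <- "#name\tn\tLn\tsfs_nonsyn(1..n-1)\tLs\tsfs_syn(1..n-1)\tLn\tDn\tLs\tDs"
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read spectrum sets written by [write_sfs()]
#'
#' @param path file path.
#' @param folded logical flag to set on the spectra read (the dialect itself
#'   does not record it).
#' @return A list of `spectrum_set` objects, named by their labels.
#' @export
read_sfs <- function(path, folded = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    name <- f[1L]; n <- as.integer(f[2L]); v <- as.numeric(f[-(1:2)])
    m <- n - 1L
    if (length(v) != 2L * m + 6L)
      stop("malformed SFS line for '", name, "'")
    Ln <- v[1L]; x <- v[2L:(m + 1L)]
    Ls <- v[m + 2L]; s <- v[(m + 3L):(2L * m + 2L)]
    Dn <- v[2L * m + 4L]; Ds <- v[2L * m + 6L]
    spectrum_set(n, Ls, Ln, s, x, Ds, Dn, folded = folded, name = name)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Tabulate a spectrum set as a data frame
#'
#' Long-format table (one row per frequency class and mutation class) plus
#' attribute rows for opportunities and divergence; convenient for TSV export.
#'
#' @param s a [spectrum_set()].
#' @return A data frame with columns `class`, `i`, `count`.
#' @export
as.data.frame.spectrum_set <- function(x, ...) {
  s <- x
  m <- s$n - 1L
  data.frame(
    class = rep(c("syn", "nonsyn"), each = m),
    i = rep(seq_len(m), 2L),
    count = c(s$sfs_syn, s$sfs_nonsyn)
  )
}
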