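## Gene- and residue-level covariate annotation and categorization:
## relative solvent accessibility (RSA), buried/exposed classification,
## intrinsic disorder flagging, equal-count binning with a dedicated RSA = 0
## category, structure-to-sequence mapping, and Grantham conservative/radical
## substitution classes.

#' Theoretical maximum accessible surface areas (A^2) per amino acid
#'
#' Theoretical upper bounds of the solvent-accessible surface area of residue
#' X in an extended Gly-X-Gly tripeptide, used to normalize raw DSSP
#' accessibility into relative solvent accessibility.  Values follow the
#' theoretical scale of Tien et al. (2013).
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
max_asa_table <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
    H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
    T = 172, W = 285, Y = 263, V = 174)
}

#' Grantham amino-acid property indices
#'
#' Side-chain volume and polarity scales used to classify amino-acid
#' substitutions as conservative or radical.
#'
#' @return A list with named numeric vectors `volume` and `polarity`.
#' @export
grantham_indices <- function() {
  list(
    volume = c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
               G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
               P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84),
    polarity = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
                 E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
                 M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
                 Y = 6.2, V = 5.9))
}

#' Relative solvent accessibility of a residue
#'
#' `rsa = sa / max_asa[residue]`, clamped to `[0, 1]`.  Residues with letters
#' absent from the table yield `NA` with a warning (callers drop them).
#'
#' @param sa solvent-accessible area (A^2), vectorized.
#' @param residue one-letter amino-acid codes (recycled against `sa`).
#' @param max_asa per-residue normalization table, by default
#'   [max_asa_table()].
#' @return Numeric vector of RSA values in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' compute_rsa(c(50, 120), c("A", "G"))
compute_rsa <- function(sa, residue, max_asa = max_asa_table()) {
  if (any(sa < 0, na.rm = TRUE)) stop("'sa' must be non-negative")
  mx <- unname(max_asa[toupper(residue)])
  if (anyNA(mx)) {
    warning(sum(is.na(mx)), " residue(s) with unknown letter skipped")
  }
  pmin(pmax(sa / mx, 0), 1)
}

#' Classify residues as buried or exposed
#'
#' Buried if `rsa < 0.05`, exposed if `rsa >= 0.05` (strict inequality on the
#' buried side).
#'
#' @param rsa numeric vector of RSA values in `[0, 1]`.
#' @return Factor with ordered levels `buried < exposed`.
#' @export
#' @examples
#' classify_exposure(c(0, 0.049, 0.05, 0.8))
classify_exposure <- function(rsa) {
  if (any(rsa < 0 | rsa > 1, na.rm = TRUE)) stop("'rsa' must lie in [0, 1]")
  factor(ifelse(rsa < 0.05, "buried", "exposed"),
         levels = c("buried", "exposed"), ordered = TRUE)
}

#' Flag intrinsically disordered residues by the proteome-wide top quartile
#'
#' The disorder threshold is the 75th percentile (linear-interpolation
#' quantile) of all residue disorder probabilities across the proteome; a
#' residue is disordered iff its value is strictly greater than the
#' threshold.  Per-gene `prop_disordered` is the fraction of that gene's
#' residues flagged.
#'
#' @param disorder_p numeric vector of per-residue disorder probabilities.
#' @param gene_id parallel vector of gene ids (optional; enables the
#'   per-gene summary).
#' @return A list with `flag` (logical vector), `threshold`, and
#'   `prop_disordered` (named per-gene fractions; `NULL` without gene ids).
#' @export
#' @examples
#' flag_disordered(c(0.1, 0.2, 0.3, 0.4))$flag   # only the 0.4 residue
flag_disordered <- function(disorder_p, gene_id = NULL) {
  ok <- !is.na(disorder_p)
  if (sum(ok) < 4L) stop("need at least 4 residues with disorder values")
  thr <- stats::quantile(disorder_p[ok], 0.75, names = FALSE, type = 7)
  flag <- !is.na(disorder_p) & disorder_p > thr
  prop <- NULL
  if (!is.null(gene_id)) {
    prop <- tapply(flag[ok], gene_id[ok], mean)
    prop <- stats::setNames(as.numeric(prop), names(prop))
  }
  list(flag = flag, threshold = thr, prop_disordered = prop)
}

#' Assign units to ordered equal-count categories
#'
#' Quantile (equal-count) binning of a covariate.  Ties share the bin on the
#' lower-quantile side.  With `zero_special = TRUE`, units whose value is
#' exactly zero form their own first category (the totally-buried RSA = 0
#' convention), and the remaining units are split into `k - 1` equal-count
#' bins.  If ties make some bin empty, `k` is reduced with a warning.
#'
#' @param values named numeric vector (names are unit ids).
#' @param k total number of categories (>= 2).
#' @param zero_special give value-zero units their own first category.
#' @param scheme_name label for the scheme.
#' @param unit `"gene"` or `"site"` (bookkeeping only).
#' @return An object of class `category_assignment`: data frame with columns
#'   `unit` and `label` (ordered factor), plus attributes `scheme_name` and
#'   `unit_type`.
#' @export
#' @examples
#' v <- stats::setNames(c(0, 0, 0, 1:7), paste0("u", 1:10))
#' table(equal_count_bins(v, k = 3, zero_special = TRUE)$label)
equal_count_bins <- function(values, k, zero_special = FALSE,
                             scheme_name = "scheme", unit = c("gene", "site")) {
  unit <- match.arg(unit)
  stopifnot(k >= 2L, length(values) >= k)
  if (is.null(names(values))) names(values) <- seq_along(values)
  if (anyNA(values)) {
    values <- values[!is.na(values)]
  }
  lab <- rep(NA_character_, length(values))
  names(lab) <- names(values)

  if (zero_special) {
    zero <- values == 0
    if (!any(zero)) {
      warning("zero_special requested but no zero-valued units; ",
              "falling back to plain equal-count binning")
      return(equal_count_bins(values, k, FALSE, scheme_name, unit))
    }
    lab[zero] <- "C0"
    rest <- values[!zero]
    kk <- k - 1L
  } else {
    rest <- values
    kk <- k
  }

  bin_rest <- function(v, kk) {
    ## rank-based equal-count assignment; ties.method = "min" sends whole
    ## tie groups to the lower-quantile bin
    rk <- rank(v, ties.method = "min")
    bin <- floor((rk - 1) * kk / length(v)) + 1L
    bin
  }
  repeat {
    bin <- bin_rest(rest, kk)
    if (length(unique(bin)) == kk || kk <= 1L) break
    warning("ties prevent ", kk, " non-empty bins; reducing to ", kk - 1L)
    kk <- kk - 1L
  }
  lab[names(rest)] <- paste0("C", bin)

  lev <- c(if (zero_special) "C0", paste0("C", seq_len(kk)))
  out <- data.frame(unit = names(lab),
                    label = factor(lab, levels = lev, ordered = TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, scheme_name = scheme_name, unit_type = unit,
            class = c("category_assignment", "data.frame"))
}

#' Transfer structure-derived residue features onto a protein sequence
#'
#' Given a pairwise alignment between a protein sequence and the sequence of
#' its assigned structure (aligned strings of equal length, gaps `-`),
#' transfers per-residue features (indexed by structure residue) to protein
#' positions.  Features are transferred only at columns where both sequences
#' have a residue and, under the default `match = "identity"` policy, the
#' residues agree; `match = "any"` transfers at every aligned column.
#' Unmapped residues are dropped and counted.
#'
#' @param protein_aln,structure_aln aligned sequences (equal length strings).
#' @param features data frame with a `residue_index` column (0-based index
#'   into the *structure* sequence) and arbitrary feature columns.
#' @param match mismatch policy, `"identity"` or `"any"`.
#' @return `features` restricted to mapped residues, with a new 0-based
#'   `codon_index` column giving the protein position; attribute
#'   `"n_unmapped"` counts dropped structure residues.
#' @export
map_structure_to_alignment <- function(protein_aln, structure_aln, features,
                                       match = c("identity", "any")) {
  match <- match.arg(match)
  p <- strsplit(toupper(protein_aln), "")[[1L]]
  s <- strsplit(toupper(structure_aln), "")[[1L]]
  if (length(p) != length(s))
    stop("aligned sequences must have equal length")
  p_idx <- cumsum(p != "-") - 1L   # 0-based protein position per column
  s_idx <- cumsum(s != "-") - 1L   # 0-based structure position per column
  aligned <- p != "-" & s != "-"
  if (match == "identity") aligned <- aligned & p == s
  map <- stats::setNames(p_idx[aligned], s_idx[aligned])

  hit <- as.character(features$residue_index) %in% names(map)
  out <- features[hit, , drop = FALSE]
  out$codon_index <- as.integer(map[as.character(out$residue_index)])
  n_unmapped <- nrow(features) - nrow(out)
  if (nrow(out) == 0L) warning("no residues could be mapped")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Classify an amino-acid change as conservative or radical
#'
#' Uses the absolute differences of the Grantham volume and polarity indices:
#' a change is radical iff either difference exceeds its cutoff.  Default
#' cutoffs are the midpoint of each index's range.  Classification is
#' symmetric in its arguments.
#'
#' @param aa_from,aa_to standard one-letter amino-acid codes (vectorized).
#' @param cutoffs named numeric vector `c(volume = , polarity = )`.
#' @return Character vector, `"conservative"` or `"radical"`.
#' @export
#' @examples
#' grantham_class("A", "W")   # radical (large volume difference)
#' grantham_class("I", "L")   # conservative
grantham_class <- function(aa_from, aa_to, cutoffs = NULL) {
  idx <- grantham_indices()
  if (is.null(cutoffs)) {
    cutoffs <- c(volume = diff(range(idx$volume)) / 2,
                 polarity = diff(range(idx$polarity)) / 2)
  }
  aa_from <- toupper(aa_from); aa_to <- toupper(aa_to)
  if (!all(c(aa_from, aa_to) %in% names(idx$volume)))
    stop("nonstandard amino-acid letter")
  dv <- abs(idx$volume[aa_from] - idx$volume[aa_to])
  dp <- abs(idx$polarity[aa_from] - idx$polarity[aa_to])
  unname(ifelse(dv > cutoffs[["volume"]] | dp > cutoffs[["polarity"]],
                "radical", "conservative"))
}

#' Read a per-residue structural feature table
#'
#' Tab-separated with a header; expected columns: `gene_id`,
#' `residue_index` (0-based), one of `rsa` or (`sa` + `residue`), and
#' optionally `ss` (`sheet`/`helix`/`loop`), `disorder_p`, `active_site`.
#' When raw accessibility `sa` is given, RSA is derived with
#' [compute_rsa()].
#'
#' @param path TSV file path.
#' @param max_asa normalization table for [compute_rsa()].
#' @return Data frame of residue features with an `rsa` column.
#' @export
read_residue_features <- function(path, max_asa = max_asa_table()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "residue_index")
  if (!all(need %in% names(d)))
    stop("residue feature table must contain columns: ",
         paste(need, collapse = ", "))
  if (!"rsa" %in% names(d)) {
    if (!all(c("sa", "residue") %in% names(d)))
      stop("need either an 'rsa' column or 'sa' plus 'residue'")
    d$rsa <- compute_rsa(d$sa, d$residue, max_asa)
  }
  d
}

#' Read a per-gene covariate table
#'
#' Tab-separated with a header; must contain `gene_id`, other columns are
#' covariates used by categorization schemes.
#'
#' @param path TSV file path.
#' @return Data frame of gene covariates.
#' @export
read_gene_features <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d))
    stop("gene feature table must contain a 'gene_id' column")
  d
}

#' Write a category assignment as TSV
#'
#' @param assignment a `category_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_category_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "category_assignment"))
  d <- data.frame(unit = assignment$unit,
                  label = as.character(assignment$label),
                  scheme = attr(assignment, "scheme_name"),
                  unit_type = attr(assignment, "unit_type"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate per-unit spectra into per-category spectra
#'
#' @param assignment a [equal_count_bins()] result (or any
#'   `category_assignment`).
#' @param spectra named list of [spectrum_set()] objects, names matching
#'   `assignment$unit`.
#' @return Named list (one `spectrum_set` per category label, in label
#'   order).  Units lacking a spectrum are excluded with a warning.
#' @export
category_spectra <- function(assignment, spectra) {
  stopifnot(inherits(assignment, "category_assignment"))
  miss <- !(assignment$unit %in% names(spectra))
  if (any(miss)) {
    warning(sum(miss), " unit(s) lack a spectrum and were excluded")
    assignment <- assignment[!miss, , drop = FALSE]
  }
  labs <- levels(assignment$label)
  out <- lapply(labs, function(lb) {
    ids <- assignment$unit[assignment$label == lb]
    if (!length(ids)) return(NULL)
    aggregate_spectra(spectra[ids], name = lb)
  })
  names(out) <- labs
  out[!vapply(out, is.null, TRUE)]
}
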