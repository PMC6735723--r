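## Building site frequency spectra from per-gene codon alignments
## (ingroup chromosomes plus one outgroup sequence).
##
## Site opportunities follow Nei-Gojobori fractional counting; mutations to
## stop codons are excluded from both the synonymous and nonsynonymous
## classes.  Polymorphisms are polarized against the outgroup allele; sites
## that cannot be polarized, contain missing data, or segregate at more than
## one nucleotide position of a codon are excluded with a reason code.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a codon alignment
#'
#' Equal-length, in-frame nucleotide sequences for one gene: an ingroup
#' sample of chromosomes plus a single outgroup sequence used to polarize
#' polymorphisms and count substitutions.  Alphabet is restricted to
#' `A C G T N -`.
#'
#' @param gene_id gene label.
#' @param ingroup character vector of ingroup sequences (>= 2).
#' @param outgroup single outgroup sequence of the same length.
#' @param genetic_code a named character vector mapping codons to amino
#'   acids, as returned by [Biostrings::getGeneticCode()]; defaults to the
#'   standard code.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, ingroup, outgroup,
                            genetic_code = Biostrings::GENETIC_CODE) {
  ingroup <- toupper(as.character(ingroup))
  outgroup <- toupper(as.character(outgroup))
  if (length(outgroup) != 1L) stop("exactly one outgroup sequence required")
  if (length(ingroup) < 2L) stop("need at least two ingroup sequences")
  len <- unique(nchar(c(ingroup, outgroup)))
  if (length(len) != 1L) stop("all sequences must have equal length")
  if (len %% 3L != 0L) stop("alignment length must be divisible by 3")
  chars <- unique(strsplit(paste(c(ingroup, outgroup), collapse = ""), "")[[1L]])
  bad <- setdiff(chars, c(VALID_BASES, "N", "-"))
  if (length(bad))
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  structure(list(gene_id = gene_id, ingroup = ingroup, outgroup = outgroup,
                 genetic_code = genetic_code, n_codons = len %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment '%s': %d ingroup chromosomes + outgroup, %d codons\n",
              x$gene_id, length(x$ingroup), x$n_codons))
  invisible(x)
}

#' Read per-gene codon alignments from FASTA
#'
#' The record whose id matches `outgroup_tag` (exactly, or as a prefix before
#' whitespace or `|`) is taken as the outgroup; all other records form the
#' ingroup sample.
#'
#' @param path FASTA file with the aligned sequences of one gene.
#' @param outgroup_tag id of the outgroup record (default `"outgroup"`).
#' @param gene_id gene label; defaults to the file name without extension.
#' @inheritParams codon_alignment
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, outgroup_tag = "outgroup",
                                 gene_id = NULL,
                                 genetic_code = Biostrings::GENETIC_CODE) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[ |]"), `[[`, character(1), 1L)
  is_out <- ids == outgroup_tag
  if (sum(is_out) != 1L)
    stop("expected exactly one record tagged '", outgroup_tag, "' in ", path)
  gene_id <- gene_id %||% sub("\\.[^.]*$", "", basename(path))
  codon_alignment(gene_id,
                  ingroup = as.character(seqs[!is_out]),
                  outgroup = as.character(seqs[is_out]),
                  genetic_code = genetic_code)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @param outgroup_tag id to give the outgroup record.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path, outgroup_tag = "outgroup") {
  ids <- c(paste0(aln$gene_id, "_", seq_along(aln$ingroup)), outgroup_tag)
  lines <- as.vector(rbind(paste0(">", ids), c(aln$ingroup, aln$outgroup)))
  writeLines(lines, path)
  invisible(path)
}

is_stop <- function(codon, code) {
  !is.na(code[codon]) & code[codon] == "*"
}

#' Nei-Gojobori site opportunities of one codon
#'
#' Enumerates the nine single-base changes of the codon and counts the
#' fraction at each position that is synonymous versus nonsynonymous.
#' Changes producing a stop codon are excluded from both classes, so
#' `syn + nonsyn = 3 - (stop changes)/3`.
#'
#' @param codon a 3-letter codon string (no `N` or gaps, not a stop codon).
#' @inheritParams codon_alignment
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @export
#' @examples
#' codon_opportunities("TTT")  # syn 1/3, nonsyn 8/3
#' codon_opportunities("GGG")  # syn 1,   nonsyn 2
codon_opportunities <- function(codon, genetic_code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  bases <- strsplit(codon, "")[[1L]]
  if (length(bases) != 3L || !all(bases %in% VALID_BASES))
    stop("codon must be a 3-mer over ACGT")
  aa <- genetic_code[[codon]]
  if (is.na(aa) || aa == "*") stop("stop codon has no defined opportunities")
  syn <- 0; nonsyn <- 0
  for (p in 1:3) {
    for (b in setdiff(VALID_BASES, bases[p])) {
      alt <- bases; alt[p] <- b
      alt_aa <- genetic_code[[paste(alt, collapse = "")]]
      if (alt_aa == "*") next         # mutation to stop: excluded
      if (alt_aa == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}

## One SiteRecord: the per-codon-site decomposition behind the SFS.
site_record <- function(gene_id, codon_index, status,
                        position_in_codon = NA_integer_,
                        syn_opportunity = NA_real_,
                        nonsyn_opportunity = NA_real_,
                        derived_count = NA_integer_, sample_size = NA_integer_,
                        reason = NA_character_) {
  list(gene_id = gene_id, codon_index = codon_index,
       position_in_codon = position_in_codon,
       syn_opportunity = syn_opportunity,
       nonsyn_opportunity = nonsyn_opportunity,
       status = status, derived_count = derived_count,
       sample_size = sample_size, reason = reason)
}

#' Classify one codon column of an alignment
#'
#' Given the ingroup codons and the outgroup codon at one codon index,
#' decides whether the site is monomorphic, a synonymous or nonsynonymous
#' polymorphism (typed by whether the amino acid changes), a fixed
#' synonymous or nonsynonymous difference to the outgroup, or excluded.
#' The derived allele is the ingroup allele differing from the outgroup
#' allele.
#'
#' Exclusion reason codes: `ingroup_missing` (N or gap in an ingroup codon),
#' `outgroup_missing`, `stop_codon`, `multi_hit` (two or more ingroup-
#' segregating positions in the codon), `multi_allelic` (three or more
#' alleles at one position), `polarization` (outgroup allele matches neither
#' ingroup allele), `multi_hit_divergence` (outgroup differs at two or more
#' positions of a monomorphic codon).  A polymorphic codon whose outgroup
#' differs additionally at a non-segregating position is counted as
#' polymorphic only; the extra divergence is discarded.
#'
#' @param ingroup_codons character vector of ingroup codons at the site.
#' @param outgroup_codon the outgroup codon.
#' @param gene_id,codon_index bookkeeping labels carried into the record.
#' @inheritParams codon_alignment
#' @return A site record (list) with fields `status`, `position_in_codon`,
#'   `syn_opportunity`, `nonsyn_opportunity`, `derived_count`,
#'   `sample_size`, `reason`.
#' @export
#' @examples
#' classify_codon_site(c("TTT", "TTT", "TTT", "TTC"), "TTT")$status
classify_codon_site <- function(ingroup_codons, outgroup_codon,
                                gene_id = NA_character_, codon_index = NA_integer_,
                                genetic_code = Biostrings::GENETIC_CODE) {
  m <- length(ingroup_codons)
  rec <- function(status, ...) site_record(gene_id, codon_index, status, ...)
  if (any(grepl("[N-]", ingroup_codons)))
    return(rec("excluded", reason = "ingroup_missing"))
  if (grepl("[N-]", outgroup_codon))
    return(rec("excluded", reason = "outgroup_missing"))
  if (any(is_stop(ingroup_codons, genetic_code)) ||
      is_stop(outgroup_codon, genetic_code))
    return(rec("excluded", reason = "stop_codon"))

  opp_mat <- vapply(ingroup_codons, codon_opportunities, numeric(2),
                    genetic_code = genetic_code)
  syn_opp <- mean(opp_mat["syn", ]); nonsyn_opp <- mean(opp_mat["nonsyn", ])

  in_mat <- do.call(rbind, strsplit(ingroup_codons, ""))
  out_b <- strsplit(outgroup_codon, "")[[1L]]
  seg_pos <- which(apply(in_mat, 2L, function(col) length(unique(col)) > 1L))

  if (length(seg_pos) >= 2L)
    return(rec("excluded", reason = "multi_hit",
               syn_opportunity = syn_opp, nonsyn_opportunity = nonsyn_opp))

  if (length(seg_pos) == 0L) {
    ## monomorphic ingroup; check divergence to outgroup
    cod <- ingroup_codons[1L]
    diff_pos <- which(in_mat[1L, ] != out_b)
    if (length(diff_pos) == 0L)
      return(rec("monomorphic", syn_opportunity = syn_opp,
                 nonsyn_opportunity = nonsyn_opp, sample_size = m))
    if (length(diff_pos) >= 2L)
      return(rec("excluded", reason = "multi_hit_divergence",
                 syn_opportunity = syn_opp, nonsyn_opportunity = nonsyn_opp))
    syn <- genetic_code[[cod]] == genetic_code[[outgroup_codon]]
    return(rec(if (syn) "divergent_syn" else "divergent_nonsyn",
               position_in_codon = diff_pos - 1L, syn_opportunity = syn_opp,
               nonsyn_opportunity = nonsyn_opp, sample_size = m))
  }

  ## exactly one segregating position
  p <- seg_pos
  alleles <- unique(in_mat[, p])
  if (length(alleles) > 2L)
    return(rec("excluded", reason = "multi_allelic",
               syn_opportunity = syn_opp, nonsyn_opportunity = nonsyn_opp))
  if (!(out_b[p] %in% alleles))
    return(rec("excluded", reason = "polarization",
               syn_opportunity = syn_opp, nonsyn_opportunity = nonsyn_opp))
  derived_base <- setdiff(alleles, out_b[p])
  derived_count <- sum(in_mat[, p] == derived_base)
  cods <- unique(ingroup_codons)
  syn <- genetic_code[[cods[1L]]] == genetic_code[[cods[2L]]]
  rec(if (syn) "polymorphic_syn" else "polymorphic_nonsyn",
      position_in_codon = p - 1L, syn_opportunity = syn_opp,
      nonsyn_opportunity = nonsyn_opp,
      derived_count = as.integer(derived_count), sample_size = m)
}

#' Hypergeometric down-sampling of a polymorphic site
#'
#' Projects a site observed in `m` chromosomes with `d` derived copies onto a
#' smaller sample of `n_target` chromosomes.  `mode = "random"` draws one
#' down-sampled derived count (sampling without replacement); `mode =
#' "expected"` returns the exact hypergeometric probability vector over
#' derived counts `0..n_target`.  Projected counts of 0 or `n_target` are no
#' longer polymorphic and contribute nothing to the SFS.
#'
#' @param m observed sample size.
#' @param d observed derived count (`0 <= d <= m`).
#' @param n_target target sample size (`<= m`).
#' @param mode `"random"` or `"expected"`.
#' @param seed optional seed for random mode.
#' @return An integer (random mode) or a named probability vector over
#'   `0..n_target` (expected mode).
#' @export
#' @examples
#' project_site(4, 2, 2, mode = "expected")  # 1/6, 4/6, 1/6
project_site <- function(m, d, n_target, mode = c("random", "expected"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (n_target > m) stop("n_target exceeds observed sample size")
  if (d < 0 || d > m) stop("derived count out of range")
  if (mode == "expected") {
    p <- stats::dhyper(0:n_target, d, m - d, n_target)
    names(p) <- 0:n_target
    return(p)
  }
  with_seed(seed, as.integer(stats::rhyper(1L, d, m - d, n_target)))
}

#' Build the spectrum set of one codon alignment
#'
#' Walks every codon column, classifies it (see [classify_codon_site()]),
#' accumulates Nei-Gojobori opportunities over retained sites into `Ls`/`Ln`,
#' fills the synonymous and nonsynonymous unfolded SFS from (optionally
#' down-sampled) derived counts, and counts fixed differences into `Ds`/`Dn`.
#'
#' Gene-level filter: any premature stop codon in a fully resolved ingroup
#' codon aborts with an error (such genes are excluded from analysis); a
#' terminal stop codon column is silently dropped.  Sites both polymorphic
#' and divergent are counted as polymorphic only.
#'
#' @param aln a [codon_alignment()].
#' @param n_target sample size to project down to; default the full ingroup
#'   sample size.  Polymorphic sites are projected with [project_site()].
#' @param mode projection mode, `"random"` (seeded) or `"expected"`
#'   (deterministic fractional SFS).
#' @param seed seed for random projection.
#' @return A `spectrum_set` with attribute `"exclusions"`, a named count of
#'   exclusion reasons.
#' @export
build_spectrum <- function(aln, n_target = NULL, mode = "random", seed = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- aln$genetic_code
  nc <- aln$n_codons
  m <- length(aln$ingroup)
  n_target <- as.integer(n_target %||% m)
  if (n_target > m) stop("n_target exceeds the ingroup sample size")
  if (n_target < 2L) stop("n_target must be >= 2")

  codons_at <- function(seqs, j) substr(seqs, 3L * j - 2L, 3L * j)

  ## gene filter: premature stop in any resolved ingroup codon
  if (nc > 1L) {
    for (j in seq_len(nc - 1L)) {
      cods <- codons_at(aln$ingroup, j)
      resolved <- !grepl("[N-]", cods)
      if (any(resolved & is_stop(cods, code)))
        stop("premature stop codon in gene '", aln$gene_id,
             "' at codon index ", j - 1L)
    }
  }

  Ls <- 0; Ln <- 0; Ds <- 0; Dn <- 0
  sfs_syn <- numeric(n_target - 1L); sfs_nonsyn <- numeric(n_target - 1L)
  exclusions <- integer(0)

  keep <- seq_len(nc)
  last <- codons_at(aln$ingroup, nc)
  if (all(!grepl("[N-]", last)) && all(is_stop(last, code)))
    keep <- keep[-nc]                     # terminal stop column

  proj_seed <- if (is.null(seed)) NULL else child_seed(seed, aln$gene_id)
  res <- with_seed(proj_seed, {
    for (j in keep) {
      rec <- classify_codon_site(codons_at(aln$ingroup, j),
                                 codons_at(aln$outgroup, j),
                                 gene_id = aln$gene_id, codon_index = j - 1L,
                                 genetic_code = code)
      if (rec$status == "excluded") {
        cur <- exclusions[rec$reason]
        exclusions[rec$reason] <- if (is.na(cur)) 1L else cur + 1L
        next
      }
      Ls <- Ls + rec$syn_opportunity
      Ln <- Ln + rec$nonsyn_opportunity
      if (rec$status == "divergent_syn") Ds <- Ds + 1
      if (rec$status == "divergent_nonsyn") Dn <- Dn + 1
      if (rec$status %in% c("polymorphic_syn", "polymorphic_nonsyn")) {
        syn <- rec$status == "polymorphic_syn"
        if (mode == "expected" && n_target < m) {
          p <- stats::dhyper(0:n_target, rec$derived_count,
                             m - rec$derived_count, n_target)
          contrib <- p[2:n_target]        # classes 1..n_target-1
          if (syn) sfs_syn <- sfs_syn + contrib
          else sfs_nonsyn <- sfs_nonsyn + contrib
        } else {
          d <- if (n_target < m)
            as.integer(stats::rhyper(1L, rec$derived_count,
                                     m - rec$derived_count, n_target))
          else rec$derived_count
          if (d >= 1L && d <= n_target - 1L) {
            if (syn) sfs_syn[d] <- sfs_syn[d] + 1
            else sfs_nonsyn[d] <- sfs_nonsyn[d] + 1
          }
        }
      }
    }
    list(Ls = Ls, Ln = Ln, Ds = Ds, Dn = Dn,
         sfs_syn = sfs_syn, sfs_nonsyn = sfs_nonsyn, exclusions = exclusions)
  })

  if (res$Ls + res$Ln == 0)
    warning("no sites retained for gene '", aln$gene_id, "'")
  out <- spectrum_set(n_target, res$Ls, res$Ln, res$sfs_syn, res$sfs_nonsyn,
                      res$Ds, res$Dn, folded = FALSE, name = aln$gene_id)
  attr(out, "exclusions") <- res$exclusions
  out
}
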