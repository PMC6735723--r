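## Codon opportunities, site classification, projection, spectrum assembly.

test_that("Nei-Gojobori opportunities match enumeration of single-base changes", {
  expect_equal(codon_opportunities("TTT"),
               c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_equal(codon_opportunities("ATG"), c(syn = 0, nonsyn = 3))
  expect_equal(codon_opportunities("GGG"), c(syn = 1, nonsyn = 2))
  expect_error(codon_opportunities("TAA"), "stop")
  expect_error(codon_opportunities("TNT"), "ACGT")
})

test_that("opportunities sum to 3 minus the stop-excluded fraction", {
  code <- Biostrings::GENETIC_CODE
  codons <- setdiff(names(code), names(code)[code == "*"])
  for (cod in codons) {
    o <- codon_opportunities(cod)
    b <- strsplit(cod, "")[[1L]]
    n_stop <- 0
    for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
      cb <- b; cb[p] <- alt
      if (code[[paste(cb, collapse = "")]] == "*") n_stop <- n_stop + 1
    }
    expect_equal(sum(o), 3 - n_stop / 3, tolerance = 1e-12)
  }
})

test_that("codon columns are classified and polarized against the outgroup", {
  r <- classify_codon_site(c("TTT", "TTT", "TTT", "TTC"), "TTT")
  expect_equal(r$status, "polymorphic_syn")
  expect_equal(r$derived_count, 1L)
  expect_equal(r$sample_size, 4L)
  expect_equal(r$position_in_codon, 2L)

  expect_equal(classify_codon_site(rep("TTT", 4), "TTC")$status,
               "divergent_syn")
  expect_equal(classify_codon_site(rep("TTT", 4), "ATT")$status,
               "divergent_nonsyn")
  expect_equal(classify_codon_site(rep("TTT", 4), "TTT")$status,
               "monomorphic")

  ## nonsynonymous polymorphism typed by the amino-acid change
  r <- classify_codon_site(c("ATT", "ATT", "GTT", "GTT"), "ATT")
  expect_equal(r$status, "polymorphic_nonsyn")
  expect_equal(r$derived_count, 2L)
})

test_that("unresolvable codon columns are excluded with reason codes", {
  expect_equal(classify_codon_site(rep("TTT", 4), "T-T")$reason,
               "outgroup_missing")
  expect_equal(classify_codon_site(c("TNT", rep("TTT", 3)), "TTT")$reason,
               "ingroup_missing")
  ## three alleles at one position
  expect_equal(classify_codon_site(c("ATT", "CTT", "GTT", "ATT"),
                                   "ATT")$reason, "multi_allelic")
  ## two segregating positions
  expect_equal(classify_codon_site(c("ATT", "ATC", "GTT", "GTT"),
                                   "ATT")$reason, "multi_hit")
  ## outgroup matches neither ingroup allele at the segregating position
  expect_equal(classify_codon_site(c("ATT", "ATT", "GTT", "GTT"),
                                   "CTT")$reason, "polarization")
  ## stop codon in the column
  expect_equal(classify_codon_site(rep("TAA", 4), "TAA")$reason,
               "stop_codon")
})

test_that("a polymorphic codon with extra outgroup divergence counts as polymorphic only", {
  ## segregating at position 3 (syn), outgroup also differs at position 1
  r <- classify_codon_site(c("TTT", "TTT", "TTC", "TTC"), "CTT")
  expect_equal(r$status, "polymorphic_syn")
  expect_equal(r$derived_count, 2L)
})

test_that("hypergeometric projection matches exact enumeration", {
  p <- project_site(4, 2, 2, mode = "expected")
  expect_equal(unname(p), c(1 / 6, 4 / 6, 1 / 6))
  expect_equal(unname(project_site(4, 0, 2, mode = "expected")), c(1, 0, 0))
  expect_equal(unname(project_site(5, 5, 3, mode = "expected")),
               c(0, 0, 0, 1))
  expect_error(project_site(4, 2, 6), "exceeds")
})

test_that("random projection preserves the expected-mode distribution", {
  set.seed(11)
  draws <- replicate(1e4, project_site(6, 3, 4, mode = "random"))
  expected <- project_site(6, 3, 4, mode = "expected")
  emp <- tabulate(draws + 1L, nbins = 5L) / 1e4
  mc_se <- sqrt(expected * (1 - expected) / 1e4)
  expect_true(all(abs(emp - expected) <= 3 * mc_se + 1e-12))
  ## mean is conserved exactly in expectation
  expect_equal(mean(draws), sum(0:4 * expected), tolerance = 0.05)
})

test_that("build_spectrum reproduces the hand-computed single-gene spectrum", {
  aln <- tiny_alignment()
  s <- build_spectrum(aln)
  ## codon opportunities: TTT/TTC (1/3, 8/3), ATG (0, 3), GGG (1, 2),
  ## AAA (1/3, 7/3): the AAA -> TAA change is a stop and excluded
  expect_equal(s$Ls, 1 / 3 + 0 + 1 + 1 / 3)
  expect_equal(s$Ln, 8 / 3 + 3 + 2 + 7 / 3)
  expect_equal(s$sfs_syn, c(1, 0, 0))
  expect_equal(s$sfs_nonsyn, c(0, 0, 0))
  expect_equal(s$Ds, 0); expect_equal(s$Dn, 0)

  ## fixed nonsynonymous difference
  aln2 <- codon_alignment("g2", rep("ATGAAA", 4), "ATGACA")
  s2 <- build_spectrum(aln2)
  expect_equal(s2$Dn, 1); expect_equal(s2$Ds, 0)
})

test_that("premature stop codons abort the gene; terminal stop is dropped", {
  expect_error(build_spectrum(codon_alignment("bad", rep("TAAAAA", 3),
                                              "TAAAAA")),
               "premature stop")
  s <- build_spectrum(codon_alignment("ok", rep("AAATAA", 3), "AAATAA"))
  expect_equal(s$Ls + s$Ln, 3 - 1 / 3)   # only the AAA codon counted
})

test_that("down-sampling projection fills the spectrum deterministically", {
  aln <- tiny_alignment()
  s1 <- build_spectrum(aln, n_target = 3, seed = 5)
  s2 <- build_spectrum(aln, n_target = 3, seed = 5)
  expect_identical(s1, s2)
  se <- build_spectrum(aln, n_target = 3, mode = "expected")
  ## derived count 1 of 4 projected to 3: P(1 of 3) = C(3,2)/C(4,3) = 3/4
  expect_equal(se$sfs_syn, c(3 / 4, 0))
})

test_that("folding collapses complementary classes and conserves totals", {
  s <- spectrum_set(4, 10, 30, c(3, 2, 1), c(1, 1, 1))
  f <- fold_spectrum(s)
  expect_equal(f$sfs_syn, c(4, 2, 0))
  expect_equal(sum(f$sfs_syn), sum(s$sfs_syn))
  s5 <- spectrum_set(5, 10, 30, c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(fold_spectrum(s5)$sfs_syn, c(5, 5, 0, 0))
  expect_error(fold_spectrum(f), "already folded")
  z <- fold_spectrum(spectrum_set(4, 1, 3, c(0, 0, 0), c(0, 0, 0)))
  expect_equal(z$sfs_syn, c(0, 0, 0))
})

test_that("aggregation sums every field and checks compatibility", {
  x <- simple_spectrum()
  expect_equal(aggregate_spectra(list(x))$sfs_syn, x$sfs_syn)
  two <- aggregate_spectra(list(x, x))
  expect_equal(two$Ls, 2 * x$Ls)
  expect_equal(two$sfs_nonsyn, 2 * x$sfs_nonsyn)
  expect_equal(two$Dn, 2 * x$Dn)
  y <- spectrum_set(5, 1, 3, rep(0, 4), rep(0, 4))
  expect_error(aggregate_spectra(list(x, y)), "sample sizes")
})

test_that("per-gene spectra sum to the spectrum of the concatenated genes", {
  a1 <- tiny_alignment()
  a2 <- codon_alignment("g2", rep("ATGAAA", 4), "ATGACA")
  concat <- codon_alignment("cat",
                            paste0(a1$ingroup, a2$ingroup),
                            paste0(a1$outgroup, a2$outgroup))
  s_sum <- aggregate_spectra(list(build_spectrum(a1), build_spectrum(a2)))
  s_cat <- build_spectrum(concat)
  for (f in c("Ls", "Ln", "Ds", "Dn", "sfs_syn", "sfs_nonsyn"))
    expect_equal(s_sum[[f]], s_cat[[f]])
})

test_that("the shipped example alignment reproduces its expected spectrum", {
  fa <- system.file("extdata", "planted_gene.fasta", package = "adaptrate")
  sfs <- system.file("extdata", "planted_gene_expected.sfs",
                     package = "adaptrate")
  aln <- read_codon_alignment(fa, gene_id = "fix_planted")
  got <- build_spectrum(aln)
  want <- read_sfs(sfs)[["fix_planted"]]
  expect_equal(got$Ls, want$Ls)
  expect_equal(got$Ln, want$Ln)
  expect_equal(got$sfs_syn, want$sfs_syn)
  expect_equal(got$sfs_nonsyn, want$sfs_nonsyn)
  expect_equal(got$Ds, want$Ds)
  expect_equal(got$Dn, want$Dn)
})

test_that("FASTA and one-line SFS dialect round-trip", {
  aln <- tiny_alignment()
  fa <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln, fa)
  back <- read_codon_alignment(fa, gene_id = "tiny")
  expect_equal(back$ingroup, aln$ingroup)
  expect_equal(back$outgroup, aln$outgroup)

  s <- build_spectrum(aln)
  tf <- tempfile(fileext = ".sfs")
  write_sfs(list(s, simple_spectrum()), tf)
  back <- read_sfs(tf)
  expect_equal(length(back), 2L)
  expect_equal(back[["tiny"]]$sfs_syn, s$sfs_syn)
  expect_equal(back[["tiny"]]$Ls, s$Ls)
  expect_equal(back[["s1"]]$Dn, 4)
})
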