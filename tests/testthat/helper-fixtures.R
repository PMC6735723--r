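## Shared fixtures built in code.

## A 4-chromosome, 4-codon alignment with one planted synonymous
## polymorphism (derived count 1), hand-checkable against the examples.
tiny_alignment <- function() {
  ## codons: TTT (poly syn TTT/TTC), ATG, GGG, AAA; outgroup identical
  ingroup <- c("TTCATGGGGAAA", "TTTATGGGGAAA", "TTTATGGGGAAA",
               "TTTATGGGGAAA")
  codon_alignment("tiny", ingroup, "TTTATGGGGAAA")
}

## Spectrum sets with simple integer content for aggregation tests.
simple_spectrum <- function(name = "s1", scale = 1) {
  spectrum_set(4, 10 * scale, 30 * scale,
               scale * c(5, 2, 1), scale * c(8, 1, 0),
               Ds = 10 * scale, Dn = 4 * scale, name = name)
}

## Crafted bootstrap_result with controllable replicate tables.
crafted_bootstrap <- function(mean_del, shape, label = "A") {
  B <- length(mean_del)
  reps <- data.frame(ok = TRUE, loglik = 0, aic = 0, theta = 1,
                     shape = shape, mean_del = mean_del, p_b = 0,
                     mean_ben = NA_real_, omega = 0.2, omega_na = 0.1,
                     omega_a = 0.1, alpha = 0.5)
  structure(list(scheme = label,
                 point = reps[1L, , drop = FALSE],
                 replicates = stats::setNames(list(reps), label),
                 B = B, retained = stats::setNames(B, label)),
            class = "bootstrap_result")
}
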