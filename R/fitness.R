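# Relative viabilities of the hybrid classes. Residents and migrants (the two
# pure strains) always have fitness 1; hybrids pay for carrying incompatible
# combinations. Fitness is sex-independent in every model.

#' Relative fitness of a genotype
#'
#' Evaluates the model's fitness table. Pure strains have fitness 1; hybrid
#' genotypes combining incompatible alleles are reduced:
#'
#' * Model A: mt1-N2 has fitness `1 - s1`, mt2-N1 has `1 - s2`.
#' * Model B: A2-B1 has `1 - sA`, A1-B2 has `1 - sB`.
#' * Model C: on the mt1 background N1N2 has `1 - h1*s1` and N2N2 `1 - s1`;
#'   on the mt2 background N1N1 has `1 - s2` and N1N2 `1 - h2*s2`.
#' * Model D (asymmetric): only A2-carrying hybrids suffer -- A2A2 B1B1 has
#'   `1 - sA`; every other genotype carrying at least one A2 together with at
#'   least one B1 has `1 - hA*sA`; the A1A1 row and the B2B2 column (off the
#'   A2A2 B1B1 corner) are unaffected.
#' * Model D (symmetric): the recombinant double homozygotes A1A1 B2B2 and
#'   A2A2 B1B1 have `1 - s`; every genotype heterozygous at either locus has
#'   `1 - h*s`.
#'
#' @param params An [incompatibility_model()].
#' @param g A [genotype()] of the same model.
#' @return A single number in `[0, 1]`.
#' @examples
#' m <- incompatibility_model("A", s1 = 0.3)
#' genotype_fitness(m, genotype("A", "female", cyto = 1, n = 2))
#' @export
genotype_fitness <- function(params, g) {
  stopifnot(inherits(params, "incompatibility_model"), inherits(g, "genotype"))
  if (!identical(params$model, g$model)) {
    stop(sprintf("genotype of Model %s passed to Model %s parameters",
                 g$model, params$model))
  }
  switch(params$model,
    A = {
      if (g$cyto == 1 && g$n == 2) 1 - params$s1
      else if (g$cyto == 2 && g$n == 1) 1 - params$s2
      else 1
    },
    B = {
      if (g$a == 2 && g$b == 1) 1 - params$sA
      else if (g$a == 1 && g$b == 2) 1 - params$sB
      else 1
    },
    C = {
      k <- sum(g$n == 2L) # copies of N2
      if (g$cyto == 1) c(1, 1 - params$h1 * params$s1, 1 - params$s1)[k + 1]
      else c(1 - params$s2, 1 - params$h2 * params$s2, 1)[k + 1]
    },
    D = {
      i <- sum(g$a == 2L)
      j <- sum(g$b == 2L)
      if (params$d_variant == "asymmetric") {
        if (i == 0) 1
        else if (i == 2 && j == 0) 1 - params$sA
        else if (j == 2) 1
        else 1 - params$hA * params$sA
      } else {
        if ((i == 0 && j == 0) || (i == 2 && j == 2)) 1
        else if ((i == 0 && j == 2) || (i == 2 && j == 0)) 1 - params$s
        else 1 - params$h * params$s
      }
    })
}
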