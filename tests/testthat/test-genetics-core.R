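test_that("resident and migrant genotypes are the pure index-1 / index-2 strains", {
  expect_equal(format(resident_genotype("A", "female")), "mt1 N1 F")
  expect_equal(format(migrant_genotype("A", "male")), "mt2 N2 M")
  expect_equal(format(resident_genotype("B")), "A1 B1")
  expect_equal(format(migrant_genotype("B")), "A2 B2")
  expect_equal(format(migrant_genotype("C", "female")), "mt2 N2N2 F")
  expect_equal(format(resident_genotype("D")), "A1A1 B1B1")
  expect_equal(format(migrant_genotype("D")), "A2A2 B2B2")
})

test_that("sex handling matches the model: sexed A/C, unsexed B/D", {
  expect_error(resident_genotype("A"), "sexed")
  expect_error(genotype("B", sex = "female", a = 1, b = 1), "distinguish")
  expect_error(genotype("D", cyto = 1, a = c(1, 1), b = c(1, 1)), "cytotype")
})

test_that("diploid genotypes are unordered", {
  g1 <- genotype("C", "male", cyto = 2, n = c(1, 2))
  g2 <- genotype("C", "male", cyto = 2, n = c(2, 1))
  expect_equal(format(g1), format(g2))
})

test_that("fitness tables give residents and migrants fitness one and penalize hybrids", {
  cases <- list(
    # model, params, genotype args, expected
    list(incompatibility_model("A", s1 = 0.3, s2 = 0.8),
         genotype("A", "female", cyto = 1, n = 2), 0.7),
    list(incompatibility_model("A", s1 = 0.3, s2 = 0.8),
         genotype("A", "male", cyto = 2, n = 1), 0.2),
    list(incompatibility_model("A", s1 = 0.3, s2 = 0.8),
         migrant_genotype("A", "female"), 1),
    list(incompatibility_model("B", sA = 0.25, sB = 0.5),
         genotype("B", a = 2, b = 1), 0.75),
    list(incompatibility_model("B", sA = 0.25, sB = 0.5),
         genotype("B", a = 1, b = 2), 0.5),
    list(incompatibility_model("C", s1 = 0.9, s2 = 0.4, h1 = 0, h2 = 1),
         genotype("C", "male", cyto = 1, n = c(1, 2)), 1),      # recessive het
    list(incompatibility_model("C", s1 = 0.9, s2 = 0.4, h1 = 0, h2 = 1),
         genotype("C", "male", cyto = 2, n = c(1, 2)), 0.6),    # dominant het
    list(incompatibility_model("C", s1 = 0.9, s2 = 0.4, h1 = 0, h2 = 1),
         genotype("C", "female", cyto = 2, n = c(1, 1)), 0.6),
    list(incompatibility_model("D", s = 0.8, h = 0.5, d_variant = "symmetric"),
         genotype("D", a = c(1, 2), b = c(1, 2)), 0.6),
    list(incompatibility_model("D", s = 0.8, h = 0.5, d_variant = "symmetric"),
         genotype("D", a = c(1, 1), b = c(2, 2)), 0.2),
    list(incompatibility_model("D", sA = 0.8, hA = 0.5),
         genotype("D", a = c(1, 1), b = c(2, 2)), 1),  # A1A1 row unaffected
    list(incompatibility_model("D", sA = 0.8, hA = 0.5),
         genotype("D", a = c(2, 2), b = c(1, 1)), 0.2),
    list(incompatibility_model("D", sA = 0.8, hA = 0.5),
         genotype("D", a = c(1, 2), b = c(1, 2)), 0.6))
  for (cs in cases) {
    expect_equal(genotype_fitness(cs[[1]], cs[[2]]), cs[[3]])
  }
})

test_that("fitness corners: no selection means fitness one everywhere, s=1 hybrids die", {
  m0 <- incompatibility_model("A")
  for (cy in 1:2) for (n in 1:2) {
    expect_equal(genotype_fitness(m0, genotype("A", "male", cyto = cy, n = n)), 1)
  }
  m1 <- incompatibility_model("A", s1 = 1, s2 = 1)
  expect_equal(genotype_fitness(m1, genotype("A", "male", cyto = 1, n = 2)), 0)
  expect_equal(genotype_fitness(m1, genotype("A", "male", cyto = 2, n = 1)), 0)
})

test_that("genotype/model mismatch is rejected", {
  expect_error(
    genotype_fitness(incompatibility_model("A", s1 = 0.5), resident_genotype("B")),
    "Model")
})

test_that("parameters not belonging to a model are rejected", {
  expect_error(incompatibility_model("A", sA = 0.5), "do not belong")
  expect_error(incompatibility_model("B", h1 = 0.5), "do not belong")
  expect_error(incompatibility_model("D", s = 0.5, d_variant = "asymmetric"),
               "do not belong")
  expect_error(incompatibility_model("A", s1 = 1.5), "\\[0, 1\\]")
})

test_that("backcross of the migrant female matches the haploid MtNI fitness-graph weights", {
  p <- incompatibility_model("A", s1 = 0.2, s2 = 0.6)
  off <- offspring_distribution(p, migrant_genotype("A", "female"),
                                resident_genotype("A", "male"))
  expected <- c("mt2 N1 F" = 0.25 * 0.4, "mt2 N1 M" = 0.25 * 0.4,
                "mt2 N2 F" = 0.25, "mt2 N2 M" = 0.25)
  expect_equal(setNames(off$weight, off$genotype), expected[off$genotype])
  expect_equal(sum(off$probability), 1)
})

test_that("males pass no cytotype: migrant-male offspring carry the maternal mt1", {
  p <- incompatibility_model("A", s1 = 0.2, s2 = 0.6)
  off <- offspring_distribution(p, genotype("A", "male", cyto = 2, n = 1),
                                resident_genotype("A", "female"))
  expect_setequal(off$genotype, c("mt1 N1 F", "mt1 N1 M"))
  expect_equal(off$weight, c(0.5, 0.5))
})

test_that("two unlinked nuclear loci recombine freely in the haploid NNI cross", {
  p <- incompatibility_model("B", sA = 0.3, sB = 0.7)
  off <- offspring_distribution(p, migrant_genotype("B"), resident_genotype("B"))
  expected <- c("A1 B1" = 0.25, "A1 B2" = 0.25 * 0.3, "A2 B1" = 0.25 * 0.7,
                "A2 B2" = 0.25)
  expect_equal(setNames(off$weight, off$genotype), expected[off$genotype])
})

test_that("without selection offspring weights form a probability distribution", {
  for (model in c("A", "B", "C", "D")) {
    p <- draw_params(model, rep(0, 5))
    sexes <- if (model %in% c("A", "C")) list(c("female", "male")) else list(c(NULL, NULL))
    off <- offspring_distribution(p, migrant_genotype(model, sexes[[1]][1]),
                                  resident_genotype(model, sexes[[1]][2]))
    expect_equal(sum(off$weight), 1)
  }
})

test_that("offspring probabilities always sum to one and cytotypes are maternal", {
  set.seed(42)
  for (rep in 1:20) {
    u <- runif(5)
    for (model in c("A", "C")) {
      p <- draw_params(model, u)
      mk <- function(cy, idx, sex) {
        n <- if (model == "A") idx else c(1L, idx)
        genotype(model, sex, cyto = cy, n = n)
      }
      mother <- mk(sample(1:2, 1), sample(1:2, 1), "female")
      father <- mk(sample(1:2, 1), sample(1:2, 1), "male")
      off <- offspring_distribution(p, mother, father)
      expect_equal(sum(off$probability), 1)
      expect_true(all(grepl(paste0("mt", mother$cyto), off$genotype)))
    }
    for (model in c("B", "D")) {
      p <- draw_params(model, u, variant = if (rep %% 2) "asymmetric" else "symmetric")
      al <- function() if (model == "B") sample(1:2, 1) else sort(sample(1:2, 2, TRUE))
      g1 <- genotype(model, a = al(), b = al())
      g2 <- genotype(model, a = al(), b = al())
      off <- offspring_distribution(p, g1, g2)
      expect_equal(sum(off$probability), 1)
    }
  }
})

test_that("same-sex crosses are rejected in the sexed models", {
  p <- incompatibility_model("A", s1 = 0.5)
  expect_error(
    offspring_distribution(p, migrant_genotype("A", "female"),
                           resident_genotype("A", "female")),
    "opposite|female and one male")
})
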