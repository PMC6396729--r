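test_that("graph sizes: 8 classes (A), 4 (B), 10 (C), and the reachable NNI subset (D)", {
  expect_length(fitness_graph(incompatibility_model("A", s1 = .3, s2 = .4))$nodes, 8)
  expect_length(fitness_graph(incompatibility_model("B", sA = .3, sB = .4))$nodes, 4)
  expect_length(fitness_graph(incompatibility_model("C", s1 = .3, s2 = .4,
                                                    h1 = .2, h2 = .7))$nodes, 10)
  # Backcrossing to A1A1 B1B1 residents only: a migrant-lineage member always
  # carries an A1B1 gamete, so no descendant holds two derived alleles at any
  # locus. The recombinant double homozygotes -- the only unfit genotypes
  # under recessive NNI -- can never form.
  g <- fitness_graph(incompatibility_model("D", sA = .3, hA = .4))
  expect_length(g$nodes, 5)
  expect_false(any(c("A1A1 B2B2", "A2A2 B1B1") %in% g$nodes))
  expect_setequal(g$nodes, c("A2A2 B2B2", "A1A2 B1B2", "A1A1 B1B2",
                             "A1A2 B1B1", "A1A1 B1B1"))
})

test_that("edge weights are viability-weighted backcross proportions", {
  gA <- fitness_graph(incompatibility_model("A", s1 = .3, s2 = .4))
  eA <- gA$edges
  expect_equal(eA$weight[eA$from == "mt2 N2 F" & eA$to == "mt2 N1 M"],
               0.25 * (1 - 0.4))
  gB <- fitness_graph(incompatibility_model("B", sA = .3, sB = .4))
  eB <- gB$edges
  expect_equal(eB$weight[eB$from == "A1 B2" & eB$to == "A1 B2"],
               0.5 * (1 - 0.4))
})

# The per-model linear systems, written out literally equation by equation,
# serve as regression fixtures for the graph-derived solver.
rv_system_A <- function(s1, s2) {
  un <- c("mt1 N2 M", "mt1 N2 F", "mt2 N1 M", "mt2 N1 F", "mt2 N2 M", "mt2 N2 F")
  W <- matrix(0, 6, 6, dimnames = list(un, un))
  b <- setNames(numeric(6), un)
  W["mt1 N2 M", c("mt1 N2 M", "mt1 N2 F")] <- (1 - s1) / 4
  b["mt1 N2 M"] <- 1 / 2
  W["mt1 N2 F", ] <- W["mt1 N2 M", ]; b["mt1 N2 F"] <- b["mt1 N2 M"]
  b["mt2 N1 M"] <- 1
  W["mt2 N1 F", c("mt2 N1 M", "mt2 N1 F")] <- (1 - s2) / 2
  W["mt2 N2 M", ] <- W["mt1 N2 M", ]; b["mt2 N2 M"] <- 1 / 2
  W["mt2 N2 F", c("mt2 N1 M", "mt2 N1 F")] <- (1 - s2) / 4
  W["mt2 N2 F", c("mt2 N2 M", "mt2 N2 F")] <- 1 / 4
  solve(diag(6) - W, b)
}

rv_system_B <- function(sA, sB) {
  un <- c("A1 B2", "A2 B1", "A2 B2")
  W <- matrix(0, 3, 3, dimnames = list(un, un))
  b <- setNames(c(1 / 2, 1 / 2, 1 / 4), un)
  W["A1 B2", "A1 B2"] <- (1 - sB) / 2
  W["A2 B1", "A2 B1"] <- (1 - sA) / 2
  W["A2 B2", ] <- c((1 - sB) / 4, (1 - sA) / 4, 1 / 4)
  solve(diag(3) - W, b)
}

rv_system_C <- function(s1, s2, h1, h2) {
  un <- c("mt1 N1N2 M", "mt1 N1N2 F", "mt2 N1N1 M", "mt2 N1N1 F",
          "mt2 N1N2 M", "mt2 N1N2 F", "mt2 N2N2 M", "mt2 N2N2 F")
  W <- matrix(0, 8, 8, dimnames = list(un, un))
  b <- setNames(numeric(8), un)
  W["mt1 N1N2 M", c("mt1 N1N2 M", "mt1 N1N2 F")] <- (1 - h1 * s1) / 4
  b["mt1 N1N2 M"] <- 1 / 2
  W["mt1 N1N2 F", ] <- W["mt1 N1N2 M", ]; b["mt1 N1N2 F"] <- 1 / 2
  b["mt2 N1N1 M"] <- 1
  W["mt2 N1N1 F", c("mt2 N1N1 M", "mt2 N1N1 F")] <- (1 - s2) / 2
  W["mt2 N1N2 M", c("mt1 N1N2 M", "mt1 N1N2 F")] <- (1 - h1 * s1) / 4
  b["mt2 N1N2 M"] <- 1 / 2
  W["mt2 N1N2 F", c("mt2 N1N2 M", "mt2 N1N2 F")] <- (1 - h2 * s2) / 4
  W["mt2 N1N2 F", c("mt2 N1N1 M", "mt2 N1N1 F")] <- (1 - s2) / 4
  W["mt2 N2N2 M", c("mt1 N1N2 M", "mt1 N1N2 F")] <- (1 - h1 * s1) / 2
  W["mt2 N2N2 F", c("mt2 N1N2 M", "mt2 N1N2 F")] <- (1 - h2 * s2) / 2
  solve(diag(8) - W, b)
}

test_that("graph solver reproduces the hand-written linear systems term for term", {
  set.seed(11)
  for (i in 1:25) {
    u <- runif(4)
    pA <- incompatibility_model("A", s1 = u[1], s2 = u[2])
    vA <- reproductive_values(fitness_graph(pA))
    fixA <- rv_system_A(u[1], u[2])
    expect_equal(vA[names(fixA)], fixA, tolerance = 1e-12)
    pB <- incompatibility_model("B", sA = u[1], sB = u[2])
    vB <- reproductive_values(fitness_graph(pB))
    fixB <- rv_system_B(u[1], u[2])
    expect_equal(vB[names(fixB)], fixB, tolerance = 1e-12)
    pC <- incompatibility_model("C", s1 = u[1], s2 = u[2], h1 = u[3], h2 = u[4])
    vC <- reproductive_values(fitness_graph(pC))
    fixC <- rv_system_C(u[1], u[2], u[3], u[4])
    expect_equal(vC[names(fixC)], fixC, tolerance = 1e-12)
  }
})

test_that("reproductive values: residents are one, no selection means no barrier", {
  v <- reproductive_values(incompatibility_model("A"))
  expect_equal(unname(v), rep(1, 8))
  v1 <- reproductive_values(incompatibility_model("A", s1 = 1, s2 = 1))
  expect_equal(v1[["mt2 N2 F"]], 1 / 6)
  expect_equal(v1[["mt2 N2 M"]], 1 / 2)
  expect_equal(reproductive_values(incompatibility_model("B", sA = 1, sB = 1))[["A2 B2"]],
               1 / 3)
  vC <- reproductive_values(incompatibility_model("C", s1 = .5, s2 = .5, h1 = 1, h2 = 1))
  expect_equal(vC[["mt2 N2N2 F"]], 5 / 21, tolerance = 1e-12) # 0.238095...
  expect_true(all(v1 >= 0 & v1 <= 1))
})

test_that("gene flow factors at the classic corners", {
  expect_equal(gene_flow_factor(incompatibility_model("A", s1 = 1, s2 = 1, mf = 1)),
               1 / 6)
  expect_equal(gene_flow_factor(incompatibility_model("A", s1 = 0, s2 = 1, mf = 0)),
               1)
  expect_equal(gene_flow_factor(incompatibility_model("C", h1 = 0, h2 = 0,
                                                      s1 = .7, s2 = 1, mf = 1)),
               2 / 3)
  for (s in c(0.2, 0.6, 1)) {
    expect_equal(gene_flow_factor(incompatibility_model("D", sA = s, hA = 0)), 1)
    expect_equal(gene_flow_factor(
      incompatibility_model("D", s = s, h = 0, d_variant = "symmetric")), 1)
  }
})

test_that("migrant sex ratio mf does not affect the unsexed models", {
  p1 <- incompatibility_model("B", sA = .4, sB = .9, mf = 0)
  p2 <- incompatibility_model("B", sA = .4, sB = .9, mf = 1)
  expect_identical(gene_flow_factor(p1), gene_flow_factor(p2))
})

test_that("DOT export lists every class and edge", {
  g <- fitness_graph(incompatibility_model("B", sA = 1, sB = 1))
  dot <- graph_to_dot(g)
  expect_match(dot, "digraph")
  for (n in g$nodes) expect_match(dot, n, fixed = TRUE)
  expect_equal(length(gregexpr("->", dot)[[1]]), nrow(g$edges))
})
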