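# Random parameter draws used by the property-style tests. u is a vector of
# five uniforms; Model D alternates between its two variants via `variant`.
draw_params <- function(model, u, variant = c("asymmetric", "symmetric")) {
  variant <- match.arg(variant)
  switch(model,
    A = incompatibility_model("A", s1 = u[1], s2 = u[2], mf = u[5]),
    B = incompatibility_model("B", sA = u[1], sB = u[2]),
    C = incompatibility_model("C", s1 = u[1], s2 = u[2], h1 = u[3], h2 = u[4],
                              mf = u[5]),
    D = if (variant == "asymmetric") {
      incompatibility_model("D", sA = u[1], hA = u[3])
    } else {
      incompatibility_model("D", s = u[1], h = u[3], d_variant = "symmetric")
    })
}

migrant_value <- function(params, sex = NULL) {
  v <- reproductive_values(fitness_graph(params))
  v[[format(migrant_genotype(params$model, sex))]]
}
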