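# Closed-form reproductive values, implemented independently of the graph
# solver so they can serve as an oracle for it (and vice versa). Derivations
# follow from eliminating the hybrid classes of each model's linear system by
# hand; the resulting rational functions are evaluated directly.

check_coefs <- function(...) {
  args <- list(...)
  for (nm in names(args)) check_unit_interval(args[[nm]], nm)
  invisible(NULL)
}

#' Closed-form reproductive values, Model A (haploid MtNI)
#'
#' @param s1,s2 Selection coefficients in `[0, 1]`.
#' @return Named vector `c(male, female)` of migrant reproductive values:
#'   `male = 1/(1 + s1)`,
#'   `female = (3 + 2 s1 - s2 - 2 s1 s2) / (3 (1 + s1)(1 + s2))`.
#' @examples
#' analytic_rv_A(1, 1) # c(1/2, 1/6)
#' @export
analytic_rv_A <- function(s1, s2) {
  check_coefs(s1 = s1, s2 = s2)
  c(male = 1 / (1 + s1),
    female = (3 + 2 * s1 - s2 - 2 * s1 * s2) / (3 * (1 + s1) * (1 + s2)))
}

#' Closed-form reproductive values, Model B (haploid NNI)
#'
#' @param sA,sB Selection coefficients in `[0, 1]`.
#' @return Named vector `c(A1B2, A2B1, A2B2)`:
#'   `A1B2 = 1/(1 + sB)`, `A2B1 = 1/(1 + sA)`,
#'   `A2B2 = (3 + sA + sB - sA sB) / (3 (1 + sA + sB + sA sB))`.
#' @examples
#' analytic_rv_B(1, 1)[["A2B2"]] # 1/3
#' @export
analytic_rv_B <- function(sA, sB) {
  check_coefs(sA = sA, sB = sB)
  c(A1B2 = 1 / (1 + sB),
    A2B1 = 1 / (1 + sA),
    A2B2 = (3 + sA + sB - sA * sB) / (3 * (1 + sA + sB + sA * sB)))
}

#' Closed-form reproductive values, Model C (diploid MtNI)
#'
#' @param s1,s2,h1,h2 Selection and dominance coefficients in `[0, 1]`.
#' @return Named vector `c(male, female)`:
#'   `male = (1 - h1 s1)/(1 + h1 s1)`,
#'   `female = (1 - h2 s2)(3 + s2 + h1 s1 (1 - s2)) /
#'             ((1 + h1 s1)(1 + s2)(3 + h2 s2))`.
#' @examples
#' analytic_rv_C(0, 1, 0, 0) # recessive, s2 = 1: female = 2/3
#' @export
analytic_rv_C <- function(s1, s2, h1, h2) {
  check_coefs(s1 = s1, s2 = s2, h1 = h1, h2 = h2)
  c(male = (1 - h1 * s1) / (1 + h1 * s1),
    female = (1 - h2 * s2) * (3 + s2 + h1 * s1 * (1 - s2)) /
      ((1 + h1 * s1) * (1 + s2) * (3 + h2 * s2)))
}

#' Closed-form migrant reproductive value, Model D (diploid NNI)
#'
#' For the asymmetric (Dobzhansky-Muller) variant the migrant value is
#' `(1 - hA sA)/(1 + hA sA)`: the double heterozygote's descendants only pay
#' through A2-carrying backgrounds. For the symmetric variant both F2
#' single-heterozygote backgrounds are also unfit and the value is
#' `(1 - hs)(3 + 2hs - (hs)^2) / ((1 + hs)^2 (3 + hs))`. Both variants give 1
#' whenever the dominance coefficient is 0: fully recessive NNI is invisible
#' in a backcrossing lineage, whose members never carry two derived alleles
#' at both loci.
#'
#' @param s_coef,h_coef Selection and dominance coefficients in `[0, 1]`
#'   (`sA`/`hA` for the asymmetric variant, `s`/`h` for the symmetric one).
#' @param d_variant `"asymmetric"` or `"symmetric"`.
#' @return The migrant reproductive value (single number).
#' @examples
#' analytic_rv_D(1, 0, "symmetric") # recessive: 1
#' @export
analytic_rv_D <- function(s_coef, h_coef, d_variant = c("asymmetric", "symmetric")) {
  check_coefs(s_coef = s_coef, h_coef = h_coef)
  d_variant <- match.arg(d_variant)
  x <- h_coef * s_coef
  if (d_variant == "asymmetric") {
    (1 - x) / (1 + x)
  } else {
    (1 - x) * (3 + 2 * x - x^2) / ((1 + x)^2 * (3 + x))
  }
}

#' Gene flow factor from the closed forms
#'
#' The sex-weighted average migrant reproductive value (Models A, C) or the
#' single migrant value (Models B, D), evaluated from the closed-form
#' expressions rather than the graph solver.
#'
#' @param params An [incompatibility_model()].
#' @return A single number in `[0, 1]`.
#' @examples
#' analytic_gene_flow_factor(incompatibility_model("A", s1 = 1, s2 = 1)) # 1/3
#' @export
analytic_gene_flow_factor <- function(params) {
  stopifnot(inherits(params, "incompatibility_model"))
  switch(params$model,
    A = {
      v <- analytic_rv_A(params$s1, params$s2)
      (1 - params$mf) * v[["male"]] + params$mf * v[["female"]]
    },
    B = analytic_rv_B(params$sA, params$sB)[["A2B2"]],
    C = {
      v <- analytic_rv_C(params$s1, params$s2, params$h1, params$h2)
      (1 - params$mf) * v[["male"]] + params$mf * v[["female"]]
    },
    D = {
      if (params$d_variant == "asymmetric") {
        analytic_rv_D(params$sA, params$hA, "asymmetric")
      } else {
        analytic_rv_D(params$s, params$h, "symmetric")
      }
    })
}
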