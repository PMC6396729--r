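#' mitobarrier: gene-flow barriers from genetic incompatibilities
#'
#' Tools for quantifying how two-locus genetic incompatibilities between a
#' diverged mainland population and an island population reduce gene flow at
#' an unlinked, selectively neutral marker locus. Four deterministic
#' mainland-island models are implemented, crossing the genetic system
#' (haploid vs diploid) with the type of incompatibility (mito-nuclear, MtNI,
#' vs nuclear-nuclear, NNI):
#'
#' * **Model A** -- haploid MtNI: maternally inherited cytotype (mt1/mt2) and
#'   one nuclear locus (N1/N2); sexes tracked because only females transmit
#'   the cytotype.
#' * **Model B** -- haploid NNI: two unlinked nuclear loci (A, B); the sexes
#'   have identical fitness and need not be distinguished.
#' * **Model C** -- diploid MtNI: cytotype plus one diploid nuclear locus, with
#'   dominance coefficients for the heterozygote.
#' * **Model D** -- diploid NNI: two unlinked diploid nuclear loci, in an
#'   asymmetric (Dobzhansky-Muller) or a symmetric variant.
#'
#' The strength of the barrier is summarised by the *gene flow factor*
#' \eqn{m_e/m}: the ratio of the effective migration rate at the neutral
#' marker to the actual migration rate. In the weak-migration limit this
#' factor equals the average reproductive value of migrants, which the package
#' computes three independent ways: by solving the linear system of the
#' migrant-lineage fitness graph ([gene_flow_factor()]), from closed-form
#' expressions ([analytic_gene_flow_factor()]), and numerically from a forward
#' genotype-frequency recursion ([effective_migration_rate()]).
#'
#' @keywords internal
"_PACKAGE"

MODEL_IDS <- c("A", "B", "C", "D")

#' Define an incompatibility model and its parameters
#'
#' Constructs the parameter set of one of the four mainland-island
#' incompatibility models. Only the parameters belonging to the chosen model
#' may be supplied; all selection and dominance coefficients live in
#' \eqn{[0, 1]}.
#'
#' @param model One of `"A"` (haploid mito-nuclear), `"B"` (haploid
#'   nuclear-nuclear), `"C"` (diploid mito-nuclear), `"D"` (diploid
#'   nuclear-nuclear).
#' @param s1,s2 Selection coefficients against the hybrid combinations
#'   mt1-with-N2 (`s1`) and mt2-with-N1 (`s2`) in Models A and C.
#' @param h1,h2 Dominance of the incompatibility in nuclear heterozygotes on
#'   the mt1 (`h1`) and mt2 (`h2`) background, Model C only.
#' @param sA,sB Selection coefficients against the hybrid combinations
#'   A2-with-B1 (`sA`) and A1-with-B2 (`sB`) in Model B; `sA` is also the
#'   selection coefficient of the Model D variants.
#' @param hA Dominance coefficient of the asymmetric Model D variant.
#' @param s,h Selection and dominance coefficients of the symmetric Model D
#'   variant.
#' @param mf Fraction of females among migrants (sexed Models A and C; it has
#'   no effect on the gene flow factor of Models B and D). Default `0.5`.
#' @param d_variant For Model D, `"asymmetric"` (one derived background is
#'   harmless, the classical Dobzhansky-Muller case) or `"symmetric"` (both
#'   double-homozygous hybrid backgrounds suffer).
#'
#' @return An object of class `incompatibility_model`: a list with the model
#'   id and its parameters.
#'
#' @examples
#' incompatibility_model("A", s1 = 1, s2 = 1, mf = 1)
#' incompatibility_model("D", sA = 0.5, hA = 0.2, d_variant = "asymmetric")
#' @export
incompatibility_model <- function(model = c("A", "B", "C", "D"),
                                  s1 = NULL, s2 = NULL, h1 = NULL, h2 = NULL,
                                  sA = NULL, sB = NULL, hA = NULL,
                                  s = NULL, h = NULL,
                                  mf = 0.5,
                                  d_variant = c("asymmetric", "symmetric")) {
  model <- match.arg(model)
  supplied <- list(s1 = s1, s2 = s2, h1 = h1, h2 = h2, sA = sA, sB = sB,
                   hA = hA, s = s, h = h)
  allowed <- switch(model,
    A = c("s1", "s2"),
    B = c("sA", "sB"),
    C = c("s1", "s2", "h1", "h2"),
    D = NULL) # resolved below via variant
  if (model == "D") {
    d_variant <- match.arg(d_variant)
    allowed <- if (d_variant == "asymmetric") c("sA", "hA") else c("s", "h")
  } else {
    d_variant <- NULL
  }
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, logical(1))], allowed)
  if (length(extra)) {
    stop(sprintf("parameter(s) %s do not belong to Model %s%s",
                 paste(extra, collapse = ", "), model,
                 if (!is.null(d_variant)) paste0(" (", d_variant, ")") else ""))
  }
  p <- lapply(stats::setNames(allowed, allowed), function(nm) {
    val <- supplied[[nm]]
    if (is.null(val)) val <- 0
    check_unit_interval(val, nm)
    val
  })
  check_unit_interval(mf, "mf")
  obj <- c(list(model = model), p, list(mf = mf, d_variant = d_variant))
  class(obj) <- "incompatibility_model"
  obj
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name))
  }
  invisible(x)
}

is_sexed <- function(params) params$model %in% c("A", "C")

model_ploidy <- function(params) if (params$model %in% c("A", "B")) 1L else 2L

#' @export
print.incompatibility_model <- function(x, ...) {
  desc <- switch(x$model,
    A = "haploid mito-nuclear incompatibility (sexed)",
    B = "haploid nuclear-nuclear incompatibility",
    C = "diploid mito-nuclear incompatibility (sexed)",
    D = sprintf("diploid nuclear-nuclear incompatibility (%s)", x$d_variant))
  cat(sprintf("Model %s: %s\n", x$model, desc))
  par_names <- setdiff(names(x), c("model", "d_variant"))
  if (!is_sexed(x)) par_names <- setdiff(par_names, "mf")
  vals <- vapply(par_names, function(nm) x[[nm]], numeric(1))
  cat(paste(sprintf("  %s = %g", par_names, vals), collapse = "\n"), "\n")
  invisible(x)
}
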