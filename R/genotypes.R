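# Genotype objects: a genetic class of one of the four models. Diploid
# genotypes are stored as sorted allele-index vectors (unordered, no parental
# origin), the cytotype as an integer 1/2, and sex as "F"/"M" or NA for the
# unsexed models.

new_genotype <- function(model, sex = NA_character_, cyto = NA_integer_,
                         n = NULL, a = NULL, b = NULL) {
  g <- list(model = model, sex = sex, cyto = cyto,
            n = sort_alleles(n), a = sort_alleles(a), b = sort_alleles(b))
  class(g) <- "genotype"
  g
}

sort_alleles <- function(x) if (is.null(x)) NULL else sort(as.integer(x))

#' Construct a genotype of an incompatibility model
#'
#' @param model Model id, `"A"`--`"D"` (or an [incompatibility_model()]).
#' @param sex `"female"`/`"male"` for the sexed models A and C; omit (or
#'   `"unsexed"`) for B and D.
#' @param cyto Cytotype index, `1` or `2` (Models A, C).
#' @param n Nuclear allele indices at the N locus: one value in `1:2` for
#'   Model A, two for Model C.
#' @param a,b Allele indices at the A and B loci: one value each for Model B,
#'   two each for Model D. Diploid genotypes are unordered.
#'
#' @return An object of class `genotype`.
#' @examples
#' genotype("C", sex = "female", cyto = 2, n = c(1, 2))
#' genotype("B", a = 2, b = 1)
#' @export
genotype <- function(model, sex = NULL, cyto = NULL, n = NULL, a = NULL, b = NULL) {
  if (inherits(model, "incompatibility_model")) model <- model$model
  stopifnot(model %in% MODEL_IDS)
  sexed <- model %in% c("A", "C")
  if (sexed) {
    if (is.null(sex)) stop(sprintf("Model %s is sexed: supply sex = \"female\" or \"male\"", model))
    sex <- switch(match.arg(sex, c("female", "male")), female = "F", male = "M")
  } else {
    if (!is.null(sex) && !identical(sex, "unsexed")) {
      stop(sprintf("Model %s does not distinguish the sexes", model))
    }
    sex <- NA_character_
  }
  cyto_needed <- model %in% c("A", "C")
  if (cyto_needed) {
    if (is.null(cyto) || !cyto %in% 1:2) stop("cytotype must be 1 or 2")
    cyto <- as.integer(cyto)
  } else {
    if (!is.null(cyto)) stop(sprintf("Model %s has no cytotype", model))
    cyto <- NA_integer_
  }
  ploidy <- if (model %in% c("A", "B")) 1L else 2L
  check_locus <- function(x, nm, needed) {
    if (!needed) {
      if (!is.null(x)) stop(sprintf("locus %s does not exist in Model %s", nm, model))
      return(NULL)
    }
    if (is.null(x) || length(x) != ploidy || !all(x %in% 1:2)) {
      stop(sprintf("locus %s needs %d allele index(es) in 1:2", nm, ploidy))
    }
    x
  }
  n <- check_locus(n, "N", model %in% c("A", "C"))
  a <- check_locus(a, "A", model %in% c("B", "D"))
  b <- check_locus(b, "B", model %in% c("B", "D"))
  new_genotype(model, sex, cyto, n, a, b)
}

#' Resident (island) genotype of a model
#'
#' The island population initially consists purely of index-1 alleles:
#' mt1 N1 (Model A), A1 B1 (Model B), mt1 N1N1 (Model C), A1A1 B1B1 (Model D).
#'
#' @inheritParams genotype
#' @return A `genotype` object.
#' @examples
#' resident_genotype("A", "female")
#' resident_genotype("D")
#' @export
resident_genotype <- function(model, sex = NULL) {
  pure_genotype(model, sex, 1L)
}

#' Migrant (mainland) genotype of a model
#'
#' The mainland is fixed for index-2 alleles: mt2 N2 (A), A2 B2 (B),
#' mt2 N2N2 (C), A2A2 B2B2 (D).
#'
#' @inheritParams genotype
#' @return A `genotype` object.
#' @examples
#' migrant_genotype("C", "male")
#' @export
migrant_genotype <- function(model, sex = NULL) {
  pure_genotype(model, sex, 2L)
}

pure_genotype <- function(model, sex, idx) {
  if (inherits(model, "incompatibility_model")) model <- model$model
  ploidy <- if (model %in% c("A", "B")) 1L else 2L
  al <- rep(idx, ploidy)
  switch(model,
    A = genotype(model, sex = sex, cyto = idx, n = al),
    B = genotype(model, sex = sex, a = al, b = al),
    C = genotype(model, sex = sex, cyto = idx, n = al),
    D = genotype(model, sex = sex, a = al, b = al))
}

#' @export
format.genotype <- function(x, ...) {
  parts <- character(0)
  if (!is.na(x$cyto)) parts <- c(parts, paste0("mt", x$cyto))
  if (!is.null(x$n)) parts <- c(parts, paste0("N", paste(x$n, collapse = "N")))
  if (!is.null(x$a)) parts <- c(parts, paste0("A", paste(x$a, collapse = "A")))
  if (!is.null(x$b)) parts <- c(parts, paste0("B", paste(x$b, collapse = "B")))
  if (!is.na(x$sex)) parts <- c(parts, x$sex)
  paste(parts, collapse = " ")
}

#' @export
print.genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

genotype_label <- function(g) format(g)

# Same genetic class (model, sex, cytotype, unordered alleles)?
same_class <- function(g1, g2) identical(format(g1), format(g2))
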