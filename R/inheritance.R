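# Inheritance rules shared by the fitness-graph builder and the forward
# simulator. Cytotypes are strictly maternal; all nuclear loci are unlinked
# (free recombination, gamete types equiprobable); the offspring sex ratio is
# 1:1. In the haploid models the diploid zygote undergoes meiosis, so the
# offspring inherits each nuclear allele from either parent with probability
# one half -- formally the same transmission rule as one allele of a diploid.

#' Offspring classes of a cross, weighted by viability
#'
#' Enumerates the genetic classes of adult offspring from a cross, with
#' `weight = P(offspring class | parents) * w(offspring genotype)`. The
#' probabilities alone (column `probability`) sum to one; the weights do not,
#' because viability selection removes part of each brood. In the sexed
#' models each Mendelian class is split equally into a male and a female
#' class.
#'
#' @param params An [incompatibility_model()].
#' @param parent,mate The two parents ([genotype()] objects). In the sexed
#'   models they must be of opposite sex (in either order); in the unsexed
#'   models any two genotypes may be crossed.
#' @return A data frame with columns `genotype` (canonical class label),
#'   `probability`, `fitness` and `weight`, one row per offspring class.
#' @examples
#' m <- incompatibility_model("A", s1 = 0.2, s2 = 0.6)
#' offspring_distribution(m,
#'   migrant_genotype("A", "female"),
#'   resident_genotype("A", "male"))
#' @export
offspring_distribution <- function(params, parent, mate) {
  stopifnot(inherits(parent, "genotype"), inherits(mate, "genotype"))
  if (!identical(parent$model, params$model) || !identical(mate$model, params$model)) {
    stop("parents must belong to the model of 'params'")
  }
  sexed <- is_sexed(params)
  if (sexed) {
    if (is.na(parent$sex) || is.na(mate$sex) || parent$sex == mate$sex) {
      stop("sexed models require one female and one male parent")
    }
    mother <- if (parent$sex == "F") parent else mate
    father <- if (parent$sex == "M") parent else mate
  } else {
    mother <- parent
    father <- mate
  }
  kids <- cross_kernel(params, mother, father)
  out <- lapply(seq_along(kids$genotypes), function(i) {
    g <- kids$genotypes[[i]]
    pr <- kids$prob[i]
    w <- genotype_fitness(params, g)
    if (sexed) {
      data.frame(
        genotype = c(genotype_label(set_sex(g, "F")), genotype_label(set_sex(g, "M"))),
        probability = pr / 2, fitness = w, weight = pr / 2 * w,
        stringsAsFactors = FALSE)
    } else {
      data.frame(genotype = genotype_label(g), probability = pr,
                 fitness = w, weight = pr * w, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  agg <- stats::aggregate(out[c("probability", "weight")],
                          by = list(genotype = out$genotype), FUN = sum)
  agg$fitness <- out$fitness[match(agg$genotype, out$genotype)]
  agg[order(agg$genotype), c("genotype", "probability", "fitness", "weight")]
}

set_sex <- function(g, sex) {
  g$sex <- sex
  g
}

# Mendelian offspring genotypes (unsexed, before viability): list(genotypes,
# prob). Transmission per nuclear locus: haploid offspring take the maternal
# or paternal allele with probability 1/2; diploid offspring take one allele
# from each parent, each of a parent's two alleles with probability 1/2.
cross_kernel <- function(params, mother, father) {
  model <- params$model
  transmit <- function(alleles) {
    # distribution over transmitted alleles (values 1/2) as named probs
    tab <- table(alleles) / length(alleles)
    stats::setNames(as.numeric(tab), names(tab))
  }
  ploidy <- model_ploidy(params)
  loci <- switch(model,
    A = list(n = list(mother$n, father$n)),
    B = list(a = list(mother$a, father$a), b = list(mother$b, father$b)),
    C = list(n = list(mother$n, father$n)),
    D = list(a = list(mother$a, father$a), b = list(mother$b, father$b)))
  # per-locus offspring allele-set distributions
  locus_dists <- lapply(loci, function(al) {
    tm <- transmit(al[[1]])
    tp <- transmit(al[[2]])
    out <- list()
    for (am in names(tm)) for (ap in names(tp)) {
      pr <- tm[[am]] * tp[[ap]]
      geno <- if (ploidy == 1L) {
        # meiosis of the zygote: keep the maternal or paternal allele, 1/2 each
        list(list(al = as.integer(am), pr = pr / 2),
             list(al = as.integer(ap), pr = pr / 2))
      } else {
        list(list(al = sort(as.integer(c(am, ap))), pr = pr))
      }
      out <- c(out, geno)
    }
    # aggregate identical allele sets
    keys <- vapply(out, function(x) paste(x$al, collapse = "/"), character(1))
    agg <- tapply(vapply(out, `[[`, numeric(1), "pr"), keys, sum)
    lapply(names(agg), function(k) {
      list(al = as.integer(strsplit(k, "/")[[1]]), pr = as.numeric(agg[[k]]))
    })
  })
  # cartesian product over loci (free recombination)
  genotypes <- list()
  prob <- numeric(0)
  grid <- expand.grid(lapply(locus_dists, seq_along))
  for (r in seq_len(nrow(grid))) {
    pr <- 1
    alleles <- list()
    for (j in seq_along(locus_dists)) {
      pick <- locus_dists[[j]][[grid[r, j]]]
      pr <- pr * pick$pr
      alleles[[names(loci)[j]]] <- pick$al
    }
    g <- new_genotype(model,
                      sex = NA_character_,
                      cyto = mother$cyto, # strictly maternal (NA for B/D)
                      n = alleles$n, a = alleles$a, b = alleles$b)
    genotypes[[length(genotypes) + 1L]] <- g
    prob <- c(prob, pr)
  }
  list(genotypes = genotypes, prob = prob)
}
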