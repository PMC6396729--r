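# The migrant-lineage fitness graph. Under weak migration every individual of
# the migrant lineage mates with a resident of the opposite sex (or a resident
# at random in the unsexed models). Nodes are the genetic classes reachable
# from the migrant class(es) by repeated backcrossing; the edge weight from X
# to Y is the expected relative number of adult class-Y offspring per class-X
# parent. Equating each class's reproductive value to the weighted sum of its
# offspring's values yields a small linear system whose solution, averaged
# over migrant sexes, is the gene flow factor in the weak-migration limit.

#' Build the migrant-lineage fitness graph
#'
#' Discovers, by breadth-first closure from the migrant class(es), every
#' genetic class that the migrant lineage can reach when all mating is with
#' residents, and records the viability-weighted offspring proportions as
#' directed edge weights.
#'
#' @param params An [incompatibility_model()].
#' @return An object of class `fitness_graph`: list with `nodes` (class
#'   labels), `edges` (data frame `from`, `to`, `weight`), `residents`,
#'   `migrants`, and `params`.
#' @examples
#' fitness_graph(incompatibility_model("A", s1 = 0.5, s2 = 0.5))
#' @export
fitness_graph <- function(params) {
  stopifnot(inherits(params, "incompatibility_model"))
  sexed <- is_sexed(params)
  sexes <- if (sexed) c("female", "male") else list(NULL)
  migrants <- lapply(sexes, function(sx) migrant_genotype(params$model, sx))
  residents <- lapply(sexes, function(sx) resident_genotype(params$model, sx))
  res_labels <- vapply(residents, genotype_label, character(1))

  nodes <- list()
  edges <- list()
  queue <- migrants
  while (length(queue)) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    lab <- genotype_label(g)
    if (!is.null(nodes[[lab]])) next
    nodes[[lab]] <- g
    if (lab %in% res_labels) {
      # residents are the boundary of the system: unit self-loop only
      edges[[length(edges) + 1L]] <- data.frame(
        from = lab, to = lab, weight = 1, stringsAsFactors = FALSE)
      next
    }
    mate <- if (sexed) {
      residents[[if (g$sex == "F") 2L else 1L]]
    } else {
      residents[[1L]]
    }
    off <- offspring_distribution(params, g, mate)
    edges[[length(edges) + 1L]] <- data.frame(
      from = lab, to = off$genotype, weight = off$weight,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(off))) {
      if (is.null(nodes[[off$genotype[i]]])) {
        queue[[length(queue) + 1L]] <- parse_label(params$model, off$genotype[i])
      }
    }
  }
  structure(list(
    nodes = names(nodes),
    genotypes = nodes,
    edges = do.call(rbind, edges),
    residents = res_labels,
    migrants = vapply(migrants, genotype_label, character(1)),
    params = params), class = "fitness_graph")
}

# Reconstruct a genotype object from its canonical label.
parse_label <- function(model, lab) {
  toks <- strsplit(lab, " ")[[1]]
  sex <- if (toks[length(toks)] %in% c("F", "M")) toks[length(toks)] else NA_character_
  if (!is.na(sex)) toks <- toks[-length(toks)]
  fields <- list(cyto = NA_integer_, n = NULL, a = NULL, b = NULL)
  for (tk in toks) {
    if (grepl("^mt", tk)) {
      fields$cyto <- as.integer(sub("mt", "", tk))
    } else {
      locus <- tolower(substr(tk, 1, 1))
      idx <- as.integer(strsplit(gsub("[NAB]", "", tk), "")[[1]])
      fields[[locus]] <- idx
    }
  }
  new_genotype(model, sex, fields$cyto, fields$n, fields$a, fields$b)
}

#' @export
print.fitness_graph <- function(x, ...) {
  cat(sprintf("Fitness graph, Model %s: %d classes, %d edges\n",
              x$params$model, length(x$nodes), nrow(x$edges)))
  cat("  migrants:", paste(x$migrants, collapse = ", "), "\n")
  cat("  residents:", paste(x$residents, collapse = ", "), "\n")
  invisible(x)
}

#' Reproductive values of the genetic classes
#'
#' Solves the linear system of the fitness graph: the reproductive value of
#' each class equals the weight-summed reproductive values of its offspring
#' classes, with residents fixed at 1 (boundary condition, not an equation
#' row). The restricted system is dense and at most 10 x 10 and is solved by
#' direct factorization.
#'
#' @param x A [fitness_graph()] or an [incompatibility_model()].
#' @param ... Unused.
#' @return A named numeric vector of reproductive values, one per class.
#' @examples
#' reproductive_values(incompatibility_model("A", s1 = 1, s2 = 1))
#' @export
reproductive_values <- function(x, ...) UseMethod("reproductive_values")

#' @rdname reproductive_values
#' @export
reproductive_values.incompatibility_model <- function(x, ...) {
  reproductive_values(fitness_graph(x))
}

#' @rdname reproductive_values
#' @export
reproductive_values.fitness_graph <- function(x, ...) {
  free <- setdiff(x$nodes, x$residents)
  v <- stats::setNames(rep(1, length(x$nodes)), x$nodes)
  if (length(free)) {
    W <- matrix(0, length(free), length(free), dimnames = list(free, free))
    b <- stats::setNames(rep(0, length(free)), free)
    for (i in seq_len(nrow(x$edges))) {
      from <- x$edges$from[i]; to <- x$edges$to[i]; w <- x$edges$weight[i]
      if (!(from %in% free)) next
      if (to %in% free) W[from, to] <- W[from, to] + w
      else b[from] <- b[from] + w # offspring is a resident, v = 1
    }
    A <- diag(length(free)) - W
    sol <- tryCatch(solve(A, b), error = function(e) {
      stop(sprintf(
        "singular reproductive-value system for Model %s (parameters: %s): %s",
        x$params$model,
        paste(sprintf("%s=%g", setdiff(names(x$params), c("model", "d_variant")),
                      unlist(x$params[setdiff(names(x$params), c("model", "d_variant"))])),
              collapse = ", "),
        conditionMessage(e)))
    })
    v[free] <- sol
  }
  v
}

#' Gene flow factor of a model (graph method)
#'
#' The gene flow factor \eqn{m_e/m} in the weak-migration limit equals the
#' average reproductive value of migrants: the `mf`-weighted mean of the
#' female and male migrant values for the sexed Models A and C, and the single
#' migrant class value for Models B and D.
#'
#' @param params An [incompatibility_model()].
#' @return A single number in `[0, 1]`; 1 means no barrier.
#' @examples
#' gene_flow_factor(incompatibility_model("A", s1 = 1, s2 = 1, mf = 1)) # 1/6
#' @export
gene_flow_factor <- function(params) {
  v <- reproductive_values(fitness_graph(params))
  average_migrant_value(params, v)
}

average_migrant_value <- function(params, v) {
  if (is_sexed(params)) {
    vf <- v[[genotype_label(migrant_genotype(params$model, "female"))]]
    vm <- v[[genotype_label(migrant_genotype(params$model, "male"))]]
    (1 - params$mf) * vm + params$mf * vf
  } else {
    v[[genotype_label(migrant_genotype(params$model))]]
  }
}

#' Export a fitness graph in DOT format
#'
#' @param graph A [fitness_graph()].
#' @param file Optional path; if given the DOT text is written there.
#' @return The DOT source as a character scalar, invisibly if `file` is set.
#' @examples
#' cat(graph_to_dot(fitness_graph(incompatibility_model("B", sA = 1, sB = 1))))
#' @export
graph_to_dot <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "fitness_graph"))
  esc <- function(x) gsub('"', "", x)
  node_lines <- vapply(graph$nodes, function(n) {
    shape <- if (n %in% graph$residents) "doublecircle"
             else if (n %in% graph$migrants) "box"
             else "ellipse"
    sprintf('  "%s" [shape=%s];', esc(n), shape)
  }, character(1))
  edge_lines <- vapply(seq_len(nrow(graph$edges)), function(i) {
    sprintf('  "%s" -> "%s" [label="%.6g"];',
            esc(graph$edges$from[i]), esc(graph$edges$to[i]),
            graph$edges$weight[i])
  }, character(1))
  dot <- paste(c(sprintf("digraph model_%s {", graph$params$model),
                 node_lines, edge_lines, "}"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
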