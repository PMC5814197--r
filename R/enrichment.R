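#' @rdname annotationMapping
#' @export
setMethod("annotationMapping", "GeneAnnotation", function(x) x@mapping)

#' @rdname termInfo
#' @export
setMethod("termInfo", "GeneAnnotation", function(x) x@terms)

#' @rdname genesWithTerm
#' @export
setMethod("genesWithTerm", "GeneAnnotation", function(x, terms) {
  unknown <- setdiff(terms, x@terms$term)
  if (length(unknown))
    stop("unknown term id: ", paste(unknown, collapse = ", "))
  sort(unique(x@mapping$gene[x@mapping$term %in% terms]))
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(unique(object@mapping$gene)), "genes,",
      nrow(object@terms), "terms (",
      sum(object@terms$namespace == "CC"), "CC /",
      sum(object@terms$namespace == "BP"), "BP ),",
      nrow(object@mapping), "assignments\n")
})

#' Filter a gene set by annotation terms
#'
#' Keeps the genes annotated with at least one of the listed terms (union
#' semantics over terms). Used for compartment extraction, e.g. restricting
#' the continuously up-regulated genes to the extracellular matrix and
#' extracellular space, or the down-regulated genes to the mitochondrion.
#'
#' @param genes character vector of gene ids
#' @param annotation a [GeneAnnotation-class]
#' @param terms term ids; each must exist in the annotation metadata. An
#'   empty term list returns the empty set.
#' @return sorted character subset of `genes`
#' @export
filterByTerms <- function(genes, annotation, terms) {
  if (!length(terms)) return(character())
  sort(intersect(genes, genesWithTerm(annotation, terms)))
}

#' Hypergeometric over-representation test of GO terms
#'
#' For every term of the chosen namespace that annotates at least one
#' background gene, tests whether the study set contains more term-annotated
#' genes than expected under sampling without replacement: the upper-tail
#' hypergeometric probability
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' with N the background size, K the term-annotated background genes, n the
#' study size and k the term-annotated study genes. Multiplicity is corrected
#' over the number of terms tested, Bonferroni by default.
#'
#' @param study character vector of gene ids (must be a subset of
#'   `background`)
#' @param background character vector defining the gene universe
#' @param annotation a [GeneAnnotation-class]
#' @param namespace `"BP"` or `"CC"`
#' @param correction `"bonferroni"` (default) or `"bh"`
#' @return data.frame sorted by raw p then term id, with columns `term`,
#'   `name`, `k`, `n`, `K`, `N`, `p`, `p_adj`, `fold` (fold enrichment
#'   (k/n)/(K/N))
#' @export
hypergeomEnrich <- function(study, background, annotation,
                            namespace = c("BP", "CC"),
                            correction = c("bonferroni", "bh")) {
  namespace <- match.arg(namespace)
  correction <- match.arg(correction)
  study <- unique(study); background <- unique(background)
  if (!length(background)) stop("background must be non-empty")
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  terms <- annotation@terms[annotation@terms$namespace == namespace, ,
                            drop = FALSE]
  map <- annotation@mapping[annotation@mapping$term %in% terms$term &
                              annotation@mapping$gene %in% background, ,
                            drop = FALSE]
  N <- length(background); n <- length(study)
  res <- lapply(seq_len(nrow(terms)), function(i) {
    g <- map$gene[map$term == terms$term[i]]
    K <- length(g)
    if (K == 0L) return(NULL)
    k <- sum(study %in% g)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = terms$term[i], name = terms$name[i],
               k = k, n = n, K = K, N = N, p = p,
               fold = if (n > 0) (k / n) / (K / N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      fold = numeric(), stringsAsFactors = FALSE))
  res$p_adj <- if (correction == "bonferroni")
    pmin(1, nrow(res) * res$p) else p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term),
             c("term", "name", "k", "n", "K", "N", "p", "p_adj", "fold")]
  rownames(res) <- NULL
  res
}
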