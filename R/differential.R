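# Vectorised two-group one-way ANOVA over the rows of a matrix.
# For two groups F equals the square of the pooled-variance t statistic on
# 1 and (nA + nB - 2) degrees of freedom.
.rowAnovaTwoGroup <- function(matA, matB) {
  nA <- ncol(matA); nB <- ncol(matB)
  mA <- rowMeans(matA); mB <- rowMeans(matB)
  ssA <- rowSums((matA - mA)^2)
  ssB <- rowSums((matB - mB)^2)
  df2 <- nA + nB - 2L
  pooled <- (ssA + ssB) / df2
  between <- (mA - mB)^2 / (1 / nA + 1 / nB)
  f <- between / pooled
  zeroVar <- pooled == 0
  f[zeroVar & between == 0] <- 0
  f[zeroVar & between > 0] <- Inf
  p <- pf(f, 1, df2, lower.tail = FALSE)
  # degenerate separation: p below machine range floored, never reported 0
  p[is.infinite(f)] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  p[f == 0] <- 1
  list(F = f, p = p, meanA = mA, meanB = mB)
}

#' Two-group one-way ANOVA
#'
#' One-way ANOVA of two groups: F on 1 and \eqn{n_a + n_b - 2} degrees of
#' freedom with an asymptotic p-value from the F distribution; identical to
#' the squared pooled-variance two-sample t test. Degenerate inputs are
#' defined, not errors: equal means with zero pooled variance give
#' `F = 0, p = 1` (no evidence), while separated means with zero pooled
#' variance give `F = Inf` with p floored at the smallest positive double.
#'
#' @param a,b numeric vectors of at least 2 finite values each
#' @return list with elements `F` and `p`
#' @examples
#' anovaTwoGroup(c(4.1, 4.9, 5.0), c(6.2, 6.8, 7.3))
#' @export
anovaTwoGroup <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient replicates: each group needs at least 2 samples")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("group values must be finite")
  r <- .rowAnovaTwoGroup(matrix(a, nrow = 1L), matrix(b, nrow = 1L))
  list(F = unname(r$F), p = unname(r$p))
}

#' Per-gene differential test for one stage transition
#'
#' Compares the later stage against the earlier stage of one transition for
#' every gene in the matrix: two-group one-way ANOVA on the log2 values,
#' Bonferroni family-wise correction with m = number of genes tested in this
#' transition, and a linear fold change computed as the ratio of group means
#' after back-transforming the log2 values (later over earlier).
#'
#' @param se SummarizedExperiment with assay `"log2"` and `colData$stage`
#' @param design a [StageDesign-class]
#' @param transition either a transition index in 1..K or a character pair
#'   `c(from, to)` of adjacent stage labels
#' @return data.frame with one row per gene: `gene`, `F`, `p`, `p_adj`,
#'   `fold_change`, `direction` (`up` if FC > 1, `down` if FC < 1, `none` at
#'   equality)
#' @seealso [selectDE()]
#' @export
testTransition <- function(se, design, transition) {
  if (is(se, "SyntheticDataset")) se <- expressionData(se)
  tr <- stageTransitions(design)
  if (is.numeric(transition)) {
    if (transition < 1L || transition > nrow(tr))
      stop("transition index out of range")
    from <- tr$from[transition]; to <- tr$to[transition]
  } else {
    if (length(transition) != 2L ||
        !all(transition %in% stageLabels(design)))
      stop("unknown stage name in transition")
    from <- transition[1L]; to <- transition[2L]
  }
  stage <- as.character(se$stage)
  iA <- which(stage == from); iB <- which(stage == to)
  if (length(iA) < 2L || length(iB) < 2L)
    stop("insufficient replicates: both stages need at least 2 samples")
  mat <- SummarizedExperiment::assay(se, "log2")
  r <- .rowAnovaTwoGroup(mat[, iA, drop = FALSE], mat[, iB, drop = FALSE])
  m <- nrow(mat)
  fc <- rowMeans(2^mat[, iB, drop = FALSE]) /
    rowMeans(2^mat[, iA, drop = FALSE])
  data.frame(
    gene = rownames(mat),
    F = unname(r$F),
    p = unname(r$p),
    p_adj = pmin(1, m * unname(r$p)),
    fold_change = unname(fc),
    direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially expressed genes from transition tests
#'
#' Applies the screen's selection rule to a [testTransition()] table: a gene
#' is up-regulated if its Bonferroni-adjusted p-value is below `alpha` and
#' its linear fold change is above 1 and at least `fcThreshold`;
#' down-regulation mirrors this with `1/fcThreshold`. The default
#' `fcThreshold = 1` makes the fold-change filter direction-only, the
#' operative rule when inter-stage expression differences are small.
#'
#' @param tests data.frame from [testTransition()]
#' @param alpha adjusted-p cutoff in `[0, 1]`
#' @param fcThreshold linear fold-change threshold (>= 1)
#' @param transition character pair recorded in the result (optional)
#' @return a [DESelection-class]; gene sets sorted by id
#' @export
selectDE <- function(tests, alpha = 0.05, fcThreshold = 1,
                     transition = c(NA_character_, NA_character_)) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (fcThreshold < 1) stop("fcThreshold must be at least 1")
  sig <- tests$p_adj < alpha
  up <- sort(tests$gene[sig & tests$fold_change > 1 &
                          tests$fold_change >= fcThreshold])
  down <- sort(tests$gene[sig & tests$fold_change < 1 &
                            tests$fold_change <= 1 / fcThreshold])
  new("DESelection", transition = as.character(transition),
      up = up, down = down, alpha = alpha, fcThreshold = fcThreshold)
}

#' Run the differential screen over every transition of a design
#'
#' @param se SummarizedExperiment (or [SyntheticDataset-class])
#' @param design a [StageDesign-class]
#' @param alpha,fcThreshold selection parameters, see [selectDE()]
#' @return named list of [DESelection-class], one per transition, in design
#'   order; names are `"from->to"`
#' @export
screenTransitions <- function(se, design, alpha = 0.05, fcThreshold = 1) {
  tr <- stageTransitions(design)
  out <- lapply(seq_len(nrow(tr)), function(j) {
    tests <- testTransition(se, design, j)
    selectDE(tests, alpha, fcThreshold,
             transition = c(tr$from[j], tr$to[j]))
  })
  names(out) <- paste(tr$from, tr$to, sep = "->")
  out
}

#' @rdname upGenes
#' @export
setMethod("upGenes", "DESelection", function(x) x@up)

#' @rdname downGenes
#' @export
setMethod("downGenes", "DESelection", function(x) x@down)

setMethod("show", "DESelection", function(object) {
  cat(sprintf("DESelection %s -> %s: %d up, %d down (alpha=%g, FC>=%g)\n",
              object@transition[1L], object@transition[2L],
              length(object@up), length(object@down),
              object@alpha, object@fcThreshold))
})
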