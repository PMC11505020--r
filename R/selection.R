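#' Sample Pearson correlation between a feature and the labels
#'
#' Direct two-pass evaluation of the product-moment correlation. Returns 0
#' when either vector is constant.
#'
#' @param feature numeric vector.
#' @param labels numeric vector of the same length (>= 2).
#' @return The correlation in `[-1, 1]`.
#' @export
pearsonCorrelation <- function(feature, labels) {
  if (length(feature) != length(labels))
    stopUsage("feature and labels differ in length")
  if (length(feature) < 2L) stopUsage("need at least 2 observations")
  fd <- feature - mean(feature)
  ld <- labels - mean(labels)
  den <- sqrt(sum(fd^2)) * sqrt(sum(ld^2))
  if (den == 0) return(0)
  sum(fd * ld) / den
}

#' Connection values: absolute feature-label correlation
#'
#' @param table a [FeatureTable-class] with labels.
#' @return Numeric vector `C_i = |PCC(F_i, l)|` in `[0, 1]`, one per feature.
#' @export
connectionValues <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  l <- as.numeric(table@labels)
  apply(table@values, 2L, function(f) abs(pearsonCorrelation(f, l)))
}

#' Distance values: mean inter-feature Euclidean distance
#'
#' `D_i` is the mean Euclidean distance between feature column i and every
#' other column. Columns are z-scored first by default so the statistic is
#' scale-free (a zero-variance column maps to the zero vector).
#'
#' @param table a [FeatureTable-class] with at least 2 features.
#' @param standardize z-score columns before computing distances.
#' @return Numeric vector `D_i >= 0`, one per feature.
#' @export
distanceValues <- function(table, standardize = TRUE) {
  stopifnot(is(table, "FeatureTable"))
  v <- table@values
  if (ncol(v) < 2L) stopUsage("distanceValues needs at least 2 features")
  if (standardize) v <- zscoreColumns(v)
  d <- sqrt(crossDist2(t(v), t(v)))
  (rowSums(d)) / (ncol(v) - 1L)
}

#' ESCD feature selection: maximise connection plus distance
#'
#' Scores every feature by `C_i + D_i`, where `C_i` is the absolute
#' feature-label correlation (relevance) and `D_i` the mean distance to the
#' other features (independence). `D_i` is computed on z-scored columns and
#' divided by its maximum so it lies in `[0, 1]` and is commensurate with
#' the bounded correlation term while keeping its relative spread (a
#' min-max stretch would blow near-tied distances up to the full unit
#' interval and drown the relevance term in noise). Ties break toward the
#' lower feature index.
#'
#' @param table a [FeatureTable-class].
#' @param q number of features to keep, `1 <= q <= Q`.
#' @return List with `scores` (data.frame: feature, connection, distance,
#'   score, rank) and `selected` (character names of the top-q features).
#' @export
escdSelect <- function(table, q) {
  stopifnot(is(table, "FeatureTable"))
  Q <- ncol(table@values)
  if (q < 1L || q > Q) stopUsage("q must lie in 1..%d", Q)
  C <- connectionValues(table)
  D <- distanceValues(table, standardize = TRUE)
  Ds <- if (max(D) > 0) D / max(D) else rep(0, length(D))
  score <- C + Ds
  ord <- order(-score, seq_len(Q))
  rank <- integer(Q); rank[ord] <- seq_len(Q)
  scores <- data.frame(feature = colnames(table@values), connection = C,
                       distance = Ds, score = score, rank = rank,
                       row.names = NULL)
  list(scores = scores, selected = colnames(table@values)[ord[seq_len(q)]])
}

## ---------------------------------------------------------------------------
## Genetic algorithm (binary masks, roulette selection, single-point
## crossover, elitism)
## ---------------------------------------------------------------------------

#' Genetic-algorithm configuration
#'
#' Defaults: population 300, 250 generations,
#' elitism 10, crossover probability 0.6, mutation probability 0.2,
#' iteration cap 500. The fitness of a mask is the evaluator accuracy minus
#' `lambda` times the selected-feature fraction, so accuracy dominates and
#' smaller masks break ties.
#'
#' @param populationSize N >= 2 individuals.
#' @param generations number of generations.
#' @param elitism number of elites copied unchanged each generation.
#' @param crossover crossover probability in `[0, 1]`.
#' @param mutation per-chromosome mutation probability in `[0, 1]` (a
#'   mutating chromosome flips each bit with probability 1/Q).
#' @param maxIterations hard cap on generations.
#' @param lambda feature-count penalty weight.
#' @param reciprocal use the reciprocal of fitness for roulette weights
#'   (a variant sometimes quoted, which favours the worst chromosomes);
#'   default FALSE = standard fitness-proportional selection.
#' @param seed integer seed.
#' @return A classed list `GAConfig`.
#' @export
gaConfig <- function(populationSize = 300L, generations = 250L, elitism = 10L,
                     crossover = 0.6, mutation = 0.2, maxIterations = 500L,
                     lambda = 0.01, reciprocal = FALSE, seed = 1L) {
  if (populationSize < 2L) stopUsage("populationSize must be >= 2")
  if (crossover < 0 || crossover > 1 || mutation < 0 || mutation > 1)
    stopUsage("probabilities must lie in [0, 1]")
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 elitism = as.integer(min(elitism, populationSize)),
                 crossover = crossover, mutation = mutation,
                 maxIterations = as.integer(maxIterations), lambda = lambda,
                 reciprocal = reciprocal, seed = as.integer(seed)),
            class = "GAConfig")
}

rouletteDraw <- function(fit, n, reciprocal = FALSE) {
  w <- if (reciprocal) 1 / pmax(fit, .Machine$double.eps) else fit
  if (any(w < 0)) w <- w - min(w)          # shift so weights are usable
  if (sum(w) <= 0) w <- rep(1, length(w))
  sample.int(length(fit), n, replace = TRUE, prob = w / sum(w))
}

singlePointCross <- function(a, b) {
  Q <- length(a)
  if (Q < 2L) return(list(a, b))
  cp <- sample.int(Q - 1L, 1L)
  list(c(a[seq_len(cp)], b[(cp + 1L):Q]), c(b[seq_len(cp)], a[(cp + 1L):Q]))
}

repairChromosome <- function(bits) {
  if (!any(bits == 1L)) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

#' GA search over binary feature masks
#'
#' Every feature is a gene; a chromosome is a 0/1 selection mask. Fitness is
#' `evaluator(bits) - lambda * mean(bits)`; selection is roulette, crossover
#' single-point, mutation bitwise, and `elitism` elites survive unchanged
#' (so the best-fitness history is non-decreasing).
#'
#' @param table a [FeatureTable-class] supplying the chromosome length, or
#'   directly an integer Q (for surrogate fitness landscapes).
#' @param config a [gaConfig()].
#' @param evaluator function mapping a 0/1 vector to an accuracy in `[0, 1]`.
#' @return List with `bits` (best mask), `fitness`, `history`
#'   (per-generation best fitness) and `evalCount`.
#' @export
gaSelect <- function(table, config, evaluator) {
  stopifnot(inherits(config, "GAConfig"))
  Q <- if (is(table, "FeatureTable")) ncol(featureValues(table))
       else as.integer(table)
  N <- config$populationSize
  gens <- min(config$generations, config$maxIterations)
  evalCount <- 0L
  fitOf <- function(bits) {
    acc <- evaluator(bits)
    if (!is.finite(acc))
      stopUsage("evaluator returned a non-finite fitness for mask [%s]",
                paste(bits, collapse = ""))
    evalCount <<- evalCount + 1L
    acc - config$lambda * sum(bits) / Q
  }
  withSeed(config$seed, {
    pop <- lapply(seq_len(N), function(i)
      repairChromosome(sample(c(0L, 1L), Q, replace = TRUE)))
    fit <- vapply(pop, fitOf, numeric(1))
    bestBits <- pop[[which.max(fit)]]
    bestFit <- max(fit)
    history <- bestFit
    for (g in seq_len(gens)) {
      ord <- order(-fit)
      nextPop <- pop[ord[seq_len(config$elitism)]]
      while (length(nextPop) < N) {
        par <- rouletteDraw(fit, 2L, config$reciprocal)
        pair <- if (stats::runif(1) < config$crossover)
          singlePointCross(pop[[par[1L]]], pop[[par[2L]]])
        else list(pop[[par[1L]]], pop[[par[2L]]])
        for (child in pair) {
          if (stats::runif(1) < config$mutation) {
            flip <- stats::runif(Q) < 1 / Q
            child[flip] <- 1L - child[flip]
          }
          nextPop[[length(nextPop) + 1L]] <- repairChromosome(child)
          if (length(nextPop) == N) break
        }
      }
      pop <- nextPop
      fit <- vapply(pop, fitOf, numeric(1))
      if (max(fit) > bestFit) {
        bestFit <- max(fit); bestBits <- pop[[which.max(fit)]]
      }
      history <- c(history, bestFit)
    }
    list(bits = bestBits, fitness = bestFit, history = history,
         evalCount = evalCount)
  })
}

# Real-coded GA over bounded hyperparameter genes; same operator suite as
# gaSelect with gene-resampling mutation. bounds: list of c(lo, hi, integer?)
gaOptimizeReal <- function(bounds, config, evaluator) {
  stopifnot(inherits(config, "GAConfig"))
  N <- config$populationSize
  gens <- min(config$generations, config$maxIterations)
  G <- length(bounds)
  decode <- function(v) {
    out <- v
    for (j in seq_len(G))
      if (isTRUE(bounds[[j]][3L] == 1)) out[j] <- roundHalfUp(out[j])
    out
  }
  drawGene <- function(j) stats::runif(1, bounds[[j]][1L], bounds[[j]][2L])
  withSeed(config$seed, {
    pop <- lapply(seq_len(N), function(i)
      vapply(seq_len(G), drawGene, numeric(1)))
    fit <- vapply(pop, function(v) evaluator(decode(v)), numeric(1))
    bestIdx <- which.max(fit)
    best <- pop[[bestIdx]]; bestFit <- fit[bestIdx]
    history <- bestFit
    for (g in seq_len(gens)) {
      ord <- order(-fit)
      nextPop <- pop[ord[seq_len(config$elitism)]]
      while (length(nextPop) < N) {
        par <- rouletteDraw(fit, 2L, config$reciprocal)
        a <- pop[[par[1L]]]; b <- pop[[par[2L]]]
        if (stats::runif(1) < config$crossover && G >= 2L) {
          cp <- sample.int(G - 1L, 1L)
          tmp <- a
          a <- c(a[seq_len(cp)], b[(cp + 1L):G])
          b <- c(b[seq_len(cp)], tmp[(cp + 1L):G])
        }
        for (child in list(a, b)) {
          if (stats::runif(1) < config$mutation) {
            j <- sample.int(G, 1L)
            child[j] <- drawGene(j)
          }
          nextPop[[length(nextPop) + 1L]] <- child
          if (length(nextPop) == N) break
        }
      }
      pop <- nextPop
      fit <- vapply(pop, function(v) evaluator(decode(v)), numeric(1))
      if (max(fit) > bestFit) {
        bestFit <- max(fit); best <- pop[[which.max(fit)]]
      }
      history <- c(history, bestFit)
    }
    list(values = decode(best), fitness = bestFit, history = history)
  })
}
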