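## Quantitative selection of the number of chromatin states: candidate
## models are compared against the most complex model by emission-row
## correlation, and by k-means goodness of fit on the pooled emission rows
## of all models. The selected K is the smallest one where both criteria
## exceed the threshold (default > 0.95).

#' Series of fitted models over a range of state numbers
#'
#' @param models named or unnamed list of [emission_model()]s; names
#'   default to each model's state count.
#' @return Object of class `model_series`; the reference model is the one
#'   with the largest K.
#' @export
model_series <- function(models) {
  stopifnot(length(models) > 0)
  Ks <- vapply(models, function(m) m$K, 0L)
  feats <- lapply(models, function(m) m$feature_names)
  if (!all(vapply(feats, identical, TRUE, feats[[1]])))
    stop("all models must share the feature set")
  o <- order(Ks)
  models <- models[o]; Ks <- Ks[o]
  if (anyDuplicated(Ks)) stop("duplicate state counts in series")
  names(models) <- as.character(Ks)
  structure(list(models = models, Ks = Ks, reference_K = max(Ks)),
            class = "model_series")
}

## Pearson correlation between two emission rows; zero-variance rows give 0.
row_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Median maximal state correlation between two models
#'
#' For each state of the reference model, the maximal Pearson correlation
#' of its emission row with any state of the candidate model; the median
#' over reference states is returned. Invariant to state order in either
#' model.
#'
#' @param reference,candidate [emission_model()]s over the same features.
#' @return Value in \[-1, 1\].
#' @export
median_max_state_correlation <- function(reference, candidate) {
  if (!identical(reference$feature_names, candidate$feature_names))
    stop("models must share the feature set")
  maxcor <- vapply(seq_len(reference$K), function(i) {
    max(vapply(seq_len(candidate$K), function(j)
      row_cor(reference$E[i, ], candidate$E[j, ]), 0))
  }, 0)
  stats::median(maxcor)
}

#' k-means goodness of fit on pooled emission rows
#'
#' k-means (k-means++ style multiple seeded restarts) on the pooled
#' emission rows of every model in the series; returns between-cluster
#' sum-of-squares over total sum-of-squares.
#'
#' @param series a [model_series()].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart number of restarts (default 10).
#' @return Value in \[0, 1\].
#' @export
kmeans_goodness <- function(series, k, seed = 1L, nstart = 10L) {
  stopifnot(inherits(series, "model_series"), k >= 1)
  pooled <- do.call(rbind, lapply(series$models, function(m) m$E))
  if (k > nrow(pooled)) stop("k exceeds the number of pooled emission rows")
  totss <- sum(scale(pooled, scale = FALSE)^2)
  if (totss == 0) return(1)
  distinct <- unique(pooled)
  if (k >= nrow(distinct)) return(1)   # each distinct point its own cluster
  if (k == 1) return(0)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(pooled, centers = k, nstart = nstart,
                                       iter.max = 100))
  km$betweenss / km$totss
}

#' Select the optimal number of chromatin states
#'
#' Returns the smallest K in the series whose model exceeds `threshold` on
#' both criteria: median maximal state correlation against the most
#' complex (reference) model, and k-means between/total sum-of-squares at
#' k = K on the pooled emission rows of all models. Both comparisons are
#' strict (`>`). If no K qualifies the largest K is returned with a
#' warning.
#'
#' @param series a [model_series()].
#' @param threshold criterion threshold (default 0.95).
#' @param seed seed for the k-means criterion.
#' @return List with `K_star`, and `criteria`, a per-K `data.frame` with
#'   columns `K`, `correlation`, `goodness`, `passes`.
#' @export
select_optimal_states <- function(series, threshold = 0.95, seed = 1L) {
  stopifnot(inherits(series, "model_series"))
  reference <- series$models[[as.character(series$reference_K)]]
  crit <- data.frame(K = series$Ks, correlation = NA_real_, goodness = NA_real_)
  for (i in seq_along(series$Ks)) {
    K <- series$Ks[i]
    crit$correlation[i] <-
      median_max_state_correlation(reference, series$models[[as.character(K)]])
    crit$goodness[i] <- kmeans_goodness(series, K, seed = seed)
  }
  crit$passes <- crit$correlation > threshold & crit$goodness > threshold
  if (any(crit$passes)) {
    K_star <- min(crit$K[crit$passes])
  } else {
    warning("no state count satisfies both criteria; returning the largest")
    K_star <- series$reference_K
  }
  list(K_star = K_star, criteria = crit)
}

#' Write the per-K selection criteria table
#' @param selection result of [select_optimal_states()].
#' @param path output TSV.
#' @export
write_selection_table <- function(selection, path) {
  utils::write.table(selection$criteria, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
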