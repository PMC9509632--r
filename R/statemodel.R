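## Multivariate Bernoulli-emission hidden Markov model over binarized
## tracks. Both conditions are modelled jointly ("concatenated"): every
## chromosome x condition is an independent observation sequence sharing a
## single parameter set, so state definitions are common to the two
## conditions and per-bin state calls are directly comparable.

E_CLAMP <- 1e-6

#' Bundle binary calls across features and conditions
#'
#' Stacks per-feature [binary_calls()] into per-sequence binary matrices.
#' Every chromosome x condition becomes one observation sequence (bins x
#' features).
#'
#' @param calls_list list of [binary_calls()], one per feature per
#'   condition; all must share chromosomes, bin counts and bin size.
#' @return Object of class `calls_bundle` with elements `sequences` (named
#'   list of binary matrices), `sequence_condition`, `sequence_chrom`,
#'   `feature_names`, `conditions`, `bin_size`.
#' @export
calls_bundle <- function(calls_list) {
  stopifnot(length(calls_list) > 0)
  feats <- vapply(calls_list, function(x) x$feature, "")
  conds <- vapply(calls_list, function(x) x$condition, "")
  feature_names <- unique(feats)
  conditions <- unique(conds)
  bin_size <- calls_list[[1]]$bin_size
  chroms <- names(calls_list[[1]]$calls)
  for (x in calls_list) {
    if (!identical(names(x$calls), chroms)) stop("all calls must share chromosomes")
    if (x$bin_size != bin_size) stop("all calls must share bin_size")
  }
  sequences <- list(); seq_cond <- character(0); seq_chrom <- character(0)
  for (cond in conditions) {
    sel <- calls_list[conds == cond]
    sel_feats <- vapply(sel, function(x) x$feature, "")
    if (!setequal(sel_feats, feature_names))
      stop("condition ", cond, " is missing features")
    sel <- sel[match(feature_names, sel_feats)]
    for (chr in chroms) {
      m <- vapply(sel, function(x) as.numeric(x$calls[[chr]]),
                  numeric(length(sel[[1]]$calls[[chr]])))
      m <- matrix(m, ncol = length(feature_names),
                  dimnames = list(NULL, feature_names))
      key <- paste(cond, chr, sep = ".")
      sequences[[key]] <- m
      seq_cond <- c(seq_cond, cond); seq_chrom <- c(seq_chrom, chr)
    }
  }
  structure(list(sequences = sequences, sequence_condition = seq_cond,
                 sequence_chrom = seq_chrom, feature_names = feature_names,
                 conditions = conditions, bin_size = bin_size),
            class = "calls_bundle")
}

#' Construct an emission model
#'
#' @param E K x F matrix of per-state per-feature Bernoulli emission
#'   probabilities (clamped to `[1e-6, 1 - 1e-6]`).
#' @param A K x K row-stochastic transition matrix.
#' @param pi initial state distribution.
#' @param feature_names character vector of length F.
#' @param bin_size bin width in bp.
#' @param loglik,seed optional fit metadata.
#' @return Object of class `emission_model`.
#' @export
emission_model <- function(E, A, pi, feature_names, bin_size = 200,
                           loglik = NA_real_, seed = NA_integer_) {
  E <- as.matrix(E); A <- as.matrix(A)
  K <- nrow(E)
  if (ncol(A) != K || nrow(A) != K) stop("A must be K x K")
  if (length(pi) != K) stop("pi must have length K")
  if (any(abs(rowSums(A) - 1) > 1e-6)) stop("A rows must sum to 1")
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  E <- pmin(pmax(E, E_CLAMP), 1 - E_CLAMP)
  colnames(E) <- feature_names
  structure(list(K = K, F = ncol(E), E = E, A = A, pi = as.numeric(pi),
                 feature_names = feature_names, bin_size = bin_size,
                 loglik = loglik, seed = seed),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf("emission_model: %d states x %d features (%s), loglik %.2f\n",
              x$K, x$F, paste(x$feature_names, collapse = ", "), x$loglik))
  invisible(x)
}

## per-sequence emission likelihood matrix B[t, k] = P(x_t | state k)
emission_lik <- function(X, E) {
  logB <- X %*% t(log(E)) + (1 - X) %*% t(log1p(-E))
  exp(logB)
}

init_model <- function(bundle, K, seed) {
  set.seed(seed)
  X <- do.call(rbind, bundle$sequences)
  F <- ncol(X)
  idx <- if (nrow(X) > 20000L) sample.int(nrow(X), 20000L) else seq_len(nrow(X))
  Xs <- X[idx, , drop = FALSE]
  centers <- tryCatch({
    km <- suppressWarnings(stats::kmeans(Xs, centers = K, nstart = 3, iter.max = 50))
    km$centers
  }, error = function(e) matrix(stats::runif(K * F, 0.1, 0.9), K, F))
  E <- centers + matrix(stats::runif(K * F, -0.05, 0.05), K, F)
  E <- pmin(pmax(E, 1e-3), 1 - 1e-3)
  A <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  pi <- rep(1 / K, K)
  list(E = E, A = A, pi = pi)
}

run_em <- function(bundle, K, init, max_iter, tol) {
  E <- init$E; A <- init$A; pi <- init$pi
  n_seq <- length(bundle$sequences)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    gamma_sum <- numeric(K); gamma_x <- matrix(0, K, ncol(E))
    xi_sum <- matrix(0, K, K); gamma_first <- numeric(K)
    ll <- 0
    for (X in bundle$sequences) {
      B <- emission_lik(X, E)
      st <- .hmm_estep(B, A, pi, X, FALSE)
      gamma_sum <- gamma_sum + st$gamma_sum
      gamma_x <- gamma_x + st$gamma_x
      xi_sum <- xi_sum + st$xi_sum
      gamma_first <- gamma_first + st$gamma_first
      ll <- ll + st$loglik
    }
    ll_trace <- c(ll_trace, ll)
    # M-step
    E <- pmin(pmax(gamma_x / gamma_sum, E_CLAMP), 1 - E_CLAMP)
    rs <- rowSums(xi_sum)
    for (k in seq_len(K)) {
      if (rs[k] > 0) A[k, ] <- xi_sum[k, ] / rs[k]
    }
    pi <- gamma_first / n_seq
    pi <- pi / sum(pi)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) break
    ll_prev <- ll
  }
  list(E = E, A = A, pi = pi, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace)
}

#' Fit the Bernoulli-emission chromatin-state HMM
#'
#' Baum-Welch EM with emission
#' `P(x | k) = prod_f E[k,f]^x_f (1 - E[k,f])^(1 - x_f)`. Each chromosome x
#' condition is an independent sequence sharing one parameter set
#' (concatenated two-condition training). Initialization is seeded,
#' perturbed k-means on the bin vectors with a 0.9 self-transition boost;
#' several restarts are run and the best log-likelihood kept, so the fit
#' is reproducible bit-wise for a fixed seed.
#'
#' @param bundle a [calls_bundle()].
#' @param K number of states.
#' @param seed integer seed controlling initialization.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance: EM stops when
#'   the absolute change falls below `tol * (|loglik| + 1)` (default 1e-6).
#' @param n_restarts number of seeded restarts (default 3).
#' @return An [emission_model()] with attributes `ll_trace` (per-iteration
#'   log-likelihood of the winning restart).
#' @export
fit_hmm <- function(bundle, K, seed = 1L, max_iter = 200L, tol = 1e-6,
                    n_restarts = 3L) {
  stopifnot(inherits(bundle, "calls_bundle"), K >= 1)
  n_bins <- sum(vapply(bundle$sequences, nrow, 0L))
  if (K > n_bins) stop("K exceeds the number of bins")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- init_model(bundle, K, seed = seed + r - 1L)
    fit <- run_em(bundle, K, init, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  model <- emission_model(best$E, best$A, best$pi, bundle$feature_names,
                          bin_size = bundle$bin_size, loglik = best$loglik,
                          seed = seed)
  attr(model, "ll_trace") <- best$ll_trace
  model
}

#' Decode per-bin chromatin states
#'
#' Posterior (forward-backward) decoding: each bin is assigned its argmax
#' posterior state. Deterministic given model and data.
#'
#' @param model an [emission_model()].
#' @param bundle a [calls_bundle()] with the model's feature set.
#' @return Object of class `segmentation`: `states` is a nested list
#'   `condition -> chromosome -> integer state labels (1..K)`.
#' @export
decode_states <- function(model, bundle) {
  stopifnot(inherits(model, "emission_model"), inherits(bundle, "calls_bundle"))
  if (!identical(model$feature_names, bundle$feature_names))
    stop("bundle features do not match the model")
  states <- list()
  for (i in seq_along(bundle$sequences)) {
    X <- bundle$sequences[[i]]
    B <- emission_lik(X, model$E)
    st <- .hmm_estep(B, model$A, model$pi, X, TRUE)
    lab <- max.col(st$gamma, ties.method = "first")
    cond <- bundle$sequence_condition[i]; chr <- bundle$sequence_chrom[i]
    states[[cond]][[chr]] <- lab
  }
  structure(list(states = states, K = model$K, bin_size = model$bin_size),
            class = "segmentation")
}

#' Posterior state probabilities for one sequence
#' @param model an [emission_model()].
#' @param X bins x features binary matrix.
#' @return bins x K posterior matrix (rows sum to 1).
#' @export
state_posteriors <- function(model, X) {
  B <- emission_lik(X, model$E)
  .hmm_estep(B, model$A, model$pi, X, TRUE)$gamma
}

#' Chromatin-state enrichment of a query interval set
#'
#' At bin granularity: for each state, the observed count of bins of that
#' state overlapped by the query, against the expectation
#' `query_bins * state_bins / total_bins`, with an upper-tail
#' hypergeometric p.
#'
#' @param seg a `segmentation` from [decode_states()].
#' @param condition which condition's state path to use.
#' @param query `GRanges` of query regions.
#' @param genome named chromosome lengths.
#' @return `data.frame` with one row per state: `state`, `state_bins`,
#'   `observed`, `expected`, `fold`, `p`.
#' @export
state_enrichment <- function(seg, condition, query, genome) {
  stopifnot(inherits(seg, "segmentation"))
  labels <- seg$states[[condition]]
  if (is.null(labels)) stop("unknown condition: ", condition)
  bin <- seg$bin_size
  K <- seg$K
  state_bins <- numeric(K); obs <- numeric(K)
  total_bins <- 0; query_bins <- 0
  qchrom <- as.character(GenomicRanges::seqnames(query))
  for (chr in names(labels)) {
    v <- labels[[chr]]
    total_bins <- total_bins + length(v)
    qb <- logical(length(v))
    sel <- which(qchrom == chr)
    if (length(sel) > 0L) {
      s0 <- GenomicRanges::start(query[sel]) - 1L
      e0 <- GenomicRanges::end(query[sel])
      b1 <- pmin(s0 %/% bin + 1L, length(v))
      b2 <- pmin((e0 - 1L) %/% bin + 1L, length(v))
      for (j in seq_along(sel)) qb[b1[j]:b2[j]] <- TRUE
    }
    query_bins <- query_bins + sum(qb)
    for (k in seq_len(K)) {
      state_bins[k] <- state_bins[k] + sum(v == k)
      obs[k] <- obs[k] + sum(qb & v == k)
    }
  }
  expected <- query_bins * state_bins / total_bins
  fold <- ifelse(expected > 0, obs / expected, NA_real_)
  p <- vapply(seq_len(K), function(k) {
    if (state_bins[k] == 0 || query_bins == 0) return(1)
    hypergeom_upper_tail(obs[k], query_bins, state_bins[k], total_bins)
  }, 0)
  data.frame(state = seq_len(K), state_bins = state_bins, observed = obs,
             expected = expected, fold = fold, p = p)
}
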