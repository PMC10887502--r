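# Expectation maximization over phylotree-derived fragment likelihoods:
# joint estimation of contributor haplogroups and mixture proportions.

# Core EM on a precomputed log-likelihood matrix (rows = fragments,
# columns = candidates). Log-space E-step; M-step averages
# responsibilities. Returns the fitted state.
em_core <- function(L, tol = 1e-4, max_iter = 500L, init = NULL) {
  N <- nrow(L); H <- ncol(L)
  if (N < 1L) stop_data("nothing to deconvolute: zero informative fragments")
  pi <- if (is.null(init)) rep(1 / H, H) else init / sum(init)
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  resp <- NULL
  repeat {
    iter <- iter + 1L
    A <- sweep(L, 2L, log(pi), "+")
    A[, pi == 0] <- -Inf
    m <- A[cbind(seq_len(N), max.col(A, ties.method = "first"))]
    W <- exp(A - m)
    denom <- rowSums(W)
    ll <- sum(m + log(denom))
    if (length(trace) && ll < trace[length(trace)] - 1e-8 * (1 + abs(ll))) {
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.10g -> %.10g)",
                   iter, trace[length(trace)], ll))
    }
    trace <- c(trace, ll)
    resp <- W / denom
    pi_new <- colMeans(resp)
    delta <- max(abs(pi_new - pi))
    pi <- pi_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  names(pi) <- colnames(L)
  colnames(resp) <- colnames(L)
  structure(list(pi = pi, resp = resp, loglik = trace[length(trace)],
                 trace = trace, iterations = iter, converged = converged,
                 candidates = colnames(L), L = L,
                 n_fragments = N),
            class = "em_state")
}

#' Fit mixture proportions over candidate haplogroups by EM
#'
#' E-step: fragment responsibilities `r_ih` proportional to
#' `pi_h * exp(l_ih)` (computed in log space). M-step:
#' `pi_h = mean_i r_ih`. Iterates until the largest proportion change falls
#' below `tol` or `max_iter` is reached. The log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param obs an [build_observations()] matrix.
#' @param tree a `phylotree` with its reference attached.
#' @param candidates candidate haplogroup names (default: every tree node).
#' @param tol convergence tolerance on `max |delta pi|`.
#' @param max_iter iteration cap.
#' @param init optional initial proportions (default uniform,
#'   deterministic).
#' @param n_restarts optional extra seeded random restarts; the best
#'   log-likelihood wins.
#' @param seed seed for the random restarts.
#' @return object of class `em_state` with fields `pi`, `resp`, `loglik`,
#'   `trace`, `iterations`, `converged`, `candidates`.
#' @export
em_fit <- function(obs, tree, candidates = NULL, tol = 1e-4, max_iter = 500L,
                   init = NULL, n_restarts = 0L, seed = NULL) {
  candidates <- candidates %||% names(tree$nodes)
  L <- loglik_matrix(obs, tree, candidates)
  best <- em_core(L, tol, max_iter, init)
  if (n_restarts > 0L) {
    for (r in seq_len(n_restarts)) {
      start <- with_seed(derive_seed(seed %||% 1L, r), {
        x <- stats::rgamma(ncol(L), 1); x / sum(x)
      })
      alt <- em_core(L, tol, max_iter, start)
      if (alt$loglik > best$loglik) best <- alt
    }
  }
  best
}

#' @export
print.em_state <- function(x, ...) {
  top <- sort(x$pi, decreasing = TRUE)
  top <- top[top > 0.001]
  cat(sprintf("<em_state> %d fragments, %d candidates, logLik %.2f, %d iterations%s\n",
              x$n_fragments, length(x$candidates), x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  for (nm in names(utils::head(top, 8))) {
    cat(sprintf("  %-14s %6.3f\n", nm, top[[nm]]))
  }
  invisible(x)
}

#' Coarse candidate pruning before EM
#'
#' Drops haplogroups that are never competitive: a candidate is kept only if
#' at least `min_support` fragments score within `log_margin` of that
#' fragment's best candidate. Intended for large trees; at mini-tree scale
#' the full candidate set is cheap and pruning is unnecessary.
#'
#' @param obs an [build_observations()] matrix.
#' @param tree a `phylotree`.
#' @param candidates candidate names (default all).
#' @param log_margin closeness margin on the log-likelihood.
#' @param min_support minimum number of near-best fragments.
#' @return character vector of surviving candidate names.
#' @export
prune_candidates <- function(obs, tree, candidates = NULL,
                             log_margin = log(2), min_support = 1L) {
  candidates <- candidates %||% names(tree$nodes)
  L <- loglik_matrix(obs, tree, candidates)
  best <- apply(L, 1L, max)
  near <- L >= best - log_margin
  keep <- colSums(near) >= min_support
  candidates[keep]
}
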