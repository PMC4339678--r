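#' Run configuration for a factorization
#'
#' Bundles every tunable of a run. Defaults for the convergence parameters
#' follow the tool's canonical invocation: test every `j = 10` iterations,
#' declare convergence after `t = 40` consecutive stable tests, cap at
#' `i = 2000` iterations.
#'
#' @param k factorization rank (number of metagenes), `k >= 1`.
#' @param test_period iterations between convergence tests (`j`).
#' @param stability consecutive stable tests required (`t`).
#' @param max_iters iteration cap (`i`).
#' @param seed integer seed for the random initialization of W and H.
#' @param epsilon small positive guard added to denominators; default
#'   `2^-52` (double-precision machine epsilon).
#' @param precision `"double"` or `"single"`; selects the on-disk element
#'   size used in binary I/O and block planning. In-memory arithmetic is
#'   always double.
#' @param budget_bytes optional memory budget for blockwise execution.
#' @param workers worker count for the data-parallel mode.
#' @param track_objective if `TRUE`, record the KL divergence after every
#'   iteration in the report (costs one extra n x m product per iteration).
#' @return an object of class `"nmf_config"`.
#' @export
nmf_config <- function(k, test_period = 10L, stability = 40L,
                       max_iters = 2000L, seed = 0L,
                       epsilon = .Machine$double.eps,
                       precision = c("double", "single"),
                       budget_bytes = NULL, workers = 1L,
                       track_objective = FALSE) {
  precision <- match.arg(precision)
  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
      bnmf_config_error(sprintf("%s must be a single integer >= %d", name, min))
    as.integer(x)
  }
  k <- chk_count(k, "k")
  cfg <- structure(list(
    k = k,
    test_period = chk_count(test_period, "test_period"),
    stability = chk_count(stability, "stability"),
    max_iters = chk_count(max_iters, "max_iters"),
    seed = chk_count(seed, "seed", min = 0L),
    epsilon = epsilon,
    precision = precision,
    budget_bytes = budget_bytes,
    workers = chk_count(workers, "workers"),
    track_objective = isTRUE(track_objective)
  ), class = "nmf_config")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    bnmf_config_error("epsilon must be a positive number")
  if (!is.null(budget_bytes) &&
      (!is.numeric(budget_bytes) || length(budget_bytes) != 1L || budget_bytes <= 0))
    bnmf_config_error("budget_bytes must be a positive number")
  cfg
}

#' Seeded random initialization of the factor pair
#'
#' Fills W (n x k) and H (k x m) with i.i.d. uniform draws on (0, 1) —
#' strictly positive, so no entry is absorbed at zero by the multiplicative
#' updates — and caches the column sums of W and row sums of H that the
#' update-rule denominators consume. The same `(n, m, k, seed)` always
#' yields bit-identical factors; the caller's RNG state is left untouched.
#'
#' @param n,m,k dimensions of V and the rank.
#' @param seed integer seed.
#' @return a list with `W`, `H`, `col_sums_W` (length-k), `row_sums_H`
#'   (length-k).
#' @export
nmf_init <- function(n, m, k, seed = 0L) {
  if (n < 1L || m < 1L) bnmf_config_error("dimensions must be positive")
  if (k < 1L || k > min(n, m))
    bnmf_config_error(sprintf("k must satisfy 1 <= k <= min(n, m) = %d", min(n, m)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  W <- matrix(runif(n * k), nrow = n, ncol = k)
  H <- matrix(runif(k * m), nrow = k, ncol = m)
  list(W = W, H = H, col_sums_W = colSums(W), row_sums_H = rowSums(H))
}

check_conformable <- function(V, W, H) {
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H))
    bnmf_dim_error(sprintf(
      "non-conformable shapes: V %dx%d, W %dx%d, H %dx%d",
      nrow(V), ncol(V), nrow(W), ncol(W), nrow(H), ncol(H)))
  if (any(V < 0) || any(W < 0) || any(H < 0))
    bnmf_domain_error("non-negative input required for the update rules")
}

# Core of the H rule restricted to a set of columns: Vb and Hb are the
# corresponding column slices; csW is the (cached) vector of column sums of
# the full W. Recycling divides each column of the k x b numerator by csW.
h_rule_block <- function(Vb, W, Hb, csW, epsilon) {
  Hb * crossprod(W, Vb / (W %*% Hb + epsilon)) / (csW + epsilon)
}

# W rule restricted to a set of rows; rsH is the row-sum vector of the full
# (already updated) H.
w_rule_block <- function(Vb, Wb, H, rsH, epsilon) {
  num <- Wb * ((Vb / (Wb %*% H + epsilon)) %*% t(H))
  sweep(num, 2L, rsH + epsilon, "/")
}

#' One multiplicative update of H
#'
#' Applies the divergence-minimizing rule
#' `H_pj <- H_pj * (sum_i W_ip V_ij / (WH)_ij) / (sum_r W_rp)`
#' elementwise, with `epsilon` guarding both quotient denominators. The
#' inputs are not modified.
#'
#' @param V n x m non-negative data matrix.
#' @param W n x k current basis (metagene) matrix.
#' @param H k x m current coefficient matrix.
#' @param epsilon denominator guard.
#' @return the updated k x m matrix H'.
#' @export
nmf_update_h <- function(V, W, H, epsilon = .Machine$double.eps) {
  check_conformable(V, W, H)
  h_rule_block(V, W, H, colSums(W), epsilon)
}

#' One multiplicative update of W
#'
#' Applies `W_ip <- W_ip * (sum_j V_ij H_pj / (WH)_ij) / (sum_t H_pt)`.
#' By symmetry this is the H rule on the transposed problem:
#' `nmf_update_w(V, W, H) == t(nmf_update_h(t(V), t(H), t(W)))`.
#'
#' @inheritParams nmf_update_h
#' @return the updated n x k matrix W'.
#' @export
nmf_update_w <- function(V, W, H, epsilon = .Machine$double.eps) {
  check_conformable(V, W, H)
  w_rule_block(V, W, H, rowSums(H), epsilon)
}

#' Generalized Kullback-Leibler divergence D(V || WH)
#'
#' `D = sum_ij (V_ij log(V_ij / (WH)_ij) - V_ij + (WH)_ij)` with the
#' convention `0 log 0 = 0`; the value is `+Inf` when some `(WH)_ij = 0`
#' where `V_ij > 0`. Zero exactly when `V = WH`.
#'
#' @inheritParams nmf_update_h
#' @return a non-negative scalar (possibly `Inf`).
#' @export
kl_divergence <- function(V, W, H) {
  check_conformable(V, W, H)
  A <- W %*% H
  pos <- V > 0
  if (any(pos & A == 0)) return(Inf)
  term <- numeric(length(V))
  term[pos] <- V[pos] * log(V[pos] / A[pos])
  sum(term) - sum(V) + sum(A)
}

# --- convergence-driven iteration driver -----------------------------------
# step_fn(iter) advances the factors one full iteration (H pass then W pass)
# inside its closure environment; assign_fn() reads the current sample
# assignment; divergence_fn() the current objective. Shared by all fit modes.
nmf_run_loop <- function(cfg, step_fn, assign_fn, divergence_fn) {
  state <- new_convergence_state()
  trace <- if (cfg$track_objective) numeric(cfg$max_iters)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iters)) {
    step_fn(it)
    iters <- it
    if (cfg$track_objective) trace[it] <- divergence_fn()
    if (should_test(it, cfg$test_period)) {
      res <- record_test(state, assign_fn(), cfg$stability)
      state <- res$state
      if (res$converged) { converged <- TRUE; break }
    }
  }
  report <- list(
    converged = converged,
    stop_reason = if (converged) "stable" else "max_iters",
    iterations_run = iters,
    tests_run = state$tests_run,
    final_divergence = divergence_fn(),
    final_assignment = assign_fn()
  )
  if (cfg$track_objective) report$objective_trace <- trace[seq_len(iters)]
  report
}

new_nmf_fit <- function(pair, report, extra = list()) {
  structure(c(list(W = pair$W, H = pair$H,
                   col_sums_W = pair$col_sums_W,
                   row_sums_H = pair$row_sums_H),
              report, extra),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: %d x %d = (%d x %d) (%d x %d)\n",
              nrow(x$W), ncol(x$H), nrow(x$W), ncol(x$W), nrow(x$H), ncol(x$H)))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations_run, x$stop_reason))
  cat(sprintf("  KL divergence: %.6g\n", x$final_divergence))
  k <- nrow(x$H)
  tab <- tabulate(x$final_assignment + 1L, nbins = k)
  cat(sprintf("  samples per factor: %s\n", paste(tab, collapse = " ")))
  invisible(x)
}

#' In-memory NMF fit
#'
#' Alternates the H update then the W update (the H pass accumulates the
#' row sums of H that the W rule's denominator needs) until the
#' sample-to-factor assignment is stable over `stability` consecutive tests
#' taken every `test_period` iterations, or until `max_iters`.
#'
#' @param V non-negative n x m matrix (genes x samples); dimnames, if any,
#'   are propagated to the factors.
#' @param cfg an [nmf_config()].
#' @return an object of class `"nmf_fit"`: the factors `W`, `H`, their
#'   cached sum vectors, and the convergence report (`converged`,
#'   `stop_reason`, `iterations_run`, `final_divergence`,
#'   `final_assignment`, and `objective_trace` when tracked).
#' @examples
#' d <- make_planted(n = 60, m = 12, k = 3, seed = 1)
#' fit <- nmf_fit(d$V, nmf_config(k = 3, seed = 1))
#' table(fit$final_assignment, d$labels_true)
#' @export
nmf_fit <- function(V, cfg) {
  validate_matrix(V, "V")
  if (!inherits(cfg, "nmf_config")) bnmf_config_error("cfg must be an nmf_config")
  n <- nrow(V); m <- ncol(V)
  if (cfg$k > min(n, m))
    bnmf_config_error(sprintf("k = %d exceeds min(n, m) = %d", cfg$k, min(n, m)))
  pair <- nmf_init(n, m, cfg$k, cfg$seed)
  eps <- cfg$epsilon
  env <- environment()
  step <- function(it) {
    pair$H <- h_rule_block(V, pair$W, pair$H, pair$col_sums_W, eps)
    pair$row_sums_H <- rowSums(pair$H)
    pair$W <- w_rule_block(V, pair$W, pair$H, pair$row_sums_H, eps)
    pair$col_sums_W <- colSums(pair$W)
    assign("pair", pair, envir = env)
  }
  report <- nmf_run_loop(cfg, step,
                         function() sample_assignment(pair$H),
                         function() kl_divergence(V, pair$W, pair$H))
  pair <- label_factors(pair, V)
  new_nmf_fit(pair, report)
}

# propagate V's dimnames onto the factors; factor axis labeled f0..f(k-1)
label_factors <- function(pair, V) {
  k <- ncol(pair$W)
  f <- paste0("f", seq_len(k) - 1L)
  dimnames(pair$W) <- list(rownames(V), f)
  dimnames(pair$H) <- list(f, colnames(V))
  pair
}
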