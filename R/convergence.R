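#' Assign each sample to its dominant factor
#'
#' For each sample (column) `j` of H, returns the index of the factor `p`
#' maximizing `H[p, j]`. Ties go to the lowest factor index. Indices are
#' 0-based, matching the factor labels `f0 .. f(k-1)` used on outputs.
#'
#' @param H k x m coefficient matrix.
#' @return an integer vector of length m with entries in `[0, k)`.
#' @export
sample_assignment <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1L || ncol(H) < 1L)
    bnmf_dim_error("H must be a non-empty matrix")
  max.col(t(H), ties.method = "first") - 1L
}

#' Assign each gene to its dominant factor
#'
#' The row-wise counterpart of [sample_assignment()] on W: gene `i` belongs
#' to the metagene whose coefficient `W[i, p]` is largest (lowest index on
#' ties). Together the two assignments give the biclustering view of the
#' factorization.
#'
#' @param W n x k basis matrix.
#' @return an integer vector of length n with entries in `[0, k)`.
#' @export
gene_assignment <- function(W) {
  if (!is.matrix(W) || nrow(W) < 1L || ncol(W) < 1L)
    bnmf_dim_error("W must be a non-empty matrix")
  max.col(W, ties.method = "first") - 1L
}

new_convergence_state <- function() {
  list(last_assignment = NULL, stable_count = 0L, tests_run = 0L)
}

#' Record one convergence test
#'
#' Compares the current sample assignment with the one from the previous
#' test. An exact elementwise match increments the run of stable tests;
#' any difference resets it to zero. Convergence is declared once
#' `threshold` consecutive comparisons have found no change.
#'
#' @param state a convergence state (as returned by previous calls; pass
#'   the result of an internal fresh state for the first test).
#' @param assignment integer vector from [sample_assignment()].
#' @param threshold required run of stable comparisons (`t`).
#' @return a list with the updated `state` and a `converged` flag.
#' @export
record_test <- function(state, assignment, threshold) {
  if (threshold < 1L) bnmf_config_error("threshold must be >= 1")
  if (!is.null(state$last_assignment) &&
      length(state$last_assignment) != length(assignment))
    bnmf_state_error(sprintf(
      "assignment length changed between tests: %d then %d",
      length(state$last_assignment), length(assignment)))
  if (!is.null(state$last_assignment) &&
      all(state$last_assignment == assignment)) {
    state$stable_count <- state$stable_count + 1L
  } else {
    state$stable_count <- 0L
  }
  state$last_assignment <- assignment
  state$tests_run <- state$tests_run + 1L
  list(state = state, converged = state$stable_count >= threshold)
}

#' Should a convergence test run at this iteration?
#'
#' @param iteration 1-based iteration counter.
#' @param test_period test period `j`.
#' @return `TRUE` every `test_period`-th iteration.
#' @export
should_test <- function(iteration, test_period) {
  iteration %% test_period == 0L
}
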