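#' Synthetic expression matrix with planted factor structure
#'
#' Emulates a gene-expression matrix (genes in rows, samples in columns)
#' whose low-rank structure is known. Each sample is owned by one of the
#' `k` factors, assigned round-robin so every factor owns at least one
#' sample; in `H_true` the owning factor's coefficient is `separation`
#' times the off-block coefficients, so the planted labels are exactly the
#' argmax assignment of `H_true`. `W_true` is strictly positive uniform.
#' Optional additive noise is half-normal with scale
#' `noise_level * mean(W_true %*% H_true)`; `V` is their (already
#' non-negative) sum. Row labels `gene0001...` and column labels
#' `sample01...` exercise the labeled I/O paths.
#'
#' @param n,m number of genes and samples.
#' @param k planted rank; `k <= min(n, m)`.
#' @param separation ratio of owned to off-block coefficients, `> 1`.
#' @param noise_level half-normal noise scale relative to the mean signal;
#'   `0` gives an exactly rank-`k` matrix.
#' @param seed integer seed; same seed, same dataset.
#' @return a list: `V` (labeled n x m matrix), `W_true`, `H_true`,
#'   `labels_true` (0-based integer m-vector), `noise_level`, `seed`.
#' @export
make_planted <- function(n, m, k, separation = 10, noise_level = 0, seed = 0L) {
  if (k < 1L || k > min(n, m))
    bnmf_config_error(sprintf("k must satisfy 1 <= k <= min(n, m) = %d", min(n, m)))
  if (m < k) bnmf_config_error("need m >= k so every factor owns a sample")
  if (separation <= 1) bnmf_config_error("separation must exceed 1")
  if (noise_level < 0) bnmf_config_error("noise_level must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  labels <- rep(seq_len(k) - 1L, length.out = m)
  # per-sample expression scale; owned coefficient beats every off-block
  # coefficient in its column by exactly the separation ratio
  scale_j <- runif(m, min = 0.5, max = 1.5)
  H_true <- matrix(rep(scale_j, each = k), nrow = k, ncol = m)
  H_true[cbind(labels + 1L, seq_len(m))] <- separation * scale_j
  W_true <- matrix(runif(n * k, min = 0.1, max = 1), nrow = n, ncol = k)
  V <- W_true %*% H_true
  if (noise_level > 0) {
    noise <- abs(rnorm(n * m, sd = noise_level * mean(V)))
    V <- V + matrix(noise, nrow = n, ncol = m)
  }
  rownames(V) <- sprintf("gene%0*d", max(4L, nchar(n)), seq_len(n))
  colnames(V) <- sprintf("sample%0*d", max(2L, nchar(m)), seq_len(m))
  validate_matrix(V, "planted V")
  list(V = V, W_true = W_true, H_true = H_true,
       labels_true = labels, noise_level = noise_level, seed = seed)
}

#' Catalog of tiny worked instances
#'
#' Fixed, hand-checkable cases reused across the test suite:
#' \describe{
#'   \item{fixed_point}{`W = [1; 2]`, `H = [3 4]`, `V = W H` exactly — both
#'     update rules leave the factors unchanged.}
#'   \item{column_mean}{`W = [1; 1]`, `V = [2; 4]`, any positive `H = [h]` —
#'     one H update lands on the column mean, `[3]`.}
#'   \item{oracle_2x2}{a 2 x 2, k = 2 instance whose updates are checked
#'     against a scalar-loop evaluation of the rules.}
#' }
#'
#' @return a named list of lists with elements `V`, `W`, `H`.
#' @export
worked_instances <- function() {
  fixed_W <- matrix(c(1, 2), nrow = 2)
  fixed_H <- matrix(c(3, 4), nrow = 1)
  list(
    fixed_point = list(V = fixed_W %*% fixed_H, W = fixed_W, H = fixed_H),
    column_mean = list(V = matrix(c(2, 4), nrow = 2),
                       W = matrix(c(1, 1), nrow = 2),
                       H = matrix(0.5, nrow = 1, ncol = 1)),
    oracle_2x2 = list(V = matrix(c(1, 3, 2, 4), nrow = 2),
                      W = matrix(c(1, 3, 2, 1), nrow = 2),
                      H = matrix(0.5, nrow = 2, ncol = 2))
  )
}
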