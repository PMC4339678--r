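#' Partition a problem among workers
#'
#' Balanced contiguous split of the m columns (for the H pass) and the n
#' rows (for the W pass) among `P` workers: range sizes differ by at most
#' one, larger ranges first, deterministic for given `(n, m, P)`.
#'
#' @param n,m problem dimensions.
#' @param P worker count, `1 <= P <= min(n, m)`.
#' @return a list of `P` worker partitions, each with `rank` (0-based),
#'   `my_cols`, `my_rows` (inclusive 1-based `[start, end]`), and the
#'   global `all_col_ranges` / `all_row_ranges` tables.
#' @export
make_partition <- function(n, m, P) {
  if (P < 1L || P > min(n, m))
    bnmf_config_error(sprintf("workers must satisfy 1 <= P <= min(n, m) = %d", min(n, m)))
  n <- as.integer(n); m <- as.integer(m); P <- as.integer(P)
  split_ranges <- function(total, P) {
    sizes <- rep(total %/% P, P)
    extra <- total %% P
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    Map(c, starts, ends)
  }
  cols <- split_ranges(m, P)
  rows <- split_ranges(n, P)
  lapply(seq_len(P), function(w) list(
    rank = w - 1L, P = P,
    my_cols = cols[[w]], my_rows = rows[[w]],
    all_col_ranges = cols, all_row_ranges = rows
  ))
}

check_contributions <- function(parts, partials, P, what) {
  if (length(parts) != P || length(partials) != P ||
      any(vapply(parts, is.null, logical(1L))) ||
      any(vapply(partials, is.null, logical(1L))))
    bnmf_sync_error(sprintf("missing worker contribution in %s collective", what))
}

#' Collective synchronization after the H update
#'
#' All-gather of the column slices each worker updated, plus all-reduce
#' (elementwise sum, fixed ascending rank order) of the partial k-length
#' row-sum vectors. Every worker leaves the collective holding the
#' identical full H and the identical global `row_sums_H`.
#'
#' @param h_parts list of k x (owned columns) matrices, in rank order.
#' @param partial_row_sums list of partial k-vectors, in rank order.
#' @return list with the assembled `H` and global `row_sums_H`.
#' @export
sync_after_h <- function(h_parts, partial_row_sums) {
  check_contributions(h_parts, partial_row_sums, length(h_parts), "H")
  list(H = do.call(cbind, h_parts),
       row_sums_H = Reduce(`+`, partial_row_sums))
}

#' Collective synchronization after the W update
#'
#' Row-wise counterpart of [sync_after_h()].
#'
#' @param w_parts list of (owned rows) x k matrices, in rank order.
#' @param partial_col_sums list of partial k-vectors, in rank order.
#' @return list with the assembled `W` and global `col_sums_W`.
#' @export
sync_after_w <- function(w_parts, partial_col_sums) {
  check_contributions(w_parts, partial_col_sums, length(w_parts), "W")
  list(W = do.call(rbind, w_parts),
       col_sums_W = Reduce(`+`, partial_col_sums))
}

#' Data-parallel NMF fit
#'
#' Mirrors the multi-device scheme: V is partitioned among `cfg$workers`
#' workers (columns for the H pass, rows for the W pass), W and H are fully
#' replicated, and a collective synchronization follows each update rule —
#' exactly two collectives per iteration. Workers are executed in-process;
#' identical seeding replicates the initial factors without a broadcast.
#' Convergence is evaluated on the replicated H, so every worker stops at
#' the same iteration with the same result; with one worker the run is
#' bit-identical to [nmf_fit()].
#'
#' @param V non-negative n x m matrix.
#' @param cfg an [nmf_config()] with `workers` set.
#' @return an `"nmf_fit"` object; `$collective_steps` counts the
#'   synchronization steps performed.
#' @export
nmf_fit_distributed <- function(V, cfg) {
  validate_matrix(V, "V")
  if (!inherits(cfg, "nmf_config")) bnmf_config_error("cfg must be an nmf_config")
  n <- nrow(V); m <- ncol(V)
  if (cfg$k > min(n, m))
    bnmf_config_error(sprintf("k = %d exceeds min(n, m) = %d", cfg$k, min(n, m)))
  parts <- make_partition(n, m, cfg$workers)
  # every worker seeds identically, so the replicas agree at init
  replicas <- lapply(parts, function(p) nmf_init(n, m, cfg$k, cfg$seed))
  pair <- replicas[[1L]]
  eps <- cfg$epsilon
  collectives <- 0L
  env <- environment()
  step <- function(it) {
    h_parts <- lapply(parts, function(p) {
      rg <- p$my_cols
      h_rule_block(V[, rg[1L]:rg[2L], drop = FALSE], pair$W,
                   pair$H[, rg[1L]:rg[2L], drop = FALSE],
                   pair$col_sums_W, eps)
    })
    synced <- sync_after_h(h_parts, lapply(h_parts, rowSums))
    collectives <- collectives + 1L
    pair$H <- synced$H
    pair$row_sums_H <- synced$row_sums_H
    w_parts <- lapply(parts, function(p) {
      rg <- p$my_rows
      w_rule_block(V[rg[1L]:rg[2L], , drop = FALSE],
                   pair$W[rg[1L]:rg[2L], , drop = FALSE],
                   pair$H, pair$row_sums_H, eps)
    })
    synced <- sync_after_w(w_parts, lapply(w_parts, colSums))
    collectives <- collectives + 1L
    pair$W <- synced$W
    pair$col_sums_W <- synced$col_sums_W
    assign("pair", pair, envir = env)
    assign("collectives", collectives, envir = env)
  }
  report <- nmf_run_loop(cfg, step,
                         function() sample_assignment(pair$H),
                         function() kl_divergence(V, pair$W, pair$H))
  pair <- label_factors(pair, V)
  new_nmf_fit(pair, report, extra = list(collective_steps = collectives,
                                         workers = cfg$workers))
}
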