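#' Plan column and row blocks under a memory budget
#'
#' W and H stay fully resident; V is streamed through the budgeted region in
#' column blocks of width `b_m` during the H pass and row blocks of height
#' `b_n` during the W pass. The footprint model for a column block of width
#' `b` counts, in elements:
#' `n*k (W) + k*m (H) + n*b (V block) + n*b (WH block) + k*b (intermediate)
#' + k (accumulator)`; the row-block footprint is symmetric with `m` in
#' place of `n`. The plan picks the largest feasible block in each
#' direction; a budget covering the full matrix degenerates to one block.
#'
#' @param n,m,k problem dimensions.
#' @param element_size bytes per scalar (8 for double, 4 for single).
#' @param budget_bytes memory budget the plan must satisfy.
#' @param bm,bn optional explicit overrides for the block widths; each must
#'   itself fit the budget.
#' @return an object of class `"block_plan"`: `bm`, `bn`, `col_blocks` and
#'   `row_blocks` (lists of inclusive `[start, end]` 1-based index pairs),
#'   `budget_bytes`, `element_size`.
#' @export
plan_blocks <- function(n, m, k, element_size = 8L, budget_bytes,
                        bm = NULL, bn = NULL) {
  if (n < 1L || m < 1L || k < 1L) bnmf_config_error("dimensions must be positive")
  if (budget_bytes <= 0) bnmf_config_error("budget_bytes must be positive")
  es <- as.numeric(element_size)
  resident <- n * k + k * m + k
  solve_width <- function(dim_len, other_len, given) {
    # footprint(b) = es * (resident + b * (2*other_len + k))
    if (!is.null(given)) {
      b <- as.integer(given)
      if (b < 1L || b > dim_len)
        bnmf_config_error(sprintf("block width %d outside [1, %d]", b, dim_len))
    } else {
      b <- floor((budget_bytes / es - resident) / (2 * other_len + k))
      b <- as.integer(min(dim_len, b))
    }
    feasible_min <- es * (resident + 1 * (2 * other_len + k))
    if (b < 1L || es * (resident + b * (2 * other_len + k)) > budget_bytes)
      bnmf_config_error(sprintf(
        "budget too small: %d bytes given, minimum feasible is %.0f",
        budget_bytes, feasible_min))
    b
  }
  bm <- solve_width(m, n, bm)
  bn <- solve_width(n, m, bn)
  structure(list(
    bm = bm, bn = bn,
    col_blocks = block_ranges(m, bm),
    row_blocks = block_ranges(n, bn),
    budget_bytes = budget_bytes,
    element_size = as.integer(es)
  ), class = "block_plan")
}

# contiguous equal-width ranges with a short tail, inclusive 1-based bounds
block_ranges <- function(total, width) {
  total <- as.integer(total)
  width <- as.integer(width)
  starts <- seq.int(1L, total, by = width)
  lapply(starts, function(s) c(s, min(s + width - 1L, total)))
}

#' Block-readable view of an in-memory matrix
#'
#' Providers of the block-reader contract expose `n`, `m`, `read_cols(a, b)`
#' and `read_rows(a, b)` (inclusive 1-based bounds) plus a `peak_bytes()`
#' accessor reporting the largest single block served, so tests can verify
#' out-of-core runs never materialize more than the planned block.
#'
#' @param V a validated matrix.
#' @return a block source list.
#' @export
block_source_matrix <- function(V) {
  validate_matrix(V, "V")
  peak <- 0
  track <- function(blk) {
    peak <<- max(peak, length(blk) * 8)
    blk
  }
  list(
    n = nrow(V), m = ncol(V),
    read_cols = function(a, b) track(V[, a:b, drop = FALSE]),
    read_rows = function(a, b) track(V[a:b, , drop = FALSE]),
    peak_bytes = function() peak
  )
}

#' Block-readable view of a binary matrix file
#'
#' Serves blocks by seek-and-read over a row-major little-endian binary
#' file (see [read_matrix_bin()]), so V is never fully resident. Row blocks
#' are contiguous on disk; column blocks gather one run per row.
#'
#' @param path path to the binary file.
#' @param n_rows,n_cols dimensions (required for the raw dialect).
#' @param precision element precision on disk.
#' @param header `TRUE` for the headered dialect.
#' @return a block source list (see [block_source_matrix()]).
#' @export
block_source_binary <- function(path, n_rows = NULL, n_cols = NULL,
                                precision = c("double", "single"),
                                header = TRUE) {
  precision <- match.arg(precision)
  es <- element_size(precision)
  if (!file.exists(path)) bnmf_io_error(sprintf("file not found: %s", path))
  offset <- 0
  if (header) {
    con0 <- file(path, "rb")
    dims <- readBin(con0, "integer", n = 2L, size = 4L, endian = "little")
    close(con0)
    n_rows <- dims[1L]; n_cols <- dims[2L]
    offset <- 8
  }
  if (is.null(n_rows) || is.null(n_cols))
    bnmf_config_error("raw binary dialect requires n_rows and n_cols")
  expected <- offset + as.numeric(n_rows) * n_cols * es
  if (file.info(path)$size != expected)
    bnmf_format_error(sprintf("size mismatch: %s is not %d x %d at %d bytes/element",
                              path, n_rows, n_cols, es))
  peak <- 0
  read_chunk <- function(con, count) {
    readBin(con, "double", n = count, size = es, endian = "little")
  }
  guard <- function(vals, what) {
    if (any(!is.finite(vals)) || any(vals < 0))
      bnmf_io_error(sprintf("invalid payload while reading %s", what))
    vals
  }
  list(
    n = n_rows, m = n_cols,
    read_cols = function(a, b) {
      w <- b - a + 1L
      out <- matrix(0, nrow = n_rows, ncol = w)
      con <- file(path, "rb"); on.exit(close(con))
      for (i in seq_len(n_rows)) {
        seek(con, offset + ((i - 1) * n_cols + (a - 1)) * es)
        out[i, ] <- guard(read_chunk(con, w), sprintf("columns %d..%d", a, b))
      }
      peak <<- max(peak, length(out) * 8)
      out
    },
    read_rows = function(a, b) {
      h <- b - a + 1L
      con <- file(path, "rb"); on.exit(close(con))
      seek(con, offset + (a - 1) * n_cols * es)
      vals <- guard(read_chunk(con, h * n_cols), sprintf("rows %d..%d", a, b))
      peak <<- max(peak, length(vals) * 8)
      matrix(vals, nrow = h, ncol = n_cols, byrow = TRUE)
    },
    peak_bytes = function() peak
  )
}

as_block_source <- function(V) {
  if (is.list(V) && is.function(V$read_cols)) V else block_source_matrix(V)
}

#' Blockwise H update
#'
#' Runs the H rule column block by column block: each block's columns of V
#' are read, updated against the full resident W, written into the output,
#' and the block's row sums are reduced and accumulated into a running
#' k-vector so the following W pass finds its denominator ready. With a
#' single block this is bit-identical to [nmf_update_h()].
#'
#' @param src a block source (or a plain matrix).
#' @param W,H current factors (W held fixed for the whole pass).
#' @param plan a [plan_blocks()] plan covering `ncol(H)`.
#' @param epsilon denominator guard.
#' @param col_sums_W cached column sums of W.
#' @return list with the updated `H` and the accumulated `row_sums_H`.
#' @export
nmf_update_h_blockwise <- function(src, W, H, plan,
                                   epsilon = .Machine$double.eps,
                                   col_sums_W = colSums(W)) {
  src <- as_block_source(src)
  H_new <- H
  acc <- numeric(nrow(H))
  for (idx in seq_along(plan$col_blocks)) {
    rg <- plan$col_blocks[[idx]]
    Vb <- tryCatch(src$read_cols(rg[1L], rg[2L]), error = function(e)
      bnmf_io_error(sprintf("failed reading column block %d [%d, %d]: %s",
                            idx, rg[1L], rg[2L], conditionMessage(e))))
    Hb <- h_rule_block(Vb, W, H[, rg[1L]:rg[2L], drop = FALSE], col_sums_W, epsilon)
    H_new[, rg[1L]:rg[2L]] <- Hb
    acc <- acc + rowSums(Hb)
  }
  list(H = H_new, row_sums_H = acc)
}

#' Blockwise W update
#'
#' Row-block counterpart of [nmf_update_h_blockwise()], consuming the
#' `row_sums_H` accumulated by the preceding H pass and accumulating the
#' column sums of the updated W.
#'
#' @inheritParams nmf_update_h_blockwise
#' @param row_sums_H k-vector of row sums of (the already updated) H.
#' @return list with the updated `W` and the accumulated `col_sums_W`.
#' @export
nmf_update_w_blockwise <- function(src, W, H, plan,
                                   epsilon = .Machine$double.eps,
                                   row_sums_H = rowSums(H)) {
  src <- as_block_source(src)
  W_new <- W
  acc <- numeric(ncol(W))
  for (idx in seq_along(plan$row_blocks)) {
    rg <- plan$row_blocks[[idx]]
    Vb <- tryCatch(src$read_rows(rg[1L], rg[2L]), error = function(e)
      bnmf_io_error(sprintf("failed reading row block %d [%d, %d]: %s",
                            idx, rg[1L], rg[2L], conditionMessage(e))))
    Wb <- w_rule_block(Vb, W[rg[1L]:rg[2L], , drop = FALSE], H, row_sums_H, epsilon)
    W_new[rg[1L]:rg[2L], ] <- Wb
    acc <- acc + colSums(Wb)
  }
  list(W = W_new, col_sums_W = acc)
}

#' Out-of-core NMF fit under a memory budget
#'
#' Same iteration and convergence semantics as [nmf_fit()], but every pass
#' over V is blockwise per the plan derived from `cfg$budget_bytes` (or the
#' explicit `bm`/`bn` overrides). `V` may be an in-memory matrix, a block
#' source, or a path to a binary matrix file, in which case V is never
#' fully loaded.
#'
#' @param V matrix, block source, or path to a headered binary file.
#' @param cfg an [nmf_config()] with `budget_bytes` set (unless both `bm`
#'   and `bn` are given).
#' @param bm,bn optional explicit block widths.
#' @return an `"nmf_fit"` object; `$plan` records the block plan used.
#' @export
nmf_fit_blockwise <- function(V, cfg, bm = NULL, bn = NULL) {
  if (!inherits(cfg, "nmf_config")) bnmf_config_error("cfg must be an nmf_config")
  src <- if (is.character(V)) {
    block_source_binary(V, precision = cfg$precision)
  } else {
    as_block_source(V)
  }
  n <- src$n; m <- src$m
  if (cfg$k > min(n, m))
    bnmf_config_error(sprintf("k = %d exceeds min(n, m) = %d", cfg$k, min(n, m)))
  budget <- cfg$budget_bytes
  if (is.null(budget)) {
    if (is.null(bm) || is.null(bn))
      bnmf_config_error("blockwise fit requires budget_bytes or explicit bm and bn")
    budget <- 2^52  # overrides supplied; plan only checks their range
  }
  plan <- plan_blocks(n, m, cfg$k, element_size(cfg$precision), budget,
                      bm = bm, bn = bn)
  pair <- nmf_init(n, m, cfg$k, cfg$seed)
  eps <- cfg$epsilon
  env <- environment()
  step <- function(it) {
    hp <- nmf_update_h_blockwise(src, pair$W, pair$H, plan, eps, pair$col_sums_W)
    pair$H <- hp$H
    pair$row_sums_H <- hp$row_sums_H
    wp <- nmf_update_w_blockwise(src, pair$W, pair$H, plan, eps, pair$row_sums_H)
    pair$W <- wp$W
    pair$col_sums_W <- wp$col_sums_W
    assign("pair", pair, envir = env)
  }
  divergence <- function() {
    # streamed over column blocks so V stays out of core
    tot <- 0
    for (rg in plan$col_blocks) {
      Vb <- src$read_cols(rg[1L], rg[2L])
      tot <- tot + kl_divergence(Vb, pair$W, pair$H[, rg[1L]:rg[2L], drop = FALSE])
    }
    tot
  }
  report <- nmf_run_loop(cfg, step,
                         function() sample_assignment(pair$H),
                         divergence)
  new_nmf_fit(pair, report, extra = list(plan = plan,
                                         peak_block_bytes = src$peak_bytes()))
}
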