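# Initialization, the two multiplicative update rules, and the divergence.

test_that("seeded initialization is deterministic and strictly positive", {
  a <- nmf_init(20, 10, 3, seed = 42)
  b <- nmf_init(20, 10, 3, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$W > 0) && all(a$H > 0))
  expect_equal(a$col_sums_W, colSums(a$W))
  expect_equal(a$row_sums_H, rowSums(a$H))

  c <- nmf_init(20, 10, 3, seed = 2)
  expect_true(any(a$W != c$W))

  expect_error(nmf_init(3, 3, 4), class = "blocknmf_config_error")
  expect_error(nmf_init(0, 3, 1), class = "blocknmf_config_error")
})

test_that("update rules hold their fixed points and closed forms", {
  wi <- worked_instances()
  # V = WH exactly: the ratio matrix is all ones, so nothing moves
  fp <- wi$fixed_point
  expect_equal(nmf_update_h(fp$V, fp$W, fp$H), fp$H, tolerance = 1e-12)
  expect_equal(nmf_update_w(fp$V, fp$W, fp$H), fp$W, tolerance = 1e-12)

  # W = ones(2x1): one H update lands on the column mean of V, for any h > 0
  cm <- wi$column_mean
  for (h in c(0.01, 0.5, 7)) {
    H <- matrix(h, 1, 1)
    expect_equal(nmf_update_h(cm$V, cm$W, H), matrix(3, 1, 1), tolerance = 1e-12)
  }
})

test_that("vectorized updates match the scalar-loop oracle", {
  wi <- worked_instances()
  oc <- wi$oracle_2x2
  expect_equal(nmf_update_h(oc$V, oc$W, oc$H),
               oracle_update_h(oc$V, oc$W, oc$H), tolerance = 1e-12)
  expect_equal(nmf_update_w(oc$V, oc$W, oc$H),
               oracle_update_w(oc$V, oc$W, oc$H), tolerance = 1e-12)

  set.seed(101)
  for (rep in 1:25) {
    n <- sample(1:10, 1); m <- sample(1:10, 1); k <- sample(1:min(4, n, m), 1)
    inst <- random_instance(n, m, k)
    expect_lt(max_rel_diff(nmf_update_h(inst$V, inst$W, inst$H),
                           oracle_update_h(inst$V, inst$W, inst$H)), 1e-10)
    expect_lt(max_rel_diff(nmf_update_w(inst$V, inst$W, inst$H),
                           oracle_update_w(inst$V, inst$W, inst$H)), 1e-10)
  }
})

test_that("the W rule is the H rule on the transposed problem", {
  set.seed(102)
  for (rep in 1:10) {
    inst <- random_instance(sample(2:8, 1), sample(2:8, 1), 2)
    expect_lt(max_rel_diff(nmf_update_w(inst$V, inst$W, inst$H),
                           t(nmf_update_h(t(inst$V), t(inst$H), t(inst$W)))),
              1e-12)
  }
})

test_that("updates preserve non-negativity and reject bad input", {
  set.seed(103)
  for (rep in 1:20) {
    inst <- random_instance(sample(1:8, 1), sample(1:8, 1), sample(1:3, 1))
    expect_true(all(nmf_update_h(inst$V, inst$W, inst$H) >= 0))
    expect_true(all(nmf_update_w(inst$V, inst$W, inst$H) >= 0))
  }
  V <- matrix(1, 2, 2); W <- matrix(1, 2, 1); H <- matrix(1, 1, 2)
  expect_error(nmf_update_h(V, W, matrix(1, 2, 2)),
               class = "blocknmf_dimension_error")
  expect_error(nmf_update_h(-V, W, H), class = "blocknmf_domain_error")
})

test_that("KL divergence matches closed forms and the scalar oracle", {
  wi <- worked_instances()
  fp <- wi$fixed_point
  expect_equal(kl_divergence(fp$V, fp$W, fp$H), 0)

  # V = [[1]], WH = [[e]]  ->  1*log(1/e) - 1 + e = e - 2
  expect_equal(kl_divergence(matrix(1, 1, 1), matrix(1, 1, 1),
                             matrix(exp(1), 1, 1)),
               exp(1) - 2, tolerance = 1e-12)

  set.seed(104)
  inst <- random_instance(3, 3, 2)
  expect_equal(kl_divergence(inst$V, inst$W, inst$H),
               oracle_kl(inst$V, inst$W, inst$H), tolerance = 1e-12)

  # (WH)_ij = 0 where V_ij > 0 is infinitely divergent
  expect_identical(kl_divergence(matrix(1, 1, 1), matrix(0, 1, 1),
                                 matrix(0, 1, 1)), Inf)
  # 0 log 0 = 0: a zero in V where WH > 0 contributes only +(WH)_ij
  expect_equal(kl_divergence(matrix(0, 1, 1), matrix(1, 1, 1),
                             matrix(2, 1, 1)), 2)
})

test_that("divergence is non-increasing across full iterations", {
  set.seed(105)
  for (rep in 1:5) {
    V <- matrix(runif(30 * 12, 0.05, 4), 30, 12)
    cfg <- nmf_config(k = 3, seed = rep, max_iters = 60, stability = 10^6,
                      track_objective = TRUE)
    fit <- nmf_fit(V, cfg)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("a full fit is deterministic and reports its convergence", {
  d <- make_planted(60, 12, 3, seed = 7)
  cfg <- nmf_config(k = 3, seed = 7)
  f1 <- nmf_fit(d$V, cfg)
  f2 <- nmf_fit(d$V, cfg)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_s3_class(f1, "nmf_fit")
  expect_true(f1$converged)
  expect_identical(f1$stop_reason, "stable")
  expect_true(perm_match(f1$final_assignment, d$labels_true))
  expect_identical(colnames(f1$W), paste0("f", 0:2))
  expect_identical(rownames(f1$W), rownames(d$V))
  expect_identical(colnames(f1$H), colnames(d$V))
})

test_that("rank-1 fits are monotone with a stable tail", {
  set.seed(106)
  V <- matrix(runif(12 * 6, 0.5, 2), 12, 6)
  cfg <- nmf_config(k = 1, seed = 1, max_iters = 200, stability = 10^6,
                    track_objective = TRUE)
  fit <- nmf_fit(V, cfg)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  tail10 <- tail(tr, 10)
  expect_lt(max(abs(diff(tail10))) / max(abs(tail10), 1e-300), 1e-10)
  expect_equal(qr(fit$W %*% fit$H)$rank, 1L)
})

test_that("run configuration validates its fields", {
  expect_error(nmf_config(k = 0), class = "blocknmf_config_error")
  expect_error(nmf_config(k = 2, epsilon = 0), class = "blocknmf_config_error")
  expect_error(nmf_config(k = 2, test_period = 0), class = "blocknmf_config_error")
  expect_error(nmf_config(k = 2, budget_bytes = -5), class = "blocknmf_config_error")
  expect_error(nmf_fit(matrix(1, 2, 2), nmf_config(k = 3)),
               class = "blocknmf_config_error")
})
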