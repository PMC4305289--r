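test_that("effective Jacobian is Sigma W - G restricted to the active set", {
  net <- build_wta(2)
  J_all <- effective_jacobian(net, c(1, 1, 1))
  expect_equal(unname(J_all), net$W - diag(net$G))
  # one winner + inhibition with the reference parameters
  J2 <- effective_jacobian(fig_net(), c(0, 1, 0, 0, 1))
  expect_equal(unname(J2), matrix(c(0.1, 0.25, -3, -1.5), 2, 2))
  # empty pattern
  J0 <- effective_jacobian(fig_net(), rep(0, 5))
  expect_equal(dim(J0), c(0L, 0L))
  expect_equal(divergence(J0), 0)
})

test_that("divergence is the trace, independent of rotation strength", {
  for (a in c(0, 0.5, 1, 2, 3))
    expect_equal(divergence(matrix(c(1, -a, a, -2), 2, 2)), -1)
  expect_equal(divergence(diag(3)), 3)  # expanding yet positive divergence
  expect_equal(subspace_divergence(fig_net(), c(1, 1, 0, 0, 1)),
               0.1 + 0.1 - 1.5)
})

test_that("reference network has 16 subspaces: single-winner permitted, rest forbidden", {
  net <- fig_net()
  tab <- enumerate_subspaces(net)
  expect_equal(nrow(tab), 16L)
  expect_identical(tab$klass[tab$n_active_exc == 1], rep("permitted", 4))
  expect_identical(tab$klass[tab$n_active_exc >= 2], rep("forbidden", 11))
  expect_identical(tab$klass[tab$n_active_exc == 0], "off")
  # the off state is enumerated last; divergence descends before it
  expect_equal(tab$index[tab$klass == "off"], 16L)
  expect_true(all(diff(tab$divergence[1:15]) <= 0))
  # single-winner sets occupy ranks 12..15
  expect_identical(sort(tab$index[tab$n_active_exc == 1]), 12:15)
})

test_that("divergence equals the sum of eigenvalue real parts for every subspace", {
  for (i in 1:5) {
    p <- random_valid_params()
    net <- build_wta(sample(2:5, 1), p)
    for (s in all_patterns(enumerate_subspaces(net))) {
      if (s$klass == "off") next
      expect_lt(abs(s$divergence - sum(Re(s$eigvals))), 1e-9)
    }
  }
})

test_that("two-unit instability projection reproduces the canonical V", {
  p <- network_params()
  net <- build_wta(2, p)
  et <- expansion_test(net, c(1, 1, 1))
  expect_equal(unname(et$V),
               matrix(c(p$alpha1, 0, 0, p$alpha1, -p$beta1, -p$beta1), 2, 3))
  expect_true(et$expanding)
  expect_false(expansion_test(net, c(1, 0, 1))$expanding)
})

test_that("expansion verdict coincides with the forbidden class on the reference net", {
  net <- fig_net()
  for (s in all_patterns(enumerate_subspaces(net))) {
    if (sum(s$pattern[1:4]) == 0) next
    expect_identical(expansion_test(net, s$pattern)$expanding,
                     s$klass == "forbidden")
  }
})

test_that("top eigenvectors of forbidden subspaces are mixed; stable or symmetric ones are not", {
  net <- fig_net()
  for (s in all_patterns(enumerate_subspaces(net)))
    if (s$klass == "forbidden")
      expect_true(mixed_eigenvector_check(s$J_eff))
  expect_false(mixed_eigenvector_check(diag(2)))
  expect_false(mixed_eigenvector_check(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_error(mixed_eigenvector_check(-diag(2)), "not positive")
})

test_that("mixed-eigenvector theorem holds over randomized valid parameters", {
  for (i in 1:30) {
    p <- random_valid_params()
    net <- build_wta(sample(2:6, 1), p)
    for (s in all_patterns(enumerate_subspaces(net)))
      if (s$klass == "forbidden")
        expect_true(mixed_eigenvector_check(s$J_eff))
  }
})

test_that("gain and steady state follow the closed forms", {
  p <- network_params()
  expect_equal(wta_gain(p), 1 / 0.55)
  expect_equal(wta_gain(network_params(alpha1 = 1.0001, beta1 = 2, beta2 = 0.5)),
               1 / (1 - 1.0001 + 1), tolerance = 1e-12)
  expect_error(wta_gain(network_params(alpha1 = 1.6, beta1 = 1.2, beta2 = 0.45)),
               "stable")
  expect_equal(steady_state_winner(fig_net(), 1, 6), 15)
})

test_that("contraction metric diagonalizes the generalized Jacobian", {
  J <- effective_jacobian(fig_net(), c(0, 1, 0, 0, 1))
  cm <- contraction_metric(J)
  expect_identical(cm$source, "eigendecomposition")
  F <- cm$Theta %*% J %*% solve(cm$Theta)
  expect_lt(max(Mod(F - diag(cm$eigvals))), 1e-9)
})

# The three invariants below are properties of the continuous flow; they are
# checked at a refined Euler step (dt = 0.002) because at dt = 0.01 grazing
# threshold crossings occasionally log a spurious bounce pair (a crossing
# detected ~1 tau early that reverses), which vanishes under refinement.
fine_protocol <- function(...) input_protocol(onset_step = 10000, ...)

test_that("trajectories never leave permitted subspaces and always escape forbidden ones", {
  net <- fig_net()
  tab <- enumerate_subspaces(net)
  kl <- setNames(tab$klass, tab$key)
  set.seed(5)
  for (r in 1:20) {
    tr <- simulate_network(net, fine_protocol(input_sigma = 1),
                           n_steps = 40000, dt = 0.002,
                           x0 = "uniform", seed = 3000 + r)
    trs <- tr$transitions
    post <- trs[trs$step > 10000, , drop = FALSE]
    if (nrow(post) > 0) {
      # a permitted subspace is never a source of a post-onset transition
      expect_false(any(kl[post$from] == "permitted"))
      # every forbidden subspace visited was left (only the final state remains)
      final_key <- post$to[nrow(post)]
      expect_identical(unname(kl[final_key]), "permitted")
    }
  }
})

test_that("divergence strictly decreases across constant-input transitions", {
  net <- fig_net()
  for (r in 1:20) {
    tr <- simulate_network(net, fine_protocol(input_sigma = 1),
                           n_steps = 40000, dt = 0.002,
                           x0 = "uniform", seed = 4000 + r)
    post <- tr$transitions[tr$transitions$step > 10000, , drop = FALSE]
    if (nrow(post) == 0) next
    d_from <- vapply(post$from, function(k)
      subspace_divergence(net, as.integer(strsplit(k, "")[[1]])), numeric(1))
    d_to <- vapply(post$to, function(k)
      subspace_divergence(net, as.integer(strsplit(k, "")[[1]])), numeric(1))
    expect_true(all(d_to < d_from))
  }
})

test_that("deactivated units stay inactive under constant input", {
  net <- fig_net()
  for (r in 1:10) {
    tr <- simulate_network(net, fine_protocol(input_sigma = 1),
                           n_steps = 40000, dt = 0.002,
                           x0 = "uniform", seed = 5000 + r)
    A <- tr$active[tr$steps > 10500, 1:4, drop = FALSE]  # past onset settling
    for (u in 1:4) {
      col <- A[, u]
      drops <- which(diff(col) != 0)
      # at most one sign change: once off, never on again
      expect_lte(length(drops), 1)
      if (length(drops) == 1) expect_equal(col[length(col)], 0L)
    }
  }
})

test_that("enumeration refuses beyond the pattern cap with guidance", {
  g <- suppressWarnings(build_random_grid(grid_spec(side = 10, seed = 4)))
  expect_error(enumerate_subspaces(g, mode = "full"), "cap")
})
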