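test_that("entropy follows the Shannon formula with the 0 log 0 convention", {
  occ <- data.frame(step = c(rep(0, 4), 1, 2, 2),
                    pattern = c("a", "b", "c", "d", "a", "a", "b"),
                    p = c(rep(0.25, 4), 1, 0.5, 0.5))
  H <- entropy_curve(occ)
  expect_equal(H$H, c(2, 0, 1))
  expect_equal(H$n_patterns, c(4L, 1L, 2L))
})

test_that("occupancy is normalized and entropy bounded on a small ensemble", {
  net <- fig_net()
  ens <- run_ensemble(net, input_protocol(input_sigma = 0.25),
                      n_runs = 40, seed = 2, n_steps = 6000)
  sums <- tapply(ens$occupancy$p, ens$occupancy$step, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ens$entropy$H >= 0))
  expect_true(all(ens$entropy$H <= log2(16) + 1e-12))
  # reproducible under the master seed
  ens2 <- run_ensemble(net, input_protocol(input_sigma = 0.25),
                       n_runs = 40, seed = 2, n_steps = 6000)
  expect_identical(ens$entropy, ens2$entropy)
  expect_identical(ens$transitions, ens2$transitions)
})

test_that("a single-run ensemble carries zero entropy throughout", {
  ens <- run_ensemble(fig_net(), input_protocol(input_sigma = 0.25),
                      n_runs = 1, seed = 3, n_steps = 4000)
  expect_true(all(ens$entropy$H == 0))
})

# Strict no-noise invariants are model properties; checked at dt = 0.002
# where grazing-crossing bounce artifacts of the coarse Euler step vanish
# (see the corresponding note in test-subspace.R).
test_that("without noise no transition ever climbs the divergence gradient", {
  ens <- run_ensemble(fig_net(),
                      input_protocol(onset_step = 10000, input_sigma = 1),
                      n_runs = 60, seed = 4, n_steps = 30000, dt = 0.002)
  expect_equal(against_gradient_fraction(ens, window = "all"), 0)
  expect_equal(ens$against_gradient_fraction, 0)
})

test_that("the against-gradient fraction errors when no transitions exist", {
  expect_error(against_gradient_fraction(
    data.frame(div_from = numeric(0), div_to = numeric(0),
               in_computation = logical(0))), "undefined")
})

test_that("the no-noise transition graph is a divergence-ordered DAG", {
  ens <- run_ensemble(fig_net(),
                      input_protocol(onset_step = 10000, input_sigma = 1),
                      n_runs = 80, seed = 6, n_steps = 30000, dt = 0.002)
  g <- ens$graph
  expect_true(all(g$edges$gradient_sign == "decreasing"))
  # out-edge probabilities are conditional distributions
  out_sum <- tapply(g$edges$probability, g$edges$from, sum)
  expect_true(all(abs(out_sum - 1) < 1e-12))
  # permitted nodes are absorbing: never a source
  perm <- g$nodes$pattern[g$nodes$klass %in% c("permitted", "off")]
  expect_false(any(g$edges$from %in% perm))
  # divergence ordering implies acyclicity: follow any path, divergence drops
  div_of <- setNames(g$nodes$divergence, g$nodes$pattern)
  expect_true(all(div_of[g$edges$to] < div_of[g$edges$from]))
})

test_that("graph export to igraph keeps node and edge attributes", {
  ens <- run_ensemble(fig_net(), input_protocol(input_sigma = 1),
                      n_runs = 30, seed = 8, n_steps = 6000)
  ig <- as_igraph(ens$graph)
  expect_equal(igraph::gorder(ig), nrow(ens$graph$nodes))
  expect_equal(igraph::gsize(ig), nrow(ens$graph$edges))
  expect_true("divergence" %in% igraph::vertex_attr_names(ig))
  expect_true("gradient_sign" %in% igraph::edge_attr_names(ig))
})

test_that("steering connections skew the winner distribution; the plain net is uniform", {
  net <- fig_net()
  steered <- add_connection(add_connection(net, 1, 2, 0.2), 4, 2, 0.2)
  pr <- input_protocol(input_sigma = 0.25)
  ens_u <- run_ensemble(net, pr, n_runs = 400, seed = 11, n_steps = 10000)
  ens_s <- run_ensemble(steered, pr, n_runs = 400, seed = 11, n_steps = 10000)
  winners <- function(ens) {
    occ <- ens$occupancy
    o <- occ[occ$step == max(occ$step) &
               occ$pattern %in% c("1000", "0100", "0010", "0001"), ]
    counts <- setNames(rep(0, 4), c("1000", "0100", "0010", "0001"))
    counts[o$pattern] <- o$p * ens$n_runs
    counts
  }
  # plain network: all four permitted outcomes equally likely (chi-square)
  p_u <- stats::chisq.test(winners(ens_u))$p.value
  expect_gt(p_u, 0.01)
  # steered network: strongly non-uniform, unit 2 favoured
  w_s <- winners(ens_s)
  expect_lt(stats::chisq.test(w_s)$p.value, 0.01)
  expect_equal(names(which.max(w_s)), "0100")
  # steering lowers both peak and asymptotic entropy
  expect_lt(max(ens_s$entropy$H), max(ens_u$entropy$H))
  expect_lt(ens_s$entropy$H[nrow(ens_s$entropy)],
            ens_u$entropy$H[nrow(ens_u$entropy)])
})

test_that("entropy peaks after divergence magnitude and max eigenvalue peak", {
  net <- fig_net()
  tab <- enumerate_subspaces(net)
  div_of <- setNames(tab$divergence, tab$exc_key)
  eig_of <- setNames(tab$max_re, tab$exc_key)
  ens <- run_ensemble(net, input_protocol(input_sigma = 0.25),
                      n_runs = 200, seed = 13, n_steps = 10000)
  occ <- ens$occupancy[ens$occupancy$step >= 2000, ]
  occ <- occ[occ$pattern != "0000", ]  # off state carries no Jacobian
  mean_div <- tapply(occ$p * div_of[occ$pattern], occ$step, sum)
  mean_eig <- tapply(occ$p * eig_of[occ$pattern], occ$step, sum)
  H <- ens$entropy[ens$entropy$step >= 2000, ]
  t_H <- H$step[which.max(H$H)]
  t_div <- as.integer(names(which.max(mean_div)))
  t_eig <- as.integer(names(which.max(mean_eig)))
  expect_gt(t_H, t_div)
  expect_gt(t_H, t_eig)
})

test_that("a tiny grid converges to a permitted subspace almost immediately", {
  res <- time_to_permitted_vs_size(2, runs_per_side = 10, seed = 21,
                                   budget_steps = 3000)
  expect_equal(res$n_censored, 0)
  expect_lt(res$mean_time, 500)
})
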