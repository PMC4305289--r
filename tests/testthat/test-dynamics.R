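test_that("quiescence is a fixed point and single steps match hand computation", {
  net <- build_wta(2)
  x0 <- numeric(3)
  expect_identical(step_state(net, x0, numeric(3)), x0)
  # one Euler step from rest with drive (1,0,0): only unit 1 moves, by dt/tau
  x1 <- step_state(net, x0, c(1, 0, 0), dt = 0.01)
  expect_equal(x1, c(0.01 / net$tau * 1, 0, 0))
})

test_that("closed-form winner state is a fixed point of the integrator", {
  net <- fig_net()
  I <- 6
  xw <- steady_state_winner(net, 2, I)     # 6 / 0.4 = 15
  expect_equal(xw, 15)
  x_inh <- net$W[5, 2] * xw / net$G[5]     # inhibitory balance
  x <- c(0, xw, 0, 0, x_inh)
  drive <- c(0, I, 0, 0, 0)
  expect_lt(max(abs(step_state(net, x, drive, dt = 0.01) - x)), 0.01 * 1e-12)
})

test_that("simulation selects and amplifies the maximal input", {
  net <- fig_net()
  tr <- simulate_network(net, input_protocol(input_sigma = 1),
                         n_steps = 10000, seed = 101)
  inputs <- tr$base_input[1:4]
  winner <- which.max(inputs)
  final_pat <- tr$active[nrow(tr$active), ]
  expect_identical(which(final_pat[1:4] == 1L), winner)
  expect_equal(final_pat[5], 1L)  # inhibitory unit co-active
  # amplification: activation exceeds the input itself
  expect_gt(tr$x_final[winner], inputs[winner])
  # and matches the leak-generalized closed form
  expect_lt(abs(tr$x_final[winner] / steady_state_winner(net, winner, inputs[winner]) - 1),
            1e-6)
})

test_that("runs are bit-identical under the same seed", {
  net <- fig_net()
  pr <- input_protocol(input_sigma = 1, noise_sigma = 1)
  a <- simulate_network(net, pr, n_steps = 4000, x0 = "uniform", seed = 7)
  b <- simulate_network(net, pr, n_steps = 4000, x0 = "uniform", seed = 7)
  expect_identical(a$X, b$X)
  expect_identical(a$transitions, b$transitions)
})

test_that("states stay non-negative under noisy protocols", {
  for (s in 1:5) {
    p <- random_valid_params()
    net <- build_wta(3, p)
    tr <- simulate_network(net, input_protocol(input_sigma = 1, noise_sigma = 2),
                           n_steps = 5000, x0 = "uniform", seed = s)
    expect_true(all(tr$X >= 0))
  }
})

test_that("winner activation is linear in its input above threshold", {
  net <- fig_net()
  base <- c(0, 0, 6, 0, 0)
  tr1 <- simulate_network(net, input_protocol(base_input = base),
                          n_steps = 8000, seed = 1)
  tr2 <- simulate_network(net, input_protocol(base_input = 1.7 * base),
                          n_steps = 8000, seed = 1)
  expect_lt(abs(tr2$x_final[3] / tr1$x_final[3] - 1.7), 1e-6)
})

test_that("halving the step size barely moves the converged state", {
  net <- fig_net()
  base <- c(5.2, 6.8, 5.9, 6.3, 0)
  a <- simulate_network(net, input_protocol(base_input = base),
                        n_steps = 8000, dt = 0.01, seed = 1)
  b <- simulate_network(net, input_protocol(base_input = base),
                        n_steps = 16000, dt = 0.005, seed = 1)
  act <- a$x_final > 1e-8
  expect_lt(max(abs(a$x_final[act] - b$x_final[act]) / a$x_final[act]), 1e-4)
})

test_that("activation patterns follow the rectifier argument", {
  net <- fig_net()
  x0 <- numeric(5)
  expect_identical(active_pattern(net, x0, c(1, 0, 0, 0, 0)),
                   c(1L, 0L, 0L, 0L, 0L))
  expect_identical(active_pattern(net, x0, numeric(5)), rep(0L, 5))
  # state-based alternative rule
  expect_identical(active_pattern(net, c(2, 0, 0, 0, 0), numeric(5),
                                  use_state = TRUE),
                   c(1L, 0L, 0L, 0L, 0L))
})

test_that("the transition log agrees with the recorded pattern trace", {
  net <- fig_net()
  tr <- simulate_network(net, input_protocol(input_sigma = 1, noise_sigma = 1),
                         n_steps = 5000, seed = 9, record_stride = 1)
  keys <- apply(tr$active, 1, paste, collapse = "")
  changed <- which(keys[-1] != keys[-length(keys)])  # row i+1 = step i
  expect_identical(tr$transitions$step, as.integer(tr$steps[changed + 1]))
  expect_identical(tr$transitions$from, unname(keys[changed]))
  expect_identical(tr$transitions$to, unname(keys[changed + 1]))
})

test_that("a state-conditional input rule can push the network up the gradient", {
  net <- fig_net()
  # while in the forbidden subspace with units 1-3 active, boost unit 4
  rule <- list(trigger = c(1, 1, 1, 0, 1), target = 4, increment = 20)
  hits <- 0
  for (s in 1:20) {
    tr <- simulate_network(net,
                           input_protocol(input_sigma = 0.25,
                                          conditional_rules = list(rule)),
                           n_steps = 6000, x0 = "uniform", seed = 200 + s)
    trs <- tr$transitions
    if (!any(trs$step > 2000 & trs$to == "11101")) next
    hits <- hits + 1
    divs <- vapply(seq_len(nrow(trs)), function(i) {
      subspace_divergence(net, as.integer(strsplit(trs$to[i], "")[[1]])) -
        subspace_divergence(net, as.integer(strsplit(trs$from[i], "")[[1]]))
    }, numeric(1))
    expect_true(any(divs[trs$step > 2000] > 0))
  }
  expect_gt(hits, 0)  # the trigger pattern was actually visited
})
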