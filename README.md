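# wtadyn

Dynamics of asymmetric soft winner-take-all (sWTA) networks of linear
threshold neurons, for computational neuroscientists studying how recurrent
circuits compute through *instability*: transient expansion steered by
asymmetric excitation–inhibition loops and quenched by negative Gaussian
divergence.

The model is

```
tau * dx/dt = f(W x + I(t)) - G x,     f(u) = max(u, 0)
```

with `W[i, j]` the weight of connection `j -> i`. The canonical motif has
excitatory units with self-excitation `alpha1` competing through one shared
inhibitory unit (loop weights `beta2` up, `-beta1` back). Only units whose
rectifier argument is positive shape the dynamics; each such *active set*
defines an effective Jacobian `Sigma W - G` whose spectrum classifies the
activation subspace:

* **permitted** — all eigenvalue real parts negative (contracting): a
  candidate solution the dynamics never leave under constant input;
* **forbidden** — maximal eigenvalue positive but trace (the Gaussian
  divergence) negative: transiently expanding, escaped exponentially fast
  through a mixed top eigenvector.

Under constant input every transition strictly decreases the divergence, so
the forbidden subspaces form a hierarchy the computation descends until it
contracts onto a winner, whose activation is the input amplified by the gain
`g = 1 / (1 - alpha1 + beta1*beta2)`. The package provides the builders,
a compiled Euler integrator with noisy and state-conditional input
protocols, subspace enumeration and classification, the gradient/rotation
(Helmholtz-style) split of the subspace dynamics, ensemble state-entropy
curves `H(t) = -sum p_i log2 p_i`, transition graphs, steering experiments,
random grid assemblies, and a command-line interface
(`inst/scripts/wtadyn`).

## Worked example

```r
library(wtadyn)

net <- build_wta(4)                      # 4 competitors + shared inhibition
validate_params(network_params())        # character(0): bounds satisfied

tr <- simulate_network(net, input_protocol(input_sigma = 1),
                       n_steps = 10000, seed = 7)
tr$base_input
#> [1] 8.287 4.803 5.306 5.588 0.000
tail(tr$transitions, 3)
#>   step  from    to
#> 3 2167 11111 10111
#> 4 2213 10111 10011
#> 5 2288 10011 10001
tr$x_final
#> [1] 20.718  0.000  0.000  0.000  3.453
```

The unit with the largest input (8.287) wins and is amplified to
`8.287 / 0.4 = 20.718`, matching `steady_state_winner(net, 1, 8.287)`; the
transition log descends the divergence hierarchy (`11111` is the all-on
set, `10001` the winner plus inhibition).

```r
enumerate_subspaces(net)[c(1, 6, 12, 16), c("index", "exc_key", "divergence", "klass")]
#>    index exc_key divergence     klass
#> 1      1    1111       -1.1 forbidden
#> 6      6    1100       -1.3 forbidden
#> 12    12    1000       -1.4 permitted
#> 16    16    0000        0.0       off

ens <- run_ensemble(net, input_protocol(input_sigma = 0.25),
                    n_runs = 1000, seed = 1, n_steps = 10000)
range(ens$entropy$H)
#> [1] 0.000000 3.836661
tail(ens$entropy$H, 1)
#> [1] 2.024585
```

Ensemble entropy starts at exactly 0 (every run enters the all-on set at
input onset), peaks while runs spread over the forbidden hierarchy, and
settles at ~2 bits — four equiprobable winners. With input noise
(`noise_sigma = 1`) a minority of transitions runs *against* the divergence
gradient; `against_gradient_fraction(ens)` measures that share over each
run's computation (onset to first permitted subspace).

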