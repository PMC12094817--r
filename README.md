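# maskflow

Joint discrete generative flows over paired protein token tracks — sequence
and structure co-design by iterative unmasking.

## The problem

Protein co-design asks for an amino-acid sequence and a compatible backbone
structure *jointly*, rather than one conditioned on the other in a fixed
order. Once backbone geometry is discretised into tokens (as vector-quantised
structure codes), a protein becomes two aligned discrete tracks
`x = (s, r)`, and co-design becomes a generative-modelling problem over
paired categorical sequences.

maskflow implements the masked discrete flow-matching approach to this
problem, for researchers studying discrete generative samplers and
sequence-structure coupling:

- a per-position **linear-interpolation conditional flow** from an absorbing
  mask state to data, `p(x_t | x_1) = t f(x_1) + (1 − t) f(M)`;
- the **posterior transition kernel** of the associated continuous-time
  Markov chain: a masked position unmasks with probability
  `min(1, Δt (1 + η t) / (1 − t))` spread over the denoiser's predicted
  distribution; with balanced noise `η > 0`, observed tokens may transiently
  re-mask with probability `η Δt` (never at the final step);
- a **time-conditioned bidirectional transformer denoiser** `f_θ(x_t, t)`
  predicting per-residue categorical distributions for both tracks (zero
  mask mass), trained by cross-entropy on masked positions at a random
  `t ~ U(0, 1)`;
- **conditioning by masking**: unconditional generation, folding, inverse
  folding and motif scaffolding differ only in which tokens start observed
  and frozen;
- **track-scheduling strategies** (synchronous, asynchronous,
  sequence-first, structure-first) and evaluation metrics: generation
  entropy, unmasking accuracy across `t`, native sequence recovery (NSR),
  total-variation distribution recovery, and token-space self-consistency;
- an exactly **enumerable toy protein world** (hidden-state chain emitting
  coupled sequence/structure tokens) whose closed-form oracles — exact
  joint, exact posteriors, Bayes recovery ceiling, max-product co-folding —
  make every distributional claim testable.

## Worked example

Sample from the exact-posterior denoiser on the enumerable world and check
distribution recovery:

```r
library(maskflow)

world <- small_toy_world()              # 2 hidden states, 3 + 3 tokens
joint <- enumerate_joint(world, 3)      # exact P(s, r) over 729 outcomes
print(joint)
#> <mf_joint> N = 3 | 729 outcomes | total mass 1
cat("mutual information (nats):", joint_mutual_information(joint), "\n")
#> mutual information (nats): 0.7414327

denoiser <- make_posterior_denoiser(joint)
x0 <- protein_tokens(masked_track(3, world$seq_vocab, "sequence"),
                     masked_track(3, world$struct_vocab, "structure"))
out <- euler_sample(denoiser, x0, config = sampler_config(steps = 100, seed = 7))
print(out$x1)
#> <mf_protein> N = 3
#>   seq   : CCD
#>   struct: g2 g2 g2
cat("generation entropy:", round(out$gen_entropy, 4), "nats/residue\n")
#> generation entropy: 1.1085 nats/residue

batch <- euler_sample_batch(denoiser, 5000, x0,
                            config = sampler_config(steps = 100, seed = 8))
counts <- tabulate(outcome_index(joint, batch$seq, batch$struct),
                   nbins = length(joint$p))
cat("TV(sampled, exact):", round(tv_distance(counts, joint), 4), "\n")
#> TV(sampled, exact): 0.0635
```

The mutual information above 0 confirms the world couples its two tracks
(co-design is a real task); the entropy is the summed Shannon entropy of the
distributions each token was sampled from, per residue; and the
total-variation distance of 0.064 at 5,000 draws sits at the closed-form
multinomial sampling floor (≈ 0.065 for this joint), i.e. the sampler is
exact to within Monte-Carlo error.

Training and conditional design run the same way at toy scale:

```r
ds <- sample_toy_proteins(toy_world_params(), 5000, 16, seed = 1)
fit <- train_denoiser(ds, denoiser_config(), train_config(epochs = 20))
den <- make_model_denoiser(fit$model)
cm <- make_condition_mask(task_spec("inverse_folding",
                                    given_struct = ds[[1]]$struct), 16)
design <- euler_sample(den, cm$x0, cm$cond,
                       config = sampler_config(steps = 100, temperature = 0.1))
recovery_rate(design$x1$seq, ds[[1]]$seq)
```

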