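---
title: "Activation/recognition grammars: model, execution semantics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation/recognition grammars: model, execution semantics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argram)
```

## The model

An activation/recognition grammar is a probabilistic context-free grammar
without null symbol whose terminals are bound to environment channels:
*actuators* emit output (the grammatical image of an axon firing), *sensors*
match and consume input (the image of a dendrite receiving). The same
rewriting system can therefore run in production, in recognition, or in both
simultaneously; `Mix = DrawSquare SpotCircle DrawTriangle.` recognizes a
circle while producing a square and a triangle. Nonterminals play a purely
structural role and map one-to-one onto somata in the associated neural
circuit; alternates carry probabilities that map onto synaptic weights, with
weights above .5 read as excitatory and below .5 as inhibitory (metadata
only — the package attaches the flag but gives it no further semantics,
since none is defined).

Rules are written in a minimal Wirth-style notation augmented with weights:

```
A = .3 B | .7 C.   B = DrawSquare.   C = DrawCircle.
```

Weights may be written `.3`, `0.3`, or as arbitrary non-negative numbers;
they are normalized per rule at parse time, and a rule written without
weights is read as equipartition. Sequencing inside a rule does not convey
temporal order; the number of rule applications does (`event_order()`
exposes this partial order, with recognition ahead of production at equal
depth).

## Terminal direction is a binding, not a spelling

The formalism assigns sensor/actuator roles per example, never
syntactically: the digits `0` and `1` are read off the Turing tape in one
example and produced by the digit grammar in another. The package therefore
takes direction from an explicit registry (`arg_registry()`), with defaults
covering every shipped example (`Draw*`, `Print*`, `Look`, `Describe`, and
the tape operations `Pe P0 P1 Px R L E` as actuators; `Spot*`, `See`,
`Read*`, `0 1 x e None` and the class sensors `Symbol`/`Weight` as
sensors). Running the digit grammar in production is done by parsing it
under an override, `arg_registry(c("0" = "actuator", "1" = "actuator"))`,
not by guessing from names. A token that heads a rule is always a
nonterminal, whatever the registry says, which is why example grammars can
reuse `R` or `E` as nonterminal names without ambiguity.

## Execution semantics

`run_grammar()` expands depth-first, left-to-right, from the head of the
first rule. Alternate selection is *sensor-gated*: when at least one
alternate begins with a reachable sensor (looking through one level of
nonterminal indirection, so `Any = 0 | 1.` gates as the set `{0, 1}`), the
alternates whose leading sensor matches the environment are kept, alternates
that are not sensor-led stay viable, and one survivor is sampled by
renormalized weights. Rules with no sensor-led alternate are sampled by
their weights directly. This is how stochastic choice coexists with
deterministic control: the Turing transliteration is fully sensor-gated and
therefore reproduces the same tape regardless of seed, while the `.3`/`.7`
color and shape grammars sample freely.

Three outcomes are deliberately *not* errors but statuses on the returned
derivation: `"complete"` (no rules apply), `"exhausted"` (the
rule-application budget ran out — `A = DrawSquare A.` legally never
terminates, so the budget, default 10,000, is the only stop), and
`"failed"` (a sensor mismatch with no viable alternate, the
recognition-failure case, kept distinct from exhaustion). A derivation
carries its trace (terminal, direction, depth = rule applications from the
start symbol inclusive, and emission index) and its log-likelihood, the sum
of log weights of the chosen alternates.

The derivation engine uses an explicit stack rather than recursion so that
tail-recursive grammars (the Turing machine runs thousands of rule
applications deep) cost constant stack. `compile_grammar()` optionally
precomputes the classification and gating tables for repeated runs; results
are identical with or without it.

## Recognition

`recognize()` is a bounded backtracking search, not a chart parser: it is
sufficient for every grammar in the example set, and pathological ambiguity
is bounded by an explicit search budget (`NA` acceptance flags an
indeterminate result). Two numerical choices matter:

* **Likelihood is summed over accepting derivations** found within the
  budget, not the single best derivation; under ambiguity beyond the budget
  the reported value is a lower bound. The digit grammar's acceptance
  probabilities are checked exactly against exhaustive enumeration in the
  tests.
* **Pruning.** Because grammars have no null symbol, every sensor in the
  agenda must consume at least one input token; the recognizer precomputes
  a per-symbol lower bound on sensor yield (min-over-alternates relaxation)
  and abandons branches that provably cannot fit the remaining input. The
  bound is an underestimate, so pruning never loses a valid derivation.

## The Turing-tape environment

The tape is a sparse map over an unbounded bidirectional index with a
read/write head; `Pe/P0/P1/Px` overwrite the scanned cell, `R/L` move, `E`
blanks, and the sensors match the scanned cell (`None` = blank). Reading is
non-destructive. Figure/marker bookkeeping is not hard-coded: figures are
recovered by symbol class (`0`/`1` cells in position order), which is
agnostic to the alternating-square layout. `run_turing()` stops once the
requested number of figures exists on the tape, or returns a flagged
partial tape when the budget runs out first. The tests replay the full tape
history, operation by operation, against an independent table-driven
machine of the same five m-configurations.

## Self-description

`describe_grammar()` encodes a grammar as a grammar: the top rule sequences
one branch per described rule, each branch emitting the quoted head
(`QuoteA`) followed, per alternate, by a quoted weight literal
(`QuotePoint61` for .61) and the quoted symbols. Two conventions follow the
worked examples exactly: a single alternate of weight 1 is weight-silent in
its description, and fresh nonterminals are allocated deterministically
(`A`, `B`, `C`, ... in branch-then-alternate order), which makes the
generated description of the probabilistic orange grammar identical, letter
for letter, to the hand-written one. Weight literals default to two decimal
digits; a weight outside that precision (a three-way equipartition, for
instance) is an error rather than a silent rounding, so describe/decode
stays an exact bijection on its domain.

`linearize_grammar()` always includes a weight token per alternate even
where the describing-grammar scheme omits it: the root grammar's alternate
structure (`Alternate = Weight Symbols`) requires one when recognizing
linearizations. Weight tokens always contain a decimal point (`1.0`,
`.61`), keeping the `Symbol` and `Weight` sensor classes disjoint — without
that, two consecutive weight tokens could masquerade as a weight followed
by a symbol.

The root grammar (`root_grammar()`) is the eight-rule fixed point that
recognizes the linearization of any grammar, including its own; the
acceptance suite checks it against every shipped fixture and against
itself. `root_grammar(readable = TRUE)` applies the standard readable
recasting (`Rules`, `Rule`, `Alternates`, ...).

**Metaphor.** `retarget()` rewrites the description so each mapped actuator
becomes `UnquoteOld New`. Execution of a description
(`run_description()`) is implemented as event interception: the described
derivation is replayed and intercepted actuator events are substituted —
observably equivalent to forwarding the drawing operation to the describing
grammar, and it preserves the derivation's shape exactly (same alternates
chosen under a shared seed, only the emitted names differ).

**Composition.** `compose_grammars(host, hook, guest)` replaces the hook's
description with `UnquoteHook G` where `G` heads an embedded description of
the guest; at execution every hook event splices a full guest production.
Host and guest serialize unchanged afterwards — the combination lives only
in the description. The tests verify that dynamic composition of the digit
and orange grammars is distributionally indistinguishable (chi-squared,
alpha = .01, 10,000 runs per arm) from the static substitution grammar that
merges them textually. The shipped printed composition fixture
(`fig15_compose`) predates the canonical description scheme and is kept
verbatim as a parse/validate fixture; `compose_grammars()` emits the
canonical scheme, and behavior, not spelling, is the contract.

## Swarm learning

A swarm (`swarm_spec()` / `expand_swarm()`) is one template color grammar
instantiated at a grid of probability vectors under an equiprobable top
rule. "Closest branch" is formalized as maximum average per-token
log-likelihood — equivalently minimum cross-entropy — because that is the
measure under which the stated selection (the `.6/.4` branch is closest to
a `.61/.39` orange) is true, and it is grammar-native: it is exactly the
per-token likelihood the branch assigns when recognizing the sample. Ties
break to the lowest branch index. `estimate_weights()` is the closed-form
multinomial MLE (relative frequencies), which is what lets a swarm
concentrate on a target color; no convergence criterion is built in beyond
caller-controlled iteration, since none is specified by the formalism.

`reinforcement_step()` needs a notion of *trigger*: the closure's
recognition branch fires when the sample's selected branch is the
closure's own. Selection requires competitors, so the default context
flanks the closure's vector with `.5/.5` and `.9/.1` (the three-branch
color grid); pass `swarm =` to supply a different context. The number of
producer executions defaults to one per sample token — the source material
only says the expected color is "presented in return", so the sample size
is the natural scale. Samples themselves are generated by the engine
(`sample_color_tokens()` cuts the looping mixture grammar at n emissions),
not by a separate random-number path, so "presenting a color" and
"recognizing a color" exercise the same machinery.

## Circuit rendering

`circuit_graph()` maps nonterminals to somata (a bijection), distinct
terminals to sensor/actuator ports, and each symbol occurrence to a synapse
edge carrying its alternate's weight. A rule recursing on its own head
yields an autapse; a reference to an earlier-defined head that closes a
cycle yields a regular recurrent synapse (the two-rule loop's `B -> A` edge
is recurrent but not an autapse, and `circuit_stats()` counts the two
classes separately). Quoted terminals become dashed projection edges — the
describing circuit projecting onto the described one. Statistics are
invariant under nonterminal renaming.

DOT output encodes the visual conventions as attributes (inverted triangle
for a soma, box/circle for ports); pixel-level reproduction of any
particular drawing is a non-goal — structural isomorphism is the testable
contract, and the tests reparse the emitted DOT and compare node and edge
multisets. The grammatical schema rendering truncates recursion at a
configurable depth (default 2) because the schema of a recursive grammar is
infinite; the circuit graph has no such limitation and is never truncated.

## Problem sizes and tolerances

The stochastic checks run at the scales the claims are stated at: 10,000
productions for the 30%/70% shape mixture and for the `.61` weight
recovery (three binomial standard errors, ±1.4 and ±1.5 points
respectively), 1,000 tokens for swarm selection, 10,000 runs per arm for
the composition chi-squared, and 500+ verified steps of Turing tape
history. Weight normalization and round-trips are held to 1e-9. Branch
selection reliability is checked over repeated draws at n = 1,000.

## What the generated data does and does not show

Color samples are exchangeable token streams from a fixed two-point
mixture; they emulate the stated stimulus exactly but have none of the
structure of real sensory input (no spatial arrangement, no temporal
correlation, no noise in the token identities themselves). Passing tests
therefore demonstrate the formal properties of the machinery — gating,
likelihood selection, MLE recovery, self-description round-trips — not
robustness to realistic perceptual noise.

## Known limitations

* Recognition is budget-bounded backtracking; heavily ambiguous grammars
  outside the example family may return an indeterminate (`NA`) acceptance
  or a lower-bound likelihood.
* Quoted weight literals are decimal at fixed precision; weights such as
  1/3 cannot be described (by design, an error rather than a rounding).
* Descriptions nest one level per `describe_grammar()` call; towers are
  built by repeated calls.
* No inside-outside/EM training, no general chart parsing, and no neuron
  biophysics — circuits are structural.
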