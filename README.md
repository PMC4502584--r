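# argram

Probabilistic **activation/recognition grammars** with self-description,
swarm learning, and neural-circuit compilation.

## The problem

Pattern-based theories of mind model the brain as a hierarchy of pattern
processors. `argram` implements a formalism in which a *single* kind of
object — a stochastic context-free grammar without null symbol — covers
both directions of that processing: terminals are **actuators** (emit
output, like an axon) or **sensors** (match and consume input, like a
dendrite), so one grammar can produce a pattern, recognize it, or do both
at once. Because such grammars are fully recursive they can also *describe
other grammars* (and themselves), which turns checking, learning, metaphor,
and composition into ordinary grammar operations instead of extra
machinery. Each grammar maps one-to-one onto a neural circuit: nonterminals
are somata, alternates are weighted synapses, direct self-recursion is an
autapse.

The package is for computational-neuroscience and grammar-formalism work:
it parses the weighted Wirth notation, executes grammars in production,
recognition, and mixed mode against pluggable environments (token streams,
a Turing tape), supports quote/unquote self-description up to the
self-recognizing root grammar, learns mixture weights with grammar swarms,
and compiles any grammar to its circuit graph with DOT export.

## The core objects

A grammar is a list of rules `Head = w1 alt1 | w2 alt2 | ... .`; weights
normalize per rule and an unweighted rule is read as equipartition, so

```
A = .3 B | .7 C.   B = DrawSquare.   C = DrawCircle.
```

draws a square with probability .3 and a circle with probability .7.
Execution is depth-first and *sensor-gated*: when alternates begin with
reachable sensors, the environment's next input selects among them, which
is how one stochastic engine also runs a deterministic Turing machine.
Derivations carry a trace (terminal, direction, rule-application depth) and
a log-likelihood (sum of log weights of chosen alternates); temporal order
is conveyed by derivation depth, not by rule sequencing, with recognition
ahead of production at equal depth.

A describing grammar encodes another grammar's rules as quoted tokens
(`QuoteA`, `QuotePoint61`); `Unquote` intercepts a described event and
redirects it — the mechanism behind metaphor (`retarget()`: count circles
instead of squares) and dynamic composition (`compose_grammars()`: splice
an orange-color production at every digit-1 event while both component
grammars stay intact).

## Worked example

```r
library(argram)

g <- parse_grammar("A = .3 B | .7 C. B = DrawSquare. C = DrawCircle.")
run_grammar(g, seed = 7)
#> <derivation> 1 event(s), 2 rule application(s), status complete, loglik -1.2040
#>     terminal direction depth seq
#> 1 DrawSquare  actuator     2   1
```

The trace says: this seeded run chose the .3 branch (log .3 = −1.204) and
emitted one square, two rule applications deep.

```r
# the Turing transliteration prints the seminal figure sequence
turing <- parse_grammar(arg_fixtures()$fig6_turing)
read_figures(run_turing(turing, figure_target = 15), 15)
#> [1] "001011011101111"

# the root grammar recognizes its own linearization
root <- root_grammar()
recognizes_description(root, root)
#> [1] TRUE

# a three-branch color swarm selects the branch closest to orange (.61 green)
template <- parse_grammar("T = .5 U | .5 V. U = SpotGreenPoint. V = SpotRedPoint.")
swarm <- swarm_spec(template, list(c(.5, .5), c(.6, .4), c(.9, .1)))
sample <- sample_color_tokens(1000, p_green = 0.61, seed = 8)
sel <- select_branch(swarm, sample)
attr(sel, "loglik")
#>      .5/.5      .6/.4      .9/.1
#> -0.6931472 -0.6689570 -0.9622781
```

The `.6/.4` branch scores the highest average log-likelihood, so the swarm
identifies the orange mixture. Finally, the circuit view of the simplest
recursive grammar:

```r
circuit_stats(circuit_graph(parse_grammar("A = DrawSquare A.")))
#>         somata       synapses       autapses      recurrent   sensor_ports actuator_ports
#>              1              2              1              0              0              1
```

one soma whose recursion is an autapse, plus one actuator port.

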