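fx <- arg_fixtures()

test_that("the simple and probabilistic descriptions match the worked examples", {
  d9 <- describe_grammar(parse_grammar(fx$fig9_simple))
  expect_true(grammar_equal(d9, parse_grammar(fx$fig9_desc)))
  # the single weight-1 alternate is weight-silent in the description
  expect_false(any(grepl("QuotePoint", grammar_terminals(d9))))

  d10 <- describe_grammar(parse_grammar(fx$fig10_orange))
  expect_true(grammar_equal(d10, parse_grammar(fx$fig10_desc)))
  expect_true(all(c("QuotePoint61", "QuotePoint39") %in% grammar_terminals(d10)))
})

test_that("describe/decode is a bijection on quote-free grammars", {
  quote_free <- Filter(function(txt) !grepl("Quote", txt), fx)
  for (nm in names(quote_free)) {
    g <- parse_grammar(quote_free[[nm]])
    if (!representable(g)) {
      # three-way equipartition has no exact decimal weight literal; the
      # description must refuse rather than silently round
      expect_error(describe_grammar(g), "not representable",
                   label = paste("describe refusal for", nm))
      next
    }
    expect_true(grammar_equal(decode_description(describe_grammar(g)), g),
                label = paste("describe/decode round-trip of", nm))
  }
  set.seed(202)
  for (i in 1:200) {
    g <- random_grammar()
    expect_true(grammar_equal(decode_description(describe_grammar(g)), g),
                label = paste("random describe/decode round-trip", i))
  }
})

test_that("describing an already-described grammar requires a fresh call level", {
  d <- parse_grammar(fx$fig9_desc)
  expect_error(describe_grammar(d), "one level at a time")
  # towers still work by describing the description's description explicitly
  g <- parse_grammar(fx$fig9_simple)
  tower <- describe_grammar(decode_description(describe_grammar(g)))
  expect_true(grammar_equal(decode_description(tower), g))
})

test_that("decode rejects malformed descriptions", {
  expect_error(decode_description(parse_grammar(
    "A = QuotePoint61 B. B = QuoteX.")), "malformed")
  expect_error(decode_description(parse_grammar(
    "A = QuoteA B. B = UnquoteDrawSquare.")), "orphan")
  expect_error(decode_description(parse_grammar(fx$fig4_a)), "malformed")
})

test_that("linearization has the declared token inventory", {
  g <- parse_grammar("A = DrawSquare.")
  expect_identical(linearize_grammar(g), c("A", "1.0", "DrawSquare"))

  # combinatorial oracle: length = #rules + #alternates + #symbol occurrences
  count_len <- function(g) {
    n_alt <- sum(vapply(g$rules, function(r) length(r$alternates), integer(1)))
    n_sym <- sum(vapply(g$rules, function(r)
      sum(vapply(r$alternates, function(a) length(a$symbols), integer(1))),
      integer(1)))
    length(g$rules) + n_alt + n_sym
  }
  for (nm in c("fig13_root", "fig6_turing", "fig11_swarm")) {
    gi <- parse_grammar(fx[[nm]])
    expect_length(linearize_grammar(gi), count_len(gi))
  }
  root_lin <- linearize_grammar(parse_grammar(fx$fig13_root))
  expect_identical(sum(root_lin %in% grammar_heads(parse_grammar(fx$fig13_root)) &
                         !vapply(root_lin, argram:::is_weight_token, logical(1))) >= 8,
                   TRUE)
})

test_that("the root grammar recognizes every fixture description and itself", {
  root <- compile_grammar(root_grammar())
  for (nm in names(fx)) {
    g <- parse_grammar(fx[[nm]])
    expect_true(recognizes_description(root, g),
                label = paste("root acceptance of", nm))
  }
  expect_true(recognizes_description(root, root))
  expect_identical(nrow(validate_grammar(root)), 0L)
  expect_length(root$rules, 8)
})

test_that("ill-formed linearizations are rejected by the root grammar", {
  root <- root_grammar()
  # two consecutive weight tokens violate the alternate structure
  bad <- c("A", ".5", ".5", "DrawSquare")
  expect_false(isTRUE(recognize(root, bad, first_only = TRUE)$accepted))
  # a bare head with no alternate is not a rule
  expect_false(isTRUE(recognize(root, "A", first_only = TRUE)$accepted))
})

test_that("metaphor retargets the counting pattern to a new domain", {
  counter <- parse_grammar(fx$fig14_counter)
  m <- retarget(counter, c(DrawSquare = "DrawCircle"))
  expect_true(grammar_equal(m, parse_grammar(fx$fig14_metaphor)))
  r <- run_description(m, seed = 1)
  expect_identical(r$tokens, c("DrawCircle", "DrawCircle"))
  # the counter itself is untouched
  expect_identical(serialize_grammar(counter),
                   serialize_grammar(parse_grammar(fx$fig14_counter)))

  expect_error(retarget(parse_grammar(fx$fig1_mix), c(SpotCircle = "DrawCircle")),
               "non-actuator")
  expect_error(retarget(counter, c(DrawHexagon = "DrawCircle")), "undefined")
})

test_that("an empty metaphor mapping reproduces the original trace", {
  g <- parse_grammar(fx$fig4_a)
  d <- describe_grammar(g) # no unquotes at all
  for (s in c(2L, 9L)) {
    direct <- run_grammar(g, seed = s)
    replay <- run_description(d, seed = s)
    expect_identical(replay$tokens, direct$events$terminal)
  }
})

test_that("retargeted derivations keep their shape under a shared seed", {
  dual_map <- c(DrawSquare = "DrawTriangle", DrawCircle = "Look")
  set.seed(301)
  checked <- 0L
  for (i in 1:30) {
    g <- random_grammar()
    acts <- intersect(grammar_terminals(g), names(dual_map))
    if (length(acts) == 0) next
    m <- retarget(g, dual_map[acts])
    s <- sample.int(10000, 1)
    direct <- run_grammar(g, seed = s, max_rule_applications = 200)
    replay <- run_description(m, seed = s, max_rule_applications = 200)
    mapped <- direct$events$terminal
    hit <- mapped %in% acts
    mapped[hit] <- unname(dual_map[mapped[hit]])
    expect_identical(replay$tokens, mapped,
                     label = paste("mapped trace, random grammar", i))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("dynamic composition splices guest productions at hook events", {
  prod_reg <- arg_registry(c(`0` = "actuator", `1` = "actuator"))
  digit <- parse_grammar(fx$fig15_digit, prod_reg)
  orange <- parse_grammar(fx$fig15_orange)
  comp <- compose_grammars(digit, "1", orange)
  expect_identical(nrow(validate_grammar(comp)), 0L)
  # components stay byte-unchanged and independently executable
  expect_identical(serialize_grammar(digit),
                   serialize_grammar(parse_grammar(fx$fig15_digit, prod_reg)))
  expect_identical(serialize_grammar(orange),
                   serialize_grammar(parse_grammar(fx$fig15_orange)))
  plan <- compile_description(comp)
  set.seed(8)
  toks <- unlist(lapply(1:200, function(i) run_description(plan)$tokens))
  expect_true(all(toks %in% c("0", "PrintGreenPoint", "PrintRedPoint")))
  expect_false("1" %in% toks) # every 1 became a guest production
  expect_gt(sum(toks == "PrintGreenPoint"), 0)

  expect_error(compose_grammars(digit, "7", orange), "not a terminal")
})

test_that("single-actuator composition degenerates to a one-element metaphor", {
  counter <- parse_grammar(fx$fig14_counter)
  guest <- parse_grammar("G = DrawCircle.")
  comp <- compose_grammars(counter, "DrawSquare", guest)
  expect_identical(run_description(comp, seed = 5)$tokens,
                   run_description(retarget(counter, c(DrawSquare = "DrawCircle")),
                                   seed = 5)$tokens)
})
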