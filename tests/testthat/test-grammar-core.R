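test_that("unspecified probabilities are read as equipartition", {
  g <- parse_grammar(arg_fixtures()[["fig4_c"]])
  w <- vapply(g$rules[[1]]$alternates, function(a) a$weight, numeric(1))
  expect_equal(w, rep(0.25, 4))
})

test_that("a single unweighted alternate normalizes to weight 1", {
  g <- parse_grammar("A = DrawSquare.")
  expect_length(g$rules, 1)
  expect_length(g$rules[[1]]$alternates, 1)
  expect_equal(g$rules[[1]]$alternates[[1]]$weight, 1.0)
})

test_that("decimal and integer weight spellings normalize identically", {
  a <- parse_grammar("A = .3 B | .7 C. B = DrawSquare. C = DrawCircle.")
  b <- parse_grammar("A = 3 B | 7 C. B = DrawSquare. C = DrawCircle.")
  c3 <- parse_grammar("A = 0.3 B | 0.7 C. B = DrawSquare. C = DrawCircle.")
  expect_true(grammar_equal(a, b))
  expect_true(grammar_equal(a, c3))
  # oracle: normalize-then-compare over random raw weight vectors
  set.seed(41)
  for (i in 1:25) {
    raw <- sample(1:50, 2)
    gi <- parse_grammar(sprintf("A = %d B | %d C. B = DrawSquare. C = DrawCircle.",
                                raw[1], raw[2]))
    w <- vapply(gi$rules[[1]]$alternates, function(a) a$weight, numeric(1))
    expect_equal(w, raw / sum(raw))
  }
})

test_that("a registered numeric terminal is a symbol, not a weight", {
  g <- parse_grammar("o = 1 R Px L L L o | 0 q. q = E.")
  alt1 <- g$rules[[1]]$alternates[[1]]
  expect_identical(alt1$symbols[1], "1")
  expect_equal(alt1$weight, 0.5)
})

test_that("parser reports syntax and structural errors", {
  expect_error(parse_grammar("A = ."), "empty alternate")
  expect_error(parse_grammar("A = B | . B = DrawSquare."), "empty alternate")
  expect_error(parse_grammar("A = DrawSquare. A = DrawCircle."), "duplicate")
  expect_error(parse_grammar("A = Zork."), "neither a defined nonterminal")
  expect_error(parse_grammar("A = DrawSquare"), "not terminated")
  expect_error(parse_grammar("A = B .3 C. B = DrawSquare. C = DrawCircle."),
               "not at alternate start")
  expect_error(parse_grammar("A ; DrawSquare."), "unexpected")
})

test_that("serialize/parse round-trip is the identity, weights to 1e-9", {
  fx <- arg_fixtures()
  for (nm in names(fx)) {
    g <- parse_grammar(fx[[nm]])
    g2 <- parse_grammar(paste(serialize_grammar(g), collapse = "\n"))
    expect_true(grammar_equal(g, g2), label = paste("fixture", nm))
  }
  set.seed(101)
  for (i in 1:200) {
    g <- random_grammar()
    g2 <- parse_grammar(paste(serialize_grammar(g), collapse = "\n"))
    expect_true(grammar_equal(g, g2), label = paste("random grammar", i))
  }
})

test_that("serialization preserves the printed weight style", {
  g <- parse_grammar(arg_fixtures()[["fig4_a"]])
  s <- serialize_grammar(g)[1]
  expect_match(s, "\\.3 B", fixed = FALSE)
  expect_match(s, "\\.7 C", fixed = FALSE)
  expect_false(any(grepl("\\|\\s*\\|", serialize_grammar(g))))
})

test_that("validator flags each violation with its rule index", {
  root <- parse_grammar(arg_fixtures()[["fig13_root"]])
  expect_identical(nrow(validate_grammar(root)), 0L)

  dup <- new_grammar(list(
    new_rule("A", list(new_alternate(1, "DrawSquare"))),
    new_rule("A", list(new_alternate(1, "DrawCircle")))))
  d <- validate_grammar(dup)
  expect_identical(nrow(d), 1L)
  expect_match(d$issue, "duplicate head")
  expect_identical(d$rule, 2L)

  # mutation oracle: corrupt exactly one reference -> exactly one diagnostic
  set.seed(77)
  for (i in 1:20) {
    g <- random_grammar()
    ri <- sample(seq_along(g$rules), 1)
    ai <- sample(seq_along(g$rules[[ri]]$alternates), 1)
    si <- sample(seq_along(g$rules[[ri]]$alternates[[ai]]$symbols), 1)
    g$rules[[ri]]$alternates[[ai]]$symbols[si] <- "Zzzundefined"
    d <- validate_grammar(g)
    expect_identical(nrow(d), 1L)
    expect_identical(d$rule, ri)
  }
})

test_that("zero weights are legal but flagged", {
  g <- new_grammar(list(
    new_rule("A", list(new_alternate(0, "B"), new_alternate(1, "C"))),
    new_rule("B", list(new_alternate(1, "DrawSquare"))),
    new_rule("C", list(new_alternate(1, "DrawCircle")))))
  d <- validate_grammar(g)
  expect_identical(nrow(d), 1L)
  expect_match(d$issue, "zero-weight")
})

test_that("quote/unquote name mapping is a bijection", {
  syms <- c("A", "PrintGreenPoint", "DrawSquare", "b", "P0")
  for (s in syms) {
    q <- quote_symbol(s)
    expect_identical(quote_decode(q), list(type = "symbol", value = s))
  }
  for (w in c(0.61, 0.39, 0.5, 0.6, 0.4, 0.9, 0.1, 0.25, 0.05, 1)) {
    q <- quote_weight(w)
    expect_identical(quote_decode(q)$type, "weight")
    expect_equal(quote_decode(q)$value, w)
  }
  expect_identical(quote_weight(0.61), "QuotePoint61")
  expect_identical(quote_weight(0.6), "QuotePoint6")
  expect_error(quote_weight(1 / 3), "not representable")
  expect_identical(unquote_referent("UnquoteDrawSquare"), "DrawSquare")
})

test_that("readable renaming preserves structure and behavior", {
  root <- root_grammar()
  readable <- root_grammar(readable = TRUE)
  expect_identical(grammar_heads(readable)[1:2], c("Rules", "Rule"))
  expect_identical(serialize_grammar(readable)[2], "Rule = Symbol Alternates.")

  g <- parse_grammar(arg_fixtures()[["fig4_a"]])
  same <- rename_for_readability(g, c(A = "A", B = "B", C = "C"))
  expect_true(grammar_equal(g, same))

  expect_error(rename_for_readability(g, c(A = "X", B = "X")), "injective")
  expect_error(rename_for_readability(g, c(Zz = "X")), "undefined")
  expect_error(rename_for_readability(g, c(A = "DrawSquare")), "collide")

  # trace-equality oracle under a shared seed
  ren <- rename_for_readability(g, c(A = "Start", B = "Sq", C = "Ci"))
  d1 <- run_grammar(g, seed = 99)
  d2 <- run_grammar(ren, seed = 99)
  expect_identical(d1$events$terminal, d2$events$terminal)
  expect_identical(d1$choices$alternate, d2$choices$alternate)
})
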