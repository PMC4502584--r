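fx <- arg_fixtures()

test_that("production, recognition, and mixed mode behave per the shape trio", {
  draw <- parse_grammar(fx$fig1_draw)
  d <- run_grammar(draw, seed = 1)
  expect_identical(d$status, "complete")
  expect_identical(d$events$terminal, c("DrawSquare", "DrawCircle", "DrawTriangle"))
  expect_true(all(d$events$direction == "actuator"))

  mix <- parse_grammar(fx$fig1_mix)
  env <- env_stream("SpotCircle")
  dm <- run_grammar(mix, env, seed = 1)
  expect_identical(dm$status, "complete")
  expect_identical(dm$events$terminal[dm$events$direction == "sensor"], "SpotCircle")
  expect_identical(dm$events$terminal[dm$events$direction == "actuator"],
                   c("DrawSquare", "DrawTriangle"))
  expect_identical(env$snapshot()$consumed, 1L)
})

test_that("the gated loop draws as many squares as there are circles", {
  g <- compile_grammar(parse_grammar(fx$fig5_gated))
  for (N in c(0L, 1L, 5L, 23L)) {
    d <- run_grammar(g, env_stream(rep("SpotCircle", N)), seed = 1)
    expect_identical(sum(d$events$terminal == "DrawSquare"), N)
    expect_identical(sum(d$events$direction == "sensor"), N)
  }
})

test_that("non-termination is reported as budget exhaustion, not an error", {
  g <- parse_grammar(fx$fig5_loop)
  d <- run_grammar(g, seed = 1, max_rule_applications = 50)
  expect_identical(d$status, "exhausted")
  expect_identical(unique(d$events$terminal), "DrawSquare")
  expect_gt(nrow(d$events), 10)
})

test_that("sensor mismatch with no viable alternate is a recognition failure", {
  g <- parse_grammar(fx$fig1_spot)
  d <- run_grammar(g, env_stream(c("SpotSquare", "SpotTriangle")), seed = 1)
  expect_identical(d$status, "failed")
})

test_that("identical grammar, environment, and seed give identical traces", {
  g <- parse_grammar(fx$fig7_digits, arg_registry(c(`0` = "actuator", `1` = "actuator")))
  for (s in c(3L, 17L)) {
    d1 <- run_grammar(g, seed = s, max_rule_applications = 500)
    d2 <- run_grammar(g, seed = s, max_rule_applications = 500)
    expect_identical(d1$events, d2$events)
    expect_identical(d1$choices, d2$choices)
    expect_identical(d1$loglik, d2$loglik)
  }
})

test_that("derivation loglik is the sum of chosen alternate log-weights", {
  g <- parse_grammar(fx$fig4_a)
  d <- run_grammar(g, seed = 4)
  w <- if (d$events$terminal == "DrawSquare") 0.3 else 0.7
  expect_equal(d$loglik, log(w))
  expect_true(d$loglik <= 0)
})

test_that("event depth counts rule applications and seq strictly increases", {
  d <- run_grammar(parse_grammar(fx$fig2_c), seed = 1)
  sq <- d$events[d$events$terminal == "DrawSquare", ]
  ci <- d$events[d$events$terminal == "DrawCircle", ]
  expect_identical(sq$depth, 2L)
  expect_identical(ci$depth, 3L)
  expect_true(all(diff(d$events$seq) > 0))
  expect_true(all(d$events$depth >= 1L))
})

test_that("event order follows depth, with recognition ahead of production", {
  # square at two rule applications precedes circle at three
  d <- run_grammar(parse_grammar(fx$fig2_c), seed = 1)
  ord <- event_order(d)
  expect_identical(nrow(ord), 1L)
  expect_identical(d$events$terminal[ord$before], "DrawSquare")
  expect_identical(d$events$terminal[ord$after], "DrawCircle")

  # equal depth, both actuators: mutually unordered
  d2 <- run_grammar(parse_grammar(fx$fig2_a), seed = 1)
  expect_identical(nrow(event_order(d2)), 0L)

  # equal depth, sensor precedes actuator
  d3 <- run_grammar(parse_grammar(fx$fig1_mix), env_stream("SpotCircle"), seed = 1)
  ord3 <- event_order(d3)
  at_eq <- ord3[d3$events$depth[ord3$before] == d3$events$depth[ord3$after], ]
  expect_true(all(d3$events$direction[at_eq$before] == "sensor"))

  # single event: empty relation
  d4 <- run_grammar(parse_grammar(fx$fig9_simple), seed = 1)
  expect_identical(nrow(event_order(d4)), 0L)
})

test_that("complete-derivation probabilities sum to 1 for finite grammars", {
  for (nm in c("fig1_draw", "fig2_c", "fig4_a", "fig4_c", "fig11_swarm")) {
    ders <- enumerate_derivations(parse_grammar(fx[[nm]]), max_apps = 30)
    expect_equal(sum(vapply(ders, function(d) d$prob, numeric(1))), 1,
                 tolerance = 1e-9, label = paste("probability mass of", nm))
  }
})

test_that("recognition accepts exactly the full-consumption inputs", {
  spot <- parse_grammar(fx$fig1_spot)
  full <- recognize(spot, c("SpotSquare", "SpotCircle", "SpotTriangle"))
  expect_true(full$accepted)
  expect_equal(full$loglik, 0) # all weights 1
  expect_identical(full$consumed, 3L)

  short <- recognize(spot, c("SpotSquare", "SpotCircle"))
  expect_false(short$accepted)
  wrong <- recognize(spot, c("SpotCircle", "SpotSquare", "SpotTriangle"))
  expect_false(wrong$accepted)
})

test_that("digit-grammar acceptance probabilities match exhaustive enumeration", {
  prod_reg <- arg_registry(c(`0` = "actuator", `1` = "actuator"))
  gen <- parse_grammar(fx$fig7_digits, prod_reg)
  ders <- enumerate_derivations(gen, max_apps = 30)
  mass <- tapply(vapply(ders, function(d) d$prob, numeric(1)),
                 vapply(ders, function(d) paste(d$tokens, collapse = ""),
                        character(1)), sum)
  rec <- parse_grammar(fx$fig7_digits) # 0/1 as sensors
  set.seed(13)
  strings <- unique(c(
    unlist(lapply(1:4, function(n) apply(expand.grid(rep(list(c("0", "1")), n)),
                                         1, paste, collapse = ""))),
    vapply(1:12, function(i) paste(sample(c("0", "1"), 8, TRUE), collapse = ""),
           character(1))))
  for (s in strings) {
    r <- recognize(rec, strsplit(s, "")[[1]])
    expect_true(r$accepted, label = paste("acceptance of", s))
    expect_equal(r$loglik, log(mass[[s]]), tolerance = 1e-9,
                 label = paste("likelihood of", s))
  }
})

test_that("a sensor-dual grammar accepts any pure-actuator output trace", {
  dual_map <- c(DrawSquare = "SpotSquare", DrawCircle = "SpotCircle",
                DrawTriangle = "SpotTriangle", Look = "See",
                PrintGreenPoint = "ReadGreenPoint", PrintRedPoint = "ReadRedPoint")
  set.seed(55)
  checked <- 0L
  for (i in 1:40) {
    g <- random_grammar()
    d <- run_grammar(g, max_rule_applications = 40)
    if (!identical(d$status, "complete") || nrow(d$events) == 0 ||
        nrow(d$events) > 12) next
    dual <- sensor_dual(g)
    r <- recognize(dual, unname(dual_map[d$events$terminal]),
                   search_budget = 500000, first_only = TRUE)
    expect_true(r$accepted, label = paste("dual acceptance, random grammar", i))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("recognition flags budget exhaustion as indeterminate", {
  g <- parse_grammar(fx$fig7_digits)
  r <- recognize(g, rep("0", 12), search_budget = 5)
  expect_true(is.na(r$accepted))
  expect_true(r$exhausted)
})
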