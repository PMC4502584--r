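# Independent oracles used across the suite. These deliberately avoid the
# package's execution engine: enumeration is plain recursive expansion, the
# Turing oracle is a table-driven machine, and the DOT reader is a minimal
# line parser for the emitted dialect.

# Exhaustively enumerate complete derivations (token sequence + probability)
# up to a rule-application cap; derivations exceeding the cap are dropped.
enumerate_derivations <- function(g, max_apps = 30) {
  heads <- grammar_heads(g)
  syms <- unique(c(heads, grammar_terminals(g)))
  kinds <- symbol_kind(syms, g)
  names(kinds) <- syms
  out <- list()
  recurse <- function(agenda, prob, toks, apps) {
    if (length(agenda) == 0) {
      out[[length(out) + 1L]] <<- list(tokens = toks, prob = prob)
      return(invisible(NULL))
    }
    s <- agenda[1]
    rest <- agenda[-1]
    if (identical(unname(kinds[s]), "nonterminal")) {
      if (apps >= max_apps) return(invisible(NULL))
      r <- g$rules[[match(s, heads)]]
      for (a in r$alternates)
        recurse(c(a$symbols, rest), prob * a$weight, toks, apps + 1L)
    } else {
      recurse(rest, prob, c(toks, s), apps)
    }
    invisible(NULL)
  }
  recurse(heads[1], 1, character(), 0L)
  out
}

# Table-driven machine for the seminal example: five m-configurations
# printing the sequence of binary figures 0 0 1 0 1 1 0 1 1 1 ... Records
# the operation name and a full tape snapshot after every operation.
turing_oracle <- function(n_ops) {
  tape <- new.env(parent = emptyenv())
  head <- 0L
  scan <- function() {
    v <- tape[[as.character(head)]]
    if (is.null(v)) "None" else v
  }
  snap <- function() {
    keys <- ls(tape)
    if (length(keys) == 0) return(list(cells = character(), head = head))
    v <- vapply(keys, function(k) tape[[k]], character(1))
    names(v) <- keys
    list(cells = v[order(as.integer(keys))], head = head)
  }
  apply_op <- function(op) {
    k <- as.character(head)
    switch(op,
      Pe = assign(k, "e", envir = tape), P0 = assign(k, "0", envir = tape),
      P1 = assign(k, "1", envir = tape), Px = assign(k, "x", envir = tape),
      R = head <<- head + 1L, L = head <<- head - 1L,
      E = if (exists(k, envir = tape)) rm(list = k, envir = tape))
  }
  table <- list(
    b = list(list(scan = "*", ops = c("Pe","R","Pe","R","P0","R","R","P0","L","L"),
                  nxt = "o")),
    o = list(list(scan = "1", ops = c("R","Px","L","L","L"), nxt = "o"),
             list(scan = "0", ops = character(), nxt = "q")),
    q = list(list(scan = c("0","1"), ops = c("R","R"), nxt = "q"),
             list(scan = "None", ops = c("P1","L"), nxt = "p")),
    p = list(list(scan = "x", ops = c("E","R"), nxt = "q"),
             list(scan = "e", ops = "R", nxt = "f"),
             list(scan = "None", ops = c("L","L"), nxt = "p")),
    f = list(list(scan = c("0","1"), ops = c("R","R"), nxt = "f"),
             list(scan = "None", ops = c("P0","L","L"), nxt = "o")))
  ops <- character(); snaps <- list(); config <- "b"
  while (length(ops) < n_ops) {
    s <- scan()
    branch <- NULL
    for (br in table[[config]])
      if (identical(br$scan, "*") || s %in% br$scan) { branch <- br; break }
    if (is.null(branch)) stop("oracle machine stuck in ", config, " scanning ", s)
    for (op in branch$ops) {
      apply_op(op)
      ops <- c(ops, op)
      snaps[[length(snaps) + 1L]] <- snap()
      if (length(ops) >= n_ops) break
    }
    config <- branch$nxt
  }
  list(ops = ops, snapshots = snaps)
}

oracle_figures <- function(n) {
  st <- turing_oracle(40 * n)
  last <- st$snapshots[[length(st$snapshots)]]
  figs <- last$cells[last$cells %in% c("0", "1")]
  paste(figs[seq_len(n)], collapse = "")
}

# Minimal reader for the DOT dialect the package emits.
parse_dot <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nodes <- character(); node_attrs <- character()
  edges <- data.frame(from = character(), to = character(), label = character(),
                      stringsAsFactors = FALSE)
  for (ln in lines) {
    em <- regmatches(ln, regexec(
      '^\\s*"?([^"\\s]+)"?\\s*->\\s*"?([^"\\s]+)"?\\s*\\[(.*)\\];\\s*$', ln))[[1]]
    if (length(em) == 4) {
      lab <- regmatches(em[4], regexec('label="([^"]*)"', em[4]))[[1]]
      edges <- rbind(edges, data.frame(
        from = em[2], to = em[3],
        label = if (length(lab) == 2) lab[2] else NA_character_,
        stringsAsFactors = FALSE))
      next
    }
    nm <- regmatches(ln, regexec(
      '^\\s*"?([^"\\s]+)"?\\s*\\[(.*)\\];\\s*$', ln))[[1]]
    if (length(nm) == 3) {
      nodes <- c(nodes, nm[2]); node_attrs <- c(node_attrs, nm[3])
    }
  }
  list(nodes = nodes, node_attrs = node_attrs, edges = edges)
}

# Random quote-free grammar with two-decimal weights (so descriptions are
# representable); every referenced nonterminal is defined.
random_grammar <- function() {
  n_rules <- sample(1:5, 1)
  heads <- paste0("N", seq_len(n_rules))
  actuators <- c("DrawSquare", "DrawCircle", "DrawTriangle", "Look",
                 "PrintGreenPoint", "PrintRedPoint")
  rules <- lapply(seq_len(n_rules), function(i) {
    k <- sample(1:3, 1)
    w <- as.numeric(stats::rmultinom(1, 100 - k, rep(1, k)) + 1) / 100
    alts <- lapply(seq_len(k), function(j) {
      m <- sample(1:3, 1)
      new_alternate(w[j], sample(c(heads, actuators), m, replace = TRUE))
    })
    new_rule(heads[i], alts)
  })
  new_grammar(rules)
}

# Are all weights exactly representable as decimal quote literals?
representable <- function(g, precision = 2) {
  w <- unlist(lapply(g$rules, function(r)
    vapply(r$alternates, function(a) a$weight, numeric(1))))
  all(abs(w * 10^precision - round(w * 10^precision)) < 1e-6)
}

# Sensor dual of a pure-actuator grammar over the drawable/printable shapes.
sensor_dual <- function(g) {
  dual_map <- c(DrawSquare = "SpotSquare", DrawCircle = "SpotCircle",
                DrawTriangle = "SpotTriangle", Look = "See",
                PrintGreenPoint = "ReadGreenPoint",
                PrintRedPoint = "ReadRedPoint")
  g$rules <- lapply(g$rules, function(r) {
    r$alternates <- lapply(r$alternates, function(a) {
      hit <- a$symbols %in% names(dual_map)
      a$symbols[hit] <- unname(dual_map[a$symbols[hit]])
      a
    })
    r
  })
  g
}
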