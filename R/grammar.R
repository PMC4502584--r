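#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Data model: an activation/recognition grammar is an ordered list of rules,
# each rule an ordered list of weighted alternates over symbol sequences.
# Terminal direction (sensor vs actuator) comes from an explicit registry,
# never from the symbol's spelling: the same token can be read in one usage
# and produced in another, so direction is a property of the binding, not
# the name.
# ---------------------------------------------------------------------------

#' Default terminal registry
#'
#' Maps terminal names to their channel direction, `"sensor"` (match and
#' consume input) or `"actuator"` (emit output). The default covers every
#' terminal used by the example grammars shipped with the package, including
#' the Turing-tape operations (`Pe`, `P0`, `P1`, `Px`, `R`, `L`, `E` write or
#' move; `0`, `1`, `x`, `e`, `None` read the scanned cell) and the two class
#' sensors `Symbol` and `Weight` used by the root grammar, which match any
#' symbol token and any weight token respectively.
#'
#' A token that is the head of a rule is always a nonterminal, regardless of
#' the registry; `Quote`/`Unquote` prefixes are recognized before the
#' registry is consulted.
#'
#' @param overrides named character vector of `name = "sensor"|"actuator"`
#'   entries that replace or extend the defaults. Needed, e.g., when the
#'   digit grammar is run in production and `0`/`1` act as actuators.
#' @return named character vector, values `"sensor"` or `"actuator"`.
#' @export
arg_registry <- function(overrides = NULL) {
  reg <- c(
    DrawSquare = "actuator", DrawCircle = "actuator", DrawTriangle = "actuator",
    Look = "actuator", Describe = "actuator",
    PrintGreenPoint = "actuator", PrintRedPoint = "actuator",
    Pe = "actuator", P0 = "actuator", P1 = "actuator", Px = "actuator",
    R = "actuator", L = "actuator", E = "actuator",
    SpotSquare = "sensor", SpotCircle = "sensor", SpotTriangle = "sensor",
    See = "sensor",
    ReadGreenPoint = "sensor", ReadRedPoint = "sensor",
    SpotGreenPoint = "sensor", SpotRedPoint = "sensor",
    `0` = "sensor", `1` = "sensor", None = "sensor", x = "sensor", e = "sensor",
    Symbol = "sensor", Weight = "sensor"
  )
  if (!is.null(overrides)) {
    bad <- setdiff(unique(overrides), c("sensor", "actuator"))
    if (length(bad) > 0)
      stop("registry direction must be 'sensor' or 'actuator', got: ",
           paste(bad, collapse = ", "))
    reg[names(overrides)] <- overrides
  }
  reg
}

#' Construct an alternate (low level)
#'
#' @param weight non-negative numeric weight.
#' @param symbols non-empty character vector of symbol names.
#' @export
new_alternate <- function(weight, symbols) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.character(symbols))
  list(weight = as.numeric(weight), symbols = symbols)
}

#' Construct a rule (low level)
#'
#' @param head nonterminal name.
#' @param alternates list of alternates, see [new_alternate()].
#' @export
new_rule <- function(head, alternates) {
  stopifnot(is.character(head), length(head) == 1L, is.list(alternates))
  list(head = head, alternates = alternates)
}

#' Construct a grammar from rules (low level)
#'
#' Does not validate: use [validate_grammar()] for diagnostics. Prefer
#' [parse_grammar()] for checked construction from notation text.
#'
#' @param rules list of rules, see [new_rule()].
#' @param registry terminal registry, see [arg_registry()].
#' @export
new_grammar <- function(rules, registry = arg_registry()) {
  structure(list(rules = rules, registry = registry), class = "arg_grammar")
}

#' @export
print.arg_grammar <- function(x, ...) {
  cat("<activation/recognition grammar>", length(x$rules), "rule(s)\n")
  cat(serialize_grammar(x), sep = "\n")
  invisible(x)
}

#' Rule heads of a grammar
#' @param g grammar.
#' @return character vector of nonterminal names in definition order.
#' @export
grammar_heads <- function(g) {
  vapply(g$rules, function(r) r$head, character(1))
}

#' Distinct terminal symbols occurring in a grammar
#' @param g grammar.
#' @export
grammar_terminals <- function(g) {
  heads <- grammar_heads(g)
  syms <- unlist(lapply(g$rules, function(r)
    unlist(lapply(r$alternates, function(a) a$symbols))))
  unique(setdiff(syms, heads))
}

#' Classify symbols of a grammar
#'
#' A token is a nonterminal if it heads a rule; otherwise a quoted or
#' unquoted token if prefixed `Quote`/`Unquote`; otherwise its direction is
#' looked up in the grammar's registry.
#'
#' @param name character vector of symbol names.
#' @param g grammar providing heads and registry.
#' @return character vector over `"nonterminal"`, `"sensor"`, `"actuator"`,
#'   `"quoted"`, `"unquoted"`; `NA` for unclassifiable tokens.
#' @export
symbol_kind <- function(name, g) {
  heads <- grammar_heads(g)
  vapply(name, function(s) {
    if (s %in% heads) return("nonterminal")
    if (grepl("^Unquote.", s)) return("unquoted")
    if (grepl("^Quote.", s)) return("quoted")
    if (s %in% names(g$registry)) return(unname(g$registry[[s]]))
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Quote/unquote codec. `QuoteX` stands for the token `X` as inert data;
# `UnquoteX` intercepts the described grammar's event `X`. Weight literals
# are encoded positionally: `QuotePoint61` <-> 0.61, `QuotePoint6` <-> 0.6,
# with weight exactly 1 as `QuotePoint100`.
# ---------------------------------------------------------------------------

#' Encode a symbol token as its quoted form
#' @param name symbol token(s).
#' @export
quote_symbol <- function(name) paste0("Quote", name)

#' Encode a weight as a quoted weight literal
#'
#' @param w weight in `[0, 1]`.
#' @param precision decimal digits representable (default 2). Weights not
#'   representable at this precision are an error, not silently rounded.
#' @export
quote_weight <- function(w, precision = 2) {
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w <= 1)
  if (abs(w - 1) < 1e-9) return("QuotePoint100")
  scaled <- w * 10^precision
  if (abs(scaled - round(scaled)) > 1e-6)
    stop(sprintf("weight %.6g is not representable at %d decimal digits", w, precision))
  digits <- sprintf(paste0("%0", precision, "d"), as.integer(round(scaled)))
  digits <- sub("(.)0+$", "\\1", digits) # .60 prints as Point6, as in the worked examples
  paste0("QuotePoint", digits)
}

#' Test for a quoted weight literal
#' @param token character vector.
#' @export
is_weight_quote <- function(token) grepl("^QuotePoint[0-9]+$", token)

#' Decode a quoted token
#'
#' Inverse of [quote_symbol()] / [quote_weight()]: returns a list with
#' `type` (`"symbol"` or `"weight"`) and `value`.
#'
#' @param token a single `Quote...` token.
#' @export
quote_decode <- function(token) {
  stopifnot(length(token) == 1L)
  if (is_weight_quote(token)) {
    digits <- sub("^QuotePoint", "", token)
    value <- if (digits == "100") 1 else as.numeric(paste0("0.", digits))
    return(list(type = "weight", value = value))
  }
  if (grepl("^Quote.", token))
    return(list(type = "symbol", value = sub("^Quote", "", token)))
  stop("not a quoted token: ", token)
}

#' Referent of an unquote token
#' @param token a single `Unquote...` token.
#' @export
unquote_referent <- function(token) {
  stopifnot(grepl("^Unquote.", token))
  sub("^Unquote", "", token)
}

# Weight tokens (as used in linearized grammars) always contain a decimal
# point, keeping them disjoint from symbol tokens such as the digits 0 and 1.
is_weight_token <- function(token) grepl("^[0-9]*\\.[0-9]+$", token)

fmt_weight_token <- function(w) {
  if (abs(w - round(w)) < 1e-9) return(sprintf("%d.0", as.integer(round(w))))
  sub("^0\\.", ".", sprintf("%.10g", w))
}

# ---------------------------------------------------------------------------
# Parser
# ---------------------------------------------------------------------------

arg_tokenize <- function(text) {
  pat <- "[A-Za-z][A-Za-z0-9]*|[0-9]*\\.[0-9]+|[0-9]+|=|\\||\\."
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(data.frame(token = character(), pos = integer()))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # anything not matched must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(m))
    covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
  rest <- strsplit(text, "")[[1]][!covered]
  if (any(!grepl("^\\s$", rest)))
    stop("syntax error: unexpected character(s) ",
         paste(sQuote(unique(rest[!grepl("^\\s$", rest)])), collapse = ", "))
  data.frame(token = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

is_number_form <- function(token) grepl("^([0-9]*\\.[0-9]+|[0-9]+)$", token)
is_name_form <- function(token) grepl("^[A-Za-z][A-Za-z0-9]*$", token)

#' Parse a probability-weighted grammar from Wirth-style notation
#'
#' The notation is a minimal subset of Wirth's syntax notation augmented with
#' probabilities: rules are `Head = alternates.`, alternates are separated by
#' `|`, and each alternate is an optional weight followed by one or more
#' symbols. Weights may be written `.3`, `0.3`, or as bare non-negative
#' numbers; within a rule they are normalized to sum to 1, and a rule written
#' without weights is read as equipartition (each of k alternates gets 1/k).
#' Grammars have no null symbol: an empty alternate is a syntax error.
#'
#' A leading numeric token in an alternate is a weight unless it is a
#' registered terminal (so `o = 1 R Px L L L o | 0 q.` reads the tape symbol
#' `1`, while `A = 3 B | 7 C.` carries weights 3 and 7).
#'
#' @param text grammar text (plain, one or more rules).
#' @param registry terminal registry, see [arg_registry()].
#' @return a validated grammar object.
#' @examples
#' g <- parse_grammar("A = .3 B | .7 C. B = DrawSquare. C = DrawCircle.")
#' serialize_grammar(g)
#' @export
parse_grammar <- function(text, registry = arg_registry()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  tk <- arg_tokenize(text)
  if (nrow(tk) == 0) stop("syntax error: no tokens")
  toks <- tk$token; pos <- tk$pos
  i <- 1L; n <- length(toks)
  rules <- list()
  expect <- function(what, test) {
    if (i > n) stop(sprintf("syntax error at end of input: expected %s", what))
    if (!test(toks[i]))
      stop(sprintf("syntax error at position %d near '%s': expected %s",
                   pos[i], toks[i], what))
  }
  while (i <= n) {
    expect("rule head (a name)", is_name_form)
    head <- toks[i]; i <- i + 1L
    expect("'='", function(t) t == "=")
    i <- i + 1L
    alternates <- list()
    alt_toks <- character()
    flush_alt <- function() {
      if (length(alt_toks) == 0)
        stop(sprintf("empty alternate in rule '%s' (grammars have no null symbol)", head))
      w <- NA_real_
      if (length(alt_toks) >= 2 && is_number_form(alt_toks[1]) &&
          !(alt_toks[1] %in% names(registry))) {
        w <- as.numeric(alt_toks[1])
        alt_toks <- alt_toks[-1]
      }
      stray <- alt_toks[-1][is_number_form(alt_toks[-1]) &
                              !(alt_toks[-1] %in% names(registry))]
      if (length(stray) > 0)
        stop(sprintf("syntax error in rule '%s': weight token '%s' not at alternate start",
                     head, stray[1]))
      alternates[[length(alternates) + 1L]] <<- new_alternate(w, alt_toks)
      alt_toks <<- character()
    }
    repeat {
      if (i > n) stop(sprintf("syntax error: rule '%s' not terminated by '.'", head))
      t <- toks[i]
      if (t == ".") { flush_alt(); i <- i + 1L; break }
      if (t == "|") { flush_alt(); i <- i + 1L; next }
      if (t == "=") stop(sprintf("syntax error at position %d: unexpected '=' in rule '%s'",
                                 pos[i], head))
      alt_toks <- c(alt_toks, t)
      i <- i + 1L
    }
    rules[[length(rules) + 1L]] <- new_rule(head, alternates)
  }
  g <- new_grammar(normalize_weights(rules), registry)
  issues <- validate_grammar(g)
  hard <- issues[!grepl("^zero-weight", issues$issue), , drop = FALSE]
  if (nrow(hard) > 0)
    stop("invalid grammar: ", paste(sprintf("[rule %d] %s", hard$rule, hard$issue),
                                    collapse = "; "))
  g
}

normalize_weights <- function(rules) {
  lapply(rules, function(r) {
    k <- length(r$alternates)
    w <- vapply(r$alternates, function(a) a$weight, numeric(1))
    w[is.na(w)] <- 1 / k
    if (any(w < 0)) {
      # leave negatives for validate() to flag
    } else if (sum(w) > 0) {
      w <- w / sum(w)
    }
    r$alternates <- Map(function(a, wi) { a$weight <- wi; a }, r$alternates, w)
    r
  })
}

# ---------------------------------------------------------------------------
# Serializer and validator
# ---------------------------------------------------------------------------

fmt_weight <- function(w) {
  s <- sprintf("%.10g", w)
  sub("^0\\.", ".", s)
}

#' Serialize a grammar back to notation text
#'
#' Round-trip guarantee: `parse_grammar(serialize_grammar(g))` is
#' structurally identical to `g` (weights within 1e-9). A single alternate of
#' weight 1 is written without a weight token, matching the conventional
#' style of the example grammars.
#'
#' @param g grammar.
#' @return character vector, one rule per element.
#' @export
serialize_grammar <- function(g) {
  vapply(g$rules, function(r) {
    single <- length(r$alternates) == 1L
    alts <- vapply(r$alternates, function(a) {
      if (single && abs(a$weight - 1) < 1e-9) paste(a$symbols, collapse = " ")
      else paste(c(fmt_weight(a$weight), a$symbols), collapse = " ")
    }, character(1))
    paste0(r$head, " = ", paste(alts, collapse = " | "), ".")
  }, character(1))
}

#' Validate a grammar
#'
#' Checks the structural invariants: unique rule heads, non-empty alternates,
#' every right-hand-side nonterminal defined (terminals must be classifiable
#' by registry or `Quote`/`Unquote` prefix), and per-rule weights summing to
#' 1 within 1e-9. A weight of exactly 0 is legal but flagged, since the
#' source formalism only ever describes inhibition as probability below .5.
#'
#' @param g grammar.
#' @return data frame with columns `rule` (index) and `issue`; zero rows iff
#'   the grammar is valid.
#' @export
validate_grammar <- function(g) {
  out <- list()
  add <- function(rule, issue) out[[length(out) + 1L]] <<- list(rule = rule, issue = issue)
  heads <- grammar_heads(g)
  if (length(g$rules) == 0) add(0L, "grammar has no rules")
  dup <- which(duplicated(heads))
  for (d in dup) add(d, sprintf("duplicate head '%s'", heads[d]))
  for (i in seq_along(g$rules)) {
    r <- g$rules[[i]]
    if (length(r$alternates) == 0) { add(i, "rule has no alternates"); next }
    w <- vapply(r$alternates, function(a) a$weight, numeric(1))
    if (any(is.na(w)) || any(w < 0)) add(i, "negative or missing alternate weight")
    else {
      if (abs(sum(w) - 1) > 1e-9) add(i, sprintf("alternate weights sum to %.6g, not 1", sum(w)))
      if (any(w == 0)) add(i, "zero-weight alternate (legal but never selectable)")
    }
    for (a in r$alternates) {
      if (length(a$symbols) == 0) { add(i, "empty alternate"); next }
      kind <- symbol_kind(a$symbols, g)
      for (s in a$symbols[is.na(kind)])
        add(i, sprintf("'%s' is neither a defined nonterminal nor a classifiable terminal", s))
    }
  }
  if (length(out) == 0)
    return(data.frame(rule = integer(), issue = character(), stringsAsFactors = FALSE))
  data.frame(rule = vapply(out, `[[`, integer(1), "rule"),
             issue = vapply(out, `[[`, character(1), "issue"),
             stringsAsFactors = FALSE)
}

#' Structural equality of two grammars
#'
#' Same rules in the same order, same heads, same alternate symbol sequences,
#' weights equal within `tol`.
#'
#' @param a,b grammars.
#' @param tol numeric tolerance on weights.
#' @export
grammar_equal <- function(a, b, tol = 1e-9) {
  if (length(a$rules) != length(b$rules)) return(FALSE)
  for (i in seq_along(a$rules)) {
    ra <- a$rules[[i]]; rb <- b$rules[[i]]
    if (!identical(ra$head, rb$head)) return(FALSE)
    if (length(ra$alternates) != length(rb$alternates)) return(FALSE)
    for (j in seq_along(ra$alternates)) {
      aa <- ra$alternates[[j]]; ab <- rb$alternates[[j]]
      if (!identical(aa$symbols, ab$symbols)) return(FALSE)
      if (abs(aa$weight - ab$weight) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Rename nonterminals for readability
#'
#' Substitutes nonterminal names throughout the grammar, e.g. recasting the
#' root grammar's `A` as `Rules` and `B` as `Rule`. Derivation behavior is
#' unchanged: only names differ. Quoted tokens are left untouched (they refer
#' to the described grammar's namespace, not this one).
#'
#' @param g grammar.
#' @param mapping named character vector, `old = "new"`; must be injective
#'   and must not collide with remaining nonterminals or with terminals used
#'   in `g`.
#' @return the renamed grammar.
#' @export
rename_for_readability <- function(g, mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (anyDuplicated(mapping) > 0) stop("mapping is not injective")
  heads <- grammar_heads(g)
  unknown <- setdiff(names(mapping), heads)
  if (length(unknown) > 0)
    stop("mapping refers to undefined nonterminal(s): ", paste(unknown, collapse = ", "))
  kept <- setdiff(heads, names(mapping))
  clash <- intersect(mapping, c(kept, grammar_terminals(g)))
  if (length(clash) > 0)
    stop("new name(s) collide with existing symbols: ", paste(clash, collapse = ", "))
  subst <- function(s) ifelse(s %in% names(mapping), unname(mapping[s]), s)
  rules <- lapply(g$rules, function(r) {
    r$head <- subst(r$head)
    r$alternates <- lapply(r$alternates, function(a) {
      nt <- a$symbols %in% heads
      a$symbols[nt] <- subst(a$symbols[nt])
      a
    })
    r
  })
  new_grammar(rules, g$registry)
}
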