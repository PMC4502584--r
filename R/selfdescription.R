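# ---------------------------------------------------------------------------
# Quote/unquote self-description: grammars encoded as grammars. A describing
# grammar sequences one branch per described rule; each branch emits the
# quoted head followed, per alternate, by a quoted weight literal (omitted
# for a weight-1 single alternate) and the quoted symbols. The scheme is
# invertible, which is what makes swarms, metaphor, and composition work on
# descriptions rather than on the circuits themselves.
# ---------------------------------------------------------------------------

fresh_allocator <- function(avoid = character()) {
  pool <- c(LETTERS, as.vector(t(outer(1:99, LETTERS, function(i, l) paste0(l, i)))))
  i <- 0L
  function() {
    repeat {
      i <<- i + 1L
      if (i > length(pool)) stop("fresh-nonterminal pool exhausted")
      if (!(pool[i] %in% avoid)) return(pool[i])
    }
  }
}

#' Describe a grammar as a grammar
#'
#' Returns a describing grammar whose terminals quote the described
#' grammar's heads, weights, and symbols. The top rule sequences one branch
#' per described rule; each branch emits `QuoteHead` and then, per
#' alternate, `QuotePointNN` (omitted for a single alternate of weight 1)
#' followed by the quoted symbols. Fresh nonterminals are allocated
#' deterministically (`A`, `B`, `C`, ...) so results are reproducible and
#' comparable to hand-written descriptions by structural identity.
#'
#' One level of description per call: towers of descriptions are built by
#' repeated calls.
#'
#' @param g grammar containing no quoted symbols.
#' @param precision decimal digits for quoted weight literals (default 2);
#'   weights not representable at this precision are an error.
#' @return the describing grammar; `decode_description()` inverts it.
#' @export
describe_grammar <- function(g, precision = 2) {
  stopifnot(inherits(g, "arg_grammar"))
  kinds <- symbol_kind(unique(c(grammar_heads(g), grammar_terminals(g))), g)
  if (any(kinds %in% c("quoted", "unquoted")))
    stop("grammar already contains quoted symbols; describe one level at a time")
  alloc <- fresh_allocator()
  n <- length(g$rules)
  rules_out <- list()
  add <- function(head, alternates) rules_out[[length(rules_out) + 1L]] <<-
    new_rule(head, alternates)
  single_alt <- function(symbols) list(new_alternate(1, symbols))

  top <- alloc()
  branches <- if (n > 1) vapply(seq_len(n), function(i) alloc(), character(1)) else top
  if (n > 1) add(top, single_alt(branches))
  for (i in seq_len(n)) {
    r <- g$rules[[i]]
    alts <- r$alternates
    weightless <- length(alts) == 1L && abs(alts[[1]]$weight - 1) < 1e-9
    part <- alloc()
    add(branches[i], single_alt(c(quote_symbol(r$head), part)))
    if (weightless) {
      add(part, single_alt(quote_symbol(alts[[1]]$symbols)))
    } else {
      subs <- vapply(seq_along(alts), function(j) alloc(), character(1))
      add(part, single_alt(subs))
      for (j in seq_along(alts))
        add(subs[j], single_alt(c(quote_weight(alts[[j]]$weight, precision),
                                  quote_symbol(alts[[j]]$symbols))))
    }
  }
  new_grammar(rules_out, g$registry)
}

# Rules of `d` reachable from head `root`, root's rule first.
subgrammar <- function(d, root) {
  heads <- grammar_heads(d)
  keep <- root
  frontier <- root
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(h) {
      r <- d$rules[[match(h, heads)]]
      syms <- unlist(lapply(r$alternates, function(a) a$symbols))
      intersect(syms, heads)
    })))
    frontier <- setdiff(nxt, keep)
    keep <- c(keep, frontier)
  }
  new_grammar(d$rules[match(keep, heads)], d$registry)
}

# Full decode: described grammar plus interception map. Interceptions come
# from Unquote tokens: `UnquoteOld New` redirects the described event Old to
# the terminal New; `UnquoteOld G` with G a nonterminal of the description
# splices a full production of the grammar described under G.
decode_full <- function(d) {
  stopifnot(inherits(d, "arg_grammar"))
  heads <- grammar_heads(d)
  rule_of <- function(h) d$rules[[match(h, heads)]]
  intercepts <- list()
  malformed <- function(why) stop("malformed description: ", why)

  the_single <- function(r, what) {
    if (length(r$alternates) != 1L)
      malformed(sprintf("%s rule '%s' must have a single alternate", what, r$head))
    r$alternates[[1]]$symbols
  }
  decode_payload <- function(syms) {
    out <- character()
    i <- 1L
    while (i <= length(syms)) {
      tok <- syms[i]
      if (grepl("^Unquote.", tok)) {
        ref <- unquote_referent(tok)
        if (i == length(syms)) malformed(sprintf("orphan unquote '%s'", tok))
        nxt <- syms[i + 1L]
        if (nxt %in% heads) {
          intercepts[[ref]] <<- list(type = "grammar",
                                     plan = decode_full(subgrammar(d, nxt)))
        } else if (!grepl("^Quote.", nxt)) {
          intercepts[[ref]] <<- list(type = "terminal", value = nxt)
        } else malformed(sprintf("unquote '%s' not followed by a retarget", tok))
        out <- c(out, ref)
        i <- i + 2L
      } else if (is_weight_quote(tok)) {
        malformed(sprintf("weight literal '%s' out of place", tok))
      } else if (grepl("^Quote.", tok)) {
        out <- c(out, quote_decode(tok)$value)
        i <- i + 1L
      } else malformed(sprintf("unexpected token '%s' in description payload", tok))
    }
    if (length(out) == 0) malformed("empty alternate payload")
    out
  }

  top <- d$rules[[1]]
  tsyms <- the_single(top, "top")
  branch_rules <- if (grepl("^Quote.", tsyms[1])) list(top) else {
    if (!all(tsyms %in% heads)) malformed("top rule must sequence branch nonterminals")
    lapply(tsyms, rule_of)
  }
  out_rules <- lapply(branch_rules, function(br) {
    bs <- the_single(br, "branch")
    if (length(bs) != 2L || !grepl("^Quote.", bs[1]) || is_weight_quote(bs[1]) ||
        !(bs[2] %in% heads))
      malformed(sprintf("branch '%s' must be a quoted head and an alternates part", br$head))
    head_name <- quote_decode(bs[1])$value
    psyms <- the_single(rule_of(bs[2]), "alternates")
    if (all(psyms %in% heads)) {
      alts <- lapply(psyms, function(sh) {
        ss <- the_single(rule_of(sh), "alternate")
        if (!is_weight_quote(ss[1]))
          malformed(sprintf("alternate rule '%s' must start with a weight literal", sh))
        new_alternate(quote_decode(ss[1])$value, decode_payload(ss[-1]))
      })
    } else {
      alts <- list(new_alternate(1, decode_payload(psyms)))
    }
    new_rule(head_name, alts)
  })
  g <- new_grammar(out_rules, d$registry)
  issues <- validate_grammar(g)
  hard <- issues[!grepl("^zero-weight", issues$issue), , drop = FALSE]
  if (nrow(hard) > 0)
    malformed(paste(sprintf("decoded grammar invalid: [rule %d] %s",
                            hard$rule, hard$issue), collapse = "; "))
  list(grammar = g, intercepts = intercepts)
}

#' Decode a describing grammar
#'
#' Inverse of [describe_grammar()]: reconstructs the described grammar
#' exactly, including weights. Unquote retargets present in the description
#' (from [retarget()] or [compose_grammars()]) decode to the original
#' described symbol; the redirection itself is honored by
#' [run_description()].
#'
#' @param d a describing grammar.
#' @return the described grammar.
#' @export
decode_description <- function(d) decode_full(d)$grammar

#' Compile a describing grammar for repeated execution
#'
#' Decodes the description once into an execution plan (described grammar
#' plus interception map) that [run_description()] can reuse across many
#' runs.
#'
#' @param d describing grammar.
#' @export
compile_description <- function(d) {
  compile_plan <- function(plan) {
    plan$grammar <- compile_grammar(plan$grammar)
    plan$intercepts <- lapply(plan$intercepts, function(ic) {
      if (identical(ic$type, "grammar")) ic$plan <- compile_plan(ic$plan)
      ic
    })
    plan
  }
  structure(compile_plan(decode_full(d)), class = "arg_description_plan")
}

run_plan <- function(plan, env, out_buf, max_rule_applications) {
  wenv <- structure(list(
    matches = env$matches,
    consume = env$consume,
    emit = function(name) {
      ic <- plan$intercepts[[name]]
      if (is.null(ic)) {
        env$emit(name); out_buf$push(name)
      } else if (identical(ic$type, "terminal")) {
        env$emit(ic$value); out_buf$push(ic$value)
      } else {
        run_plan(ic$plan, env, out_buf, max_rule_applications)
      }
    },
    snapshot = env$snapshot
  ), class = "arg_env")
  run_grammar(plan$grammar, env = wenv, seed = NULL,
              max_rule_applications = max_rule_applications)
}

#' Execute a describing grammar
#'
#' Replays the described derivation and applies the description's unquote
#' redirections: an intercepted actuator event is substituted by its
#' retargeted terminal, or by a full production of a spliced guest grammar
#' (dynamic composition). With no unquotes, the emitted trace is exactly the
#' described grammar's.
#'
#' @param d describing grammar, or a plan from [compile_description()].
#' @param env environment receiving the final (post-interception) events.
#' @param seed integer seed or `NULL`.
#' @param max_rule_applications budget per (sub)derivation.
#' @return list with `tokens` (final emitted tokens in order), `derivation`
#'   (the described grammar's raw derivation), and `status`.
#' @export
run_description <- function(d, env = env_recorder(), seed = NULL,
                            max_rule_applications = 10000) {
  plan <- if (inherits(d, "arg_description_plan")) d else compile_description(d)
  if (!is.null(seed)) set.seed(seed)
  out_buf <- new_token_buffer()
  der <- run_plan(plan, env, out_buf, max_rule_applications)
  list(tokens = out_buf$tokens(), derivation = der, status = der$status)
}

#' The root grammar
#'
#' The fixed point of description: the grammar that can produce and
#' recognize the linearization of any grammar, including its own. `Symbol`
#' and `Weight` are class sensors matching any symbol token and any weight
#' token respectively.
#'
#' @param readable if `TRUE`, nonterminals are recast with descriptive names
#'   (`Rules`, `Rule`, `Alternates`, ...).
#' @return the eight-rule root grammar.
#' @export
root_grammar <- function(readable = FALSE) {
  g <- parse_grammar(arg_fixtures()[["fig13_root"]])
  if (readable)
    g <- rename_for_readability(g, c(
      A = "Rules", B = "Rule", C = "RulesSequence", D = "Alternates",
      E = "Alternate", F = "AlternatesSequence", G = "Symbols",
      H = "SymbolsSequence"))
  g
}

#' Linearize a grammar into the token stream the root grammar recognizes
#'
#' Per rule in order: the head token; then per alternate: a weight token
#' followed by each symbol token. Weight tokens always contain a decimal
#' point (`1.0`, `.61`), keeping them disjoint from symbol tokens; they are
#' always present, because the root grammar's alternate structure requires a
#' weight before the symbols.
#'
#' @param g grammar.
#' @return character vector of tokens.
#' @export
linearize_grammar <- function(g) {
  unlist(lapply(g$rules, function(r) {
    c(r$head, unlist(lapply(r$alternates, function(a)
      c(fmt_weight_token(a$weight), a$symbols))))
  }))
}

#' Does the root grammar recognize a grammar's description?
#'
#' @param root the root grammar (see [root_grammar()]).
#' @param g any grammar.
#' @param search_budget search budget passed to [recognize()].
#' @return `TRUE` iff the root grammar accepts `linearize_grammar(g)`.
#' @export
recognizes_description <- function(root = root_grammar(), g,
                                   search_budget = 200000) {
  r <- recognize(root, linearize_grammar(g), search_budget = search_budget,
                 first_only = TRUE)
  isTRUE(r$accepted)
}

#' Retarget a grammar's actuators through a describing grammar (metaphor)
#'
#' Builds the describing grammar of `g` in which each mapped actuator
#' description becomes `UnquoteOld New`: executing the result (with
#' [run_description()]) replays `g`'s derivation with the mapping applied to
#' its emissions, while `g` itself is unmodified. This retargets a fixed
#' structural pattern from one terminal domain to another -- counting circles
#' instead of squares -- without duplicating the circuit.
#'
#' @param g grammar.
#' @param mapping named character vector `old_actuator = "new_actuator"`.
#' @param precision weight-literal precision, see [describe_grammar()].
#' @return the retargeting describing grammar.
#' @export
retarget <- function(g, mapping, precision = 2) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  terms <- grammar_terminals(g)
  for (old in names(mapping)) {
    if (!(old %in% terms)) stop("cannot retarget undefined terminal: ", old)
    if (!identical(symbol_kind(old, g), "actuator"))
      stop("cannot retarget non-actuator terminal: ", old)
  }
  d <- describe_grammar(g, precision)
  d$rules <- lapply(d$rules, function(r) {
    r$alternates <- lapply(r$alternates, function(a) {
      out <- character()
      for (s in a$symbols) {
        ref <- if (grepl("^Quote.", s) && !is_weight_quote(s))
          quote_decode(s)$value else NA_character_
        if (!is.na(ref) && ref %in% names(mapping))
          out <- c(out, paste0("Unquote", ref), unname(mapping[[ref]]))
        else out <- c(out, s)
      }
      a$symbols <- out
      a
    })
    r
  })
  d
}

#' Compose two grammars dynamically through a describing grammar
#'
#' Returns a describing grammar whose execution behaves as `host` with every
#' `hook` event replaced by a full production of `guest`. Host and guest are
#' not modified and remain independently executable: the combination lives
#' entirely in the description, so the two circuits can be recombined in any
#' number of ways without accruing merged copies.
#'
#' @param host grammar providing the overall pattern.
#' @param hook a terminal of `host` whose events trigger the guest.
#' @param guest grammar produced at each hook event.
#' @param precision weight-literal precision.
#' @return the composing describing grammar; run it with
#'   [run_description()].
#' @export
compose_grammars <- function(host, hook, guest, precision = 2) {
  if (!(hook %in% grammar_terminals(host)))
    stop("hook '", hook, "' is not a terminal of the host grammar")
  d <- describe_grammar(host, precision)
  gd <- describe_grammar(guest, precision)
  alloc <- fresh_allocator(avoid = grammar_heads(d))
  gheads <- grammar_heads(gd)
  remap <- vapply(gheads, function(h) alloc(), character(1))
  gd <- rename_for_readability(gd, remap)
  guest_top <- unname(remap[gheads[1]])
  qh <- quote_symbol(hook)
  d$rules <- lapply(d$rules, function(r) {
    r$alternates <- lapply(r$alternates, function(a) {
      out <- character()
      for (s in a$symbols) {
        if (identical(s, qh)) out <- c(out, paste0("Unquote", hook), guest_top)
        else out <- c(out, s)
      }
      a$symbols <- out
      a
    })
    r
  })
  new_grammar(c(d$rules, gd$rules), d$registry)
}
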