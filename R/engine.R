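# ---------------------------------------------------------------------------
# Environments bind terminal names to channels. The contract is three
# closures: matches(name) peeks (side-effect free), consume(name) commits a
# successful match, emit(name) performs an actuator effect. snapshot()
# returns an opaque view of the state.
# ---------------------------------------------------------------------------

match_token <- function(sensor, token) {
  if (sensor == "Symbol") return(!is_weight_token(token))
  if (sensor == "Weight") return(is_weight_token(token))
  identical(sensor, token)
}

new_token_buffer <- function(init = 64L) {
  buf <- character(init); n <- 0L
  list(
    push = function(tok) {
      if (n == length(buf)) buf[2L * length(buf)] <<- NA_character_
      n <<- n + 1L; buf[n] <<- tok
    },
    count = function() n,
    tokens = function() buf[seq_len(n)]
  )
}

#' Recorder environment
#'
#' Pure production: actuator emissions are recorded in order; there is no
#' input, so every sensor fails to match.
#'
#' @return an environment object; emitted tokens are available through
#'   `$snapshot()$emitted`.
#' @export
env_recorder <- function() {
  out <- new_token_buffer()
  structure(list(
    matches = function(name) FALSE,
    consume = function(name) stop("recorder environment has no input"),
    emit = function(name) out$push(name),
    count = out$count,
    snapshot = function() list(emitted = out$tokens(), n_emitted = out$count())
  ), class = c("arg_env_recorder", "arg_env"))
}

#' Token-stream environment
#'
#' Recognition (and mixed-mode) input: sensors match against the next
#' unconsumed token and consume it on match; actuator emissions are recorded.
#' The class sensors `Symbol` and `Weight` match any symbol token or any
#' weight token respectively.
#'
#' @param tokens character vector of input tokens.
#' @export
env_stream <- function(tokens) {
  stopifnot(is.character(tokens))
  pos <- 1L; n <- length(tokens)
  out <- new_token_buffer()
  structure(list(
    matches = function(name) pos <= n && match_token(name, tokens[pos]),
    consume = function(name) pos <<- pos + 1L,
    emit = function(name) out$push(name),
    count = out$count,
    snapshot = function() list(emitted = out$tokens(), consumed = pos - 1L,
                               remaining = n - pos + 1L)
  ), class = c("arg_env_stream", "arg_env"))
}

#' Turing-tape environment
#'
#' A bidirectional tape of symbols with a read/write head, held as a sparse
#' map (absent cell = blank). Actuators: `Pe`, `P0`, `P1`, `Px` overwrite the
#' scanned cell, `R`/`L` move the head, `E` blanks the scanned cell. Sensors
#' `0`, `1`, `x`, `e` match the scanned cell; `None` matches blank. Reading
#' never modifies the tape.
#'
#' @param record_history if `TRUE`, a snapshot of the whole tape is kept
#'   after every actuator operation (used to compare runs step-for-step
#'   against a reference machine).
#' @export
env_tape <- function(record_history = FALSE) {
  cells <- new.env(parent = emptyenv())
  head <- 0L
  hist <- if (record_history) list() else NULL
  cell_at <- function(p) {
    v <- cells[[as.character(p)]]
    if (is.null(v)) NA_character_ else v
  }
  tape_view <- function() {
    keys <- ls(cells)
    if (length(keys) == 0) return(character())
    posn <- as.integer(keys)
    v <- vapply(keys, function(k) cells[[k]], character(1))
    names(v) <- keys
    v[order(posn)]
  }
  structure(list(
    matches = function(name) {
      cur <- cell_at(head)
      if (name == "None") is.na(cur) else identical(cur, name)
    },
    consume = function(name) invisible(NULL), # tape reads are non-destructive
    emit = function(name) {
      switch(name,
        Pe = assign(as.character(head), "e", envir = cells),
        P0 = assign(as.character(head), "0", envir = cells),
        P1 = assign(as.character(head), "1", envir = cells),
        Px = assign(as.character(head), "x", envir = cells),
        R = { head <<- head + 1L },
        L = { head <<- head - 1L },
        E = if (exists(as.character(head), envir = cells))
              rm(list = as.character(head), envir = cells),
        stop("unknown tape actuator: ", name)
      )
      if (record_history)
        hist[[length(hist) + 1L]] <<- list(op = name, cells = tape_view(), head = head)
    },
    snapshot = function() list(cells = tape_view(), head = head, history = hist)
  ), class = c("arg_env_tape", "arg_env"))
}

# ---------------------------------------------------------------------------
# Production / mixed-mode engine
# ---------------------------------------------------------------------------

# Leading sensors reachable from an alternate's first symbol, with one level
# of nonterminal indirection (so a rule like "Any = 0 | 1." gates as the
# sensor set {0, 1}). NULL when the alternate is not sensor-led.
leading_sensors <- function(g, alt, kinds, rule_index) {
  s1 <- alt$symbols[1]
  k <- kinds[[s1]]
  if (identical(k, "sensor")) return(s1)
  if (identical(k, "nonterminal")) {
    sub <- g$rules[[rule_index[[s1]]]]
    firsts <- vapply(sub$alternates, function(a) a$symbols[1], character(1))
    fk <- unlist(kinds[firsts])
    if (length(fk) > 0 && all(fk == "sensor")) return(firsts)
  }
  NULL
}

# data.frame without the construction overhead; columns are same-length
quick_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}

prep_exec <- function(g) {
  heads <- grammar_heads(g)
  rule_index <- as.list(seq_along(heads)); names(rule_index) <- heads
  all_syms <- unique(c(heads, grammar_terminals(g)))
  kinds <- as.list(symbol_kind(all_syms, g)); names(kinds) <- all_syms
  rules_exec <- lapply(g$rules, function(r) {
    leads <- lapply(r$alternates, leading_sensors, g = g, kinds = kinds,
                    rule_index = rule_index)
    list(alternates = lapply(r$alternates, function(a)
           list(weight = a$weight, rev_symbols = rev(a$symbols))),
         w = vapply(r$alternates, function(a) a$weight, numeric(1)),
         leads = leads,
         gated = any(!vapply(leads, is.null, logical(1))))
  })
  names(rules_exec) <- heads
  list(heads = heads, kinds = kinds, rules_exec = rules_exec)
}

#' Precompile a grammar for repeated execution
#'
#' Attaches the execution tables (symbol classification, per-rule gating
#' information) to the grammar so repeated [run_grammar()] calls skip the
#' per-call setup. Purely an optimization: results are identical.
#'
#' @param g grammar.
#' @return the same grammar carrying its execution tables.
#' @export
compile_grammar <- function(g) {
  stopifnot(inherits(g, "arg_grammar"))
  attr(g, "arg_exec") <- prep_exec(g)
  g
}

#' Execute a grammar against an environment
#'
#' Depth-first left-to-right expansion from the start symbol (head of the
#' first rule). At each rule, alternate selection is sensor-gated when one or
#' more alternates begin with a reachable sensor: alternates whose leading
#' sensor matches the environment are kept (alternates that are not
#' sensor-led stay viable) and one is sampled among them by renormalized
#' weights. Otherwise selection samples the rule's weights directly. Actuator
#' terminals emit to the environment, sensor terminals match and consume, and
#' quoted/unquoted terminals emit their own token (they are inert data unless
#' interpreted by a description runner, see [run_description()]).
#'
#' Non-termination is a legal outcome: a grammar like `A = DrawSquare A.`
#' runs until the rule-application budget is exhausted, which is reported on
#' the trace (`status = "exhausted"`), not an error. A sensor mismatch with
#' no viable alternate is a recognition failure (`status = "failed"`),
#' distinct from budget exhaustion.
#'
#' @param g grammar.
#' @param env environment object ([env_recorder()], [env_stream()],
#'   [env_tape()]).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param max_rule_applications budget on rule applications (default 10000).
#' @param stop_when optional predicate on `env` checked between steps; when
#'   it returns `TRUE` the run stops with `status = "stopped"`.
#' @return a derivation: list with `events` (data frame `terminal`,
#'   `direction`, `depth`, `seq`), `choices` (data frame `head`,
#'   `alternate`), `loglik` (sum of log weights of chosen alternates),
#'   `status` (`"complete"`, `"exhausted"`, `"failed"`, `"stopped"`), and
#'   `rule_applications`.
#' @export
run_grammar <- function(g, env = env_recorder(), seed = NULL,
                        max_rule_applications = 10000, stop_when = NULL) {
  stopifnot(inherits(g, "arg_grammar"), max_rule_applications > 0)
  if (!is.null(seed)) set.seed(seed)
  exec <- attr(g, "arg_exec")
  if (is.null(exec)) exec <- prep_exec(g)
  heads <- exec$heads
  kinds <- exec$kinds
  rules_exec <- exec$rules_exec

  # explicit stacks (symbol, depth) to keep deep tail recursion flat
  cap <- 256L
  st_sym <- character(cap); st_dep <- integer(cap); top <- 0L
  push <- function(sym, dep) {
    while (top + length(sym) > length(st_sym)) {
      st_sym[2L * length(st_sym)] <<- NA_character_
      st_dep[2L * length(st_dep)] <<- NA_integer_
    }
    idx <- top + seq_along(sym)
    st_sym[idx] <<- sym; st_dep[idx] <<- dep
    top <<- top + length(sym)
  }
  ev_t <- character(64L); ev_d <- character(64L); ev_depth <- integer(64L); n_ev <- 0L
  ch_h <- character(64L); ch_a <- integer(64L); n_ch <- 0L
  add_event <- function(term, dir, dep) {
    if (n_ev == length(ev_t)) {
      ev_t[2L * length(ev_t)] <<- NA_character_
      ev_d[2L * length(ev_d)] <<- NA_character_
      ev_depth[2L * length(ev_depth)] <<- NA_integer_
    }
    n_ev <<- n_ev + 1L
    ev_t[n_ev] <<- term; ev_d[n_ev] <<- dir; ev_depth[n_ev] <<- dep
  }

  push(heads[1], 0L)
  loglik <- 0; apps <- 0L; status <- "complete"
  while (top > 0L) {
    if (!is.null(stop_when) && isTRUE(stop_when(env))) { status <- "stopped"; break }
    sym <- st_sym[top]; dep <- st_dep[top]; top <- top - 1L
    k <- kinds[[sym]]
    if (identical(k, "nonterminal")) {
      if (apps >= max_rule_applications) { status <- "exhausted"; break }
      apps <- apps + 1L
      rx <- rules_exec[[sym]]
      alts <- rx$alternates
      nalt <- length(alts)
      if (!rx$gated) {
        idx <- if (nalt == 1L) 1L else sample.int(nalt, 1L, prob = rx$w)
      } else {
        viable <- vapply(seq_len(nalt), function(j) {
          if (is.null(rx$leads[[j]])) TRUE
          else any(vapply(rx$leads[[j]], env$matches, logical(1)))
        }, logical(1))
        if (!any(viable)) { status <- "failed"; break }
        vi <- which(viable)
        idx <- if (length(vi) == 1L) vi else {
          w <- rx$w[vi]
          if (sum(w) <= 0) { status <- "failed"; break }
          vi[sample.int(length(vi), 1L, prob = w)]
        }
      }
      if (n_ch == length(ch_h)) {
        ch_h[2L * length(ch_h)] <- NA_character_
        ch_a[2L * length(ch_a)] <- NA_integer_
      }
      n_ch <- n_ch + 1L; ch_h[n_ch] <- sym; ch_a[n_ch] <- idx
      loglik <- loglik + log(alts[[idx]]$weight)
      push(alts[[idx]]$rev_symbols, dep + 1L)
    } else if (identical(k, "sensor")) {
      if (env$matches(sym)) {
        env$consume(sym)
        add_event(sym, "sensor", dep)
      } else { status <- "failed"; break }
    } else if (identical(k, "actuator") || identical(k, "quoted") ||
               identical(k, "unquoted")) {
      env$emit(sym)
      add_event(sym, "actuator", dep)
    } else stop("unclassifiable symbol in execution: ", sym)
  }
  structure(list(
    events = quick_df(list(terminal = ev_t[seq_len(n_ev)],
                           direction = ev_d[seq_len(n_ev)],
                           depth = ev_depth[seq_len(n_ev)],
                           seq = seq_len(n_ev))),
    choices = quick_df(list(head = ch_h[seq_len(n_ch)],
                            alternate = ch_a[seq_len(n_ch)])),
    loglik = loglik, status = status, rule_applications = apps
  ), class = "arg_derivation")
}

#' @export
print.arg_derivation <- function(x, ...) {
  cat(sprintf("<derivation> %d event(s), %d rule application(s), status %s, loglik %.4f\n",
              nrow(x$events), x$rule_applications, x$status, x$loglik))
  if (nrow(x$events) > 0) print(utils::head(x$events, 20))
  invisible(x)
}

#' Partial order over derivation events
#'
#' Sequencing in rule text does not convey order; the number of rule
#' applications does. Event `e1` precedes `e2` iff `depth(e1) < depth(e2)`;
#' at equal depth a sensor (recognition) event precedes an actuator
#' (production) event; remaining pairs are unordered.
#'
#' @param d derivation from [run_grammar()].
#' @return data frame of ordered pairs (`before`, `after`), as `seq` indices.
#' @export
event_order <- function(d) {
  ev <- d$events
  n <- nrow(ev)
  pairs <- list()
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      prec <- ev$depth[i] < ev$depth[j] ||
        (ev$depth[i] == ev$depth[j] &&
           ev$direction[i] == "sensor" && ev$direction[j] == "actuator")
      if (prec) pairs[[length(pairs) + 1L]] <- c(ev$seq[i], ev$seq[j])
    }
  }
  if (length(pairs) == 0)
    return(data.frame(before = integer(), after = integer()))
  m <- do.call(rbind, pairs)
  data.frame(before = m[, 1], after = m[, 2])
}

# ---------------------------------------------------------------------------
# Recognition by bounded backtracking search
# ---------------------------------------------------------------------------

#' Recognize a token sequence
#'
#' Backtracking derivation search: the input is accepted iff some derivation
#' consumes it entirely with every sensor matched. The reported
#' log-likelihood is the log of the summed probability of all accepting
#' derivations found within the search budget (a lower bound for grammars
#' ambiguous beyond the budget). Actuator terminals encountered during the
#' search emit nothing and consume nothing.
#'
#' @param g grammar.
#' @param input character vector of tokens; each must be matchable by some
#'   sensor of the grammar.
#' @param search_budget maximum number of search-node expansions.
#' @param first_only stop at the first accepting derivation (acceptance
#'   check only; the log-likelihood then reflects that single derivation).
#' @return list with `accepted` (`TRUE`, `FALSE`, or `NA` when the budget ran
#'   out before any decision), `loglik`, `consumed`, and `exhausted`.
#' @export
recognize <- function(g, input, search_budget = 100000, first_only = FALSE) {
  stopifnot(inherits(g, "arg_grammar"), is.character(input))
  n <- length(input)
  heads <- grammar_heads(g)
  rule_index <- as.list(seq_along(heads)); names(rule_index) <- heads
  all_syms <- unique(c(heads, grammar_terminals(g)))
  kinds <- as.list(symbol_kind(all_syms, g)); names(kinds) <- all_syms
  path_cap <- 10L * n + 100L

  # lower bound on the number of input tokens a symbol must consume; grammars
  # have no null symbol, so iterating the min-over-alternates relaxation from
  # zero yields a sound (under-)estimate used to prune hopeless branches
  yield <- stats::setNames(numeric(length(all_syms)), all_syms)
  for (s in all_syms) if (identical(kinds[[s]], "sensor")) yield[s] <- 1
  for (iter in seq_len(length(heads) + 2L)) {
    for (h in heads) {
      alts <- g$rules[[rule_index[[h]]]]$alternates
      yield[h] <- min(vapply(alts, function(a) sum(yield[a$symbols]), numeric(1)))
    }
  }

  ctr <- new.env(parent = emptyenv())
  ctr$budget <- search_budget; ctr$prob <- 0; ctr$found <- FALSE
  ctr$exhausted <- FALSE; ctr$max_pos <- 0L

  search <- function(agenda, pos, logp, apps, need) {
    if (ctr$found && first_only) return(invisible(NULL))
    if (need > n - pos + 1L) return(invisible(NULL)) # cannot fit in the input
    if (ctr$budget <= 0L) { ctr$exhausted <- TRUE; return(invisible(NULL)) }
    ctr$budget <- ctr$budget - 1L
    if (pos - 1L > ctr$max_pos) ctr$max_pos <- pos - 1L
    if (is.null(agenda)) {
      if (pos > n) { ctr$prob <- ctr$prob + exp(logp); ctr$found <- TRUE }
      return(invisible(NULL))
    }
    sym <- agenda$sym
    k <- kinds[[sym]]
    if (identical(k, "nonterminal")) {
      if (apps >= path_cap) return(invisible(NULL))
      for (a in g$rules[[rule_index[[sym]]]]$alternates) {
        if (a$weight <= 0) next
        rest <- agenda$rest
        for (s in rev(a$symbols)) rest <- list(sym = s, rest = rest)
        search(rest, pos, logp + log(a$weight), apps + 1L,
               need - yield[[sym]] + sum(yield[a$symbols]))
        if (ctr$found && first_only) return(invisible(NULL))
      }
    } else if (identical(k, "sensor")) {
      if (pos <= n && match_token(sym, input[pos]))
        search(agenda$rest, pos + 1L, logp, apps, need - 1)
    } else {
      # actuators/quotes are silent here
      search(agenda$rest, pos, logp, apps, need - yield[[sym]])
    }
    invisible(NULL)
  }
  search(list(sym = heads[1], rest = NULL), 1L, 0, 0L, yield[[heads[1]]])
  accepted <- if (ctr$found) TRUE else if (ctr$exhausted) NA else FALSE
  list(accepted = accepted,
       loglik = if (ctr$prob > 0) log(ctr$prob) else -Inf,
       consumed = if (isTRUE(accepted)) n else ctr$max_pos,
       exhausted = ctr$exhausted)
}

# ---------------------------------------------------------------------------
# Turing-tape runner
# ---------------------------------------------------------------------------

#' Run a grammar as a Turing machine on a blank tape
#'
#' Executes the mixed activation/recognition engine against a Turing-tape
#' environment, head at position 0, with fully sensor-gated (hence
#' deterministic) control. The run stops once the tape holds `figure_target`
#' cells containing binary figures (`0` or `1`), or when the rule-application
#' budget is exhausted, in which case the partial tape is returned flagged
#' incomplete.
#'
#' @param g grammar over tape actuators `Pe, P0, P1, Px, R, L, E` and tape
#'   sensors `0, 1, x, e, None`.
#' @param figure_target number of binary figures that must exist on the tape
#'   before stopping (>= 1).
#' @param cap rule-application budget.
#' @param record_history keep a full tape snapshot per actuator operation.
#' @return a tape state: list with `cells` (named character vector, names are
#'   integer positions), `head`, `complete`, `history` (or `NULL`), and the
#'   underlying `derivation`.
#' @export
run_turing <- function(g, figure_target, cap = 200000, record_history = FALSE) {
  stopifnot(figure_target >= 1)
  env <- env_tape(record_history = record_history)
  count_figures <- function(env) {
    cells <- env$snapshot()$cells
    sum(cells %in% c("0", "1")) >= figure_target
  }
  d <- run_grammar(g, env = env, seed = NULL, max_rule_applications = cap,
                   stop_when = count_figures)
  snap <- env$snapshot()
  structure(list(cells = snap$cells, head = snap$head,
                 complete = identical(d$status, "stopped"),
                 history = snap$history, derivation = d),
            class = "arg_tape")
}

#' @export
print.arg_tape <- function(x, ...) {
  cat(sprintf("<tape> %d non-blank cell(s), head at %d, %s\n",
              length(x$cells), x$head,
              if (x$complete) "complete" else "incomplete"))
  if (length(x$cells) > 0)
    cat(paste0(names(x$cells), ":", x$cells, collapse = " "), "\n")
  invisible(x)
}

#' Read binary figures off a tape
#'
#' Concatenates, in increasing position order, the cells whose symbol is `0`
#' or `1`, truncated to the first `n`.
#'
#' @param t tape state from [run_turing()].
#' @param n number of figures requested; an error if fewer are available.
#' @return a digit string.
#' @export
read_figures <- function(t, n) {
  stopifnot(inherits(t, "arg_tape"), n >= 0)
  figs <- t$cells[t$cells %in% c("0", "1")]
  if (length(figs) < n)
    stop(sprintf("tape holds %d figure(s), %d requested", length(figs), n))
  paste(figs[seq_len(n)], collapse = "")
}
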