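# ---------------------------------------------------------------------------
# Swarm learning: a single grammar whose top-level alternates instantiate the
# same template at different probability vectors. Presented with a sample,
# the branch closest to the generating distribution -- formalized as maximum
# average log-likelihood, i.e. minimum cross-entropy -- recognizes it.
# ---------------------------------------------------------------------------

designated_rule_index <- function(g, rule = NULL) {
  heads <- grammar_heads(g)
  if (!is.null(rule)) {
    i <- match(rule, heads)
    if (is.na(i)) stop("no rule with head '", rule, "'")
    return(i)
  }
  multi <- which(vapply(g$rules, function(r) length(r$alternates) > 1L, logical(1)))
  if (length(multi) == 0) 1L else multi[1]
}

# The unique terminal an alternate resolves to, following unit nonterminal
# chains (e.g. ".5 E" with "E = SpotGreenPoint." resolves to SpotGreenPoint).
resolve_terminal <- function(g, alt) {
  heads <- grammar_heads(g)
  syms <- alt$symbols
  guard <- 0L
  while (TRUE) {
    if (length(syms) != 1L)
      stop("alternate does not resolve to a single terminal: ",
           paste(alt$symbols, collapse = " "))
    s <- syms[1]
    if (!(s %in% heads)) return(s)
    r <- g$rules[[match(s, heads)]]
    if (length(r$alternates) != 1L)
      stop("alternate resolves through a branching rule; terminal is ambiguous")
    syms <- r$alternates[[1]]$symbols
    guard <- guard + 1L
    if (guard > length(g$rules)) stop("cyclic unit chain while resolving terminal")
  }
}

# Terminal distribution of a grammar's designated rule: named weights.
terminal_distribution <- function(g, rule = NULL) {
  r <- g$rules[[designated_rule_index(g, rule)]]
  terms <- vapply(r$alternates, function(a) resolve_terminal(g, a), character(1))
  w <- vapply(r$alternates, function(a) a$weight, numeric(1))
  tapply(w, terms, sum)[unique(terms)]
}

#' Specify a grammar swarm
#'
#' A swarm is one template grammar with a designated weighted rule,
#' replicated over a grid of probability vectors, one per branch.
#'
#' @param template grammar; its designated rule's alternates carry the
#'   probabilities that vary across the swarm.
#' @param grid list of probability vectors, each of the designated rule's
#'   arity and summing to 1.
#' @param labels branch identifiers; defaults to the grid vectors printed as
#'   `"p1/p2/..."`.
#' @param rule head of the designated rule; defaults to the first rule with
#'   more than one alternate.
#' @export
swarm_spec <- function(template, grid, labels = NULL, rule = NULL) {
  stopifnot(inherits(template, "arg_grammar"), is.list(grid), length(grid) >= 1)
  i <- designated_rule_index(template, rule)
  arity <- length(template$rules[[i]]$alternates)
  for (v in grid) {
    if (length(v) != arity)
      stop(sprintf("grid vector of length %d does not match rule arity %d",
                   length(v), arity))
    if (abs(sum(v) - 1) > 1e-6) stop("grid vector does not sum to 1")
    if (any(v < 0)) stop("grid vector has negative entries")
  }
  if (is.null(labels))
    labels <- vapply(grid, function(v) paste(fmt_weight(v), collapse = "/"),
                     character(1))
  stopifnot(length(labels) == length(grid))
  structure(list(template = template, rule = grammar_heads(template)[i],
                 grid = grid, labels = labels),
            class = "arg_swarm_spec")
}

set_rule_weights <- function(g, rule, w) {
  i <- designated_rule_index(g, rule)
  g$rules[[i]]$alternates <- Map(function(a, wi) { a$weight <- wi; a },
                                 g$rules[[i]]$alternates, w)
  g
}

# Template instantiated at one grid vector, nonterminals renamed via alloc().
instantiate_branch <- function(s, v, alloc = NULL) {
  g <- set_rule_weights(s$template, s$rule, v)
  if (is.null(alloc)) return(g)
  heads <- grammar_heads(g)
  remap <- vapply(heads, function(h) alloc(), character(1))
  rename_for_readability(g, remap)
}

#' Expand a swarm specification into a single grammar
#'
#' The expanded grammar's top rule has one equiprobable alternate per
#' branch, each branch instantiating the template with its grid vector under
#' fresh nonterminal names. A single-branch swarm is the template itself
#' (with its grid vector installed).
#'
#' @param s swarm specification from [swarm_spec()].
#' @return a grammar; `attr(, "branches")` maps branch labels to the head
#'   nonterminal of each instantiated branch.
#' @export
expand_swarm <- function(s) {
  stopifnot(inherits(s, "arg_swarm_spec"))
  k <- length(s$grid)
  if (k == 1L) {
    out <- set_rule_weights(s$template, s$rule, s$grid[[1]])
    attr(out, "branches") <- data.frame(label = s$labels,
                                        head = grammar_heads(out)[1],
                                        stringsAsFactors = FALSE)
    return(out)
  }
  alloc <- fresh_allocator()
  top <- alloc()
  branch_tops <- vapply(seq_len(k), function(b) alloc(), character(1))
  branch_rules <- list()
  for (b in seq_len(k)) {
    inst <- set_rule_weights(s$template, s$rule, s$grid[[b]])
    heads <- grammar_heads(inst)
    remap <- c(stats::setNames(branch_tops[b], heads[1]),
               if (length(heads) > 1)
                 vapply(heads[-1], function(h) alloc(), character(1)))
    inst <- rename_for_readability(inst, remap)
    branch_rules <- c(branch_rules, inst$rules)
  }
  top_rule <- new_rule(top, lapply(branch_tops, function(h)
    new_alternate(1 / k, h)))
  out <- new_grammar(c(list(top_rule), branch_rules), s$template$registry)
  attr(out, "branches") <- data.frame(label = s$labels, head = branch_tops,
                                      stringsAsFactors = FALSE)
  out
}

#' Average per-token log-likelihood of a sample under a branch
#'
#' The branch's designated rule induces a distribution over its resolved
#' terminals; the score is the mean log-probability of the sample's tokens
#' under that distribution. A token outside the branch's terminal support
#' scores `-Inf`.
#'
#' @param branch a (color) grammar.
#' @param sample character vector of tokens.
#' @param rule optional head of the designated rule.
#' @export
branch_loglik <- function(branch, sample, rule = NULL) {
  stopifnot(length(sample) >= 1)
  p <- terminal_distribution(branch, rule)
  lp <- log(p[sample])
  lp[is.na(lp)] <- -Inf
  mean(lp)
}

#' Select the swarm branch closest to a sample
#'
#' Arg-max of [branch_loglik()] over the swarm's branches (equivalently, the
#' branch of minimum cross-entropy to the sample's empirical distribution).
#' Ties break deterministically toward the lowest branch index.
#'
#' @param swarm swarm specification.
#' @param sample non-empty token vector.
#' @return the selected branch's label; `attr(, "loglik")` carries all
#'   branch scores and `attr(, "index")` the selected index.
#' @export
select_branch <- function(swarm, sample) {
  stopifnot(inherits(swarm, "arg_swarm_spec"), length(sample) >= 1)
  ll <- vapply(swarm$grid, function(v) {
    branch_loglik(set_rule_weights(swarm$template, swarm$rule, v), sample,
                  rule = swarm$rule)
  }, numeric(1))
  if (all(!is.finite(ll))) stop("sample has no support under any branch")
  i <- which.max(ll) # which.max takes the first maximum: lowest-index tie-break
  structure(swarm$labels[i], loglik = stats::setNames(ll, swarm$labels), index = i)
}

#' Maximum-likelihood weight recovery
#'
#' Replaces the designated rule's weights by the relative frequencies of the
#' sample tokens matching each alternate's resolved terminal: the closed-form
#' multinomial MLE.
#'
#' @param skeleton grammar whose designated rule's alternates resolve to
#'   distinct terminals.
#' @param sample non-empty token vector; every token must match one of those
#'   terminals.
#' @param rule optional head of the designated rule.
#' @return the skeleton with estimated weights installed.
#' @export
estimate_weights <- function(skeleton, sample, rule = NULL) {
  if (length(sample) == 0) stop("cannot estimate weights from an empty sample")
  i <- designated_rule_index(skeleton, rule)
  r <- skeleton$rules[[i]]
  terms <- vapply(r$alternates, function(a) resolve_terminal(skeleton, a),
                  character(1))
  if (anyDuplicated(terms) > 0)
    stop("designated rule alternates must resolve to distinct terminals")
  unknown <- setdiff(unique(sample), terms)
  if (length(unknown) > 0)
    stop("sample token(s) outside the skeleton's terminals: ",
         paste(unknown, collapse = ", "))
  counts <- vapply(terms, function(t) sum(sample == t), numeric(1))
  set_rule_weights(skeleton, r$head, counts / length(sample))
}

has_quotes <- function(g) {
  any(grepl("^Quote|^Unquote", grammar_terminals(g)))
}

#' One step of the reinforcement loop
#'
#' The closure grammar follows the recognition-plus-description shape: its
#' top rule sequences a recognition branch (weighted sensors) and the
#' description of a target producer. If, within the swarm context, the
#' sample selects the closure's own recognition branch, the described
#' producer is decoded and executed, returning its emitted tokens as the
#' expected color presented back for reinforcement; otherwise the result is
#' empty.
#'
#' @param closure grammar of the stated shape.
#' @param sample non-empty token vector presented to the swarm.
#' @param seed integer seed for the producer runs, or `NULL`.
#' @param swarm swarm context the closure's branch competes in; defaults to
#'   the three-branch color grid (.5/.5, the closure's own vector, .9/.1).
#' @param n_produce number of producer executions (one emitted token each
#'   for the color producers); defaults to `length(sample)`.
#' @return character vector of produced tokens (empty when not triggered).
#' @export
reinforcement_step <- function(closure, sample, seed = NULL, swarm = NULL,
                               n_produce = length(sample)) {
  stopifnot(inherits(closure, "arg_grammar"), length(sample) >= 1)
  top <- closure$rules[[1]]
  if (length(top$alternates) != 1L || length(top$alternates[[1]]$symbols) != 2L)
    stop("malformed closure grammar: top rule must sequence a recognition ",
         "branch and a description")
  parts <- lapply(top$alternates[[1]]$symbols, function(h) subgrammar(closure, h))
  is_desc <- vapply(parts, has_quotes, logical(1))
  if (sum(is_desc) != 1L)
    stop("malformed closure grammar: exactly one part must be a description")
  recog <- parts[[which(!is_desc)]]
  desc <- parts[[which(is_desc)]]
  p_rec <- terminal_distribution(recog)
  if (is.null(swarm)) {
    if (length(p_rec) != 2L)
      stop("default swarm context requires a two-terminal recognition branch")
    swarm <- swarm_spec(recog, list(c(.5, .5), as.numeric(p_rec), c(.9, .1)))
  }
  sel <- select_branch(swarm, sample)
  chosen <- swarm$grid[[attr(sel, "index")]]
  triggered <- length(chosen) == length(p_rec) &&
    max(abs(chosen - as.numeric(p_rec))) < 1e-9
  if (!triggered) return(character())
  producer <- compile_grammar(decode_description(desc))
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(seq_len(n_produce), function(i) {
    d <- run_grammar(producer)
    d$events$terminal[d$events$direction == "actuator"]
  }))
}

#' Sample color tokens from a green/red mixture
#'
#' Generates a token sample by executing the looping two-color mixture
#' grammar (`A = B A. B = p C | (1-p) D.`) with the requested vocabulary
#' bound as actuators, cutting the infinite production at `n` emissions.
#' This is the package's stand-in for "presenting a color": a color is a
#' stream of green/red point events in the stated proportion.
#'
#' @param n number of tokens.
#' @param p_green probability of a green point (default .61, the orange
#'   mixture).
#' @param seed integer seed or `NULL`.
#' @param vocabulary two terminal names, green then red.
#' @return character vector of `n` tokens.
#' @export
sample_color_tokens <- function(n, p_green = 0.61, seed = NULL,
                                vocabulary = c("SpotGreenPoint", "SpotRedPoint")) {
  stopifnot(n >= 1, length(vocabulary) == 2, p_green >= 0, p_green <= 1)
  reg <- arg_registry(stats::setNames(c("actuator", "actuator"), vocabulary))
  g <- new_grammar(list(
    new_rule("A", list(new_alternate(1, c("B", "A")))),
    new_rule("B", list(new_alternate(p_green, "C"),
                       new_alternate(1 - p_green, "D"))),
    new_rule("C", list(new_alternate(1, vocabulary[1]))),
    new_rule("D", list(new_alternate(1, vocabulary[2])))
  ), reg)
  if (!is.null(seed)) set.seed(seed)
  d <- run_grammar(g, env = env_recorder(),
                   max_rule_applications = 4L * n + 16L,
                   stop_when = function(env) env$count() >= n)
  toks <- d$events$terminal[d$events$direction == "actuator"]
  toks[seq_len(n)]
}
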