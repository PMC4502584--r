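# ---------------------------------------------------------------------------
# The complete set of worked example grammars, keyed by the figure each
# illustrates, as plain notation text. These are the package's reference
# inputs: every fixture parses clean and validates under the default
# registry (the digit grammars additionally run in production under a
# registry override binding 0/1 as actuators).
# ---------------------------------------------------------------------------

#' Example grammar fixtures
#'
#' Named list of grammar texts covering the full worked-example set: the
#' three-shape production/recognition/mixed trio, ordering variants, the
#' look-see-describe action grammar, weighted and equipartition grammars,
#' the two recursive loops, the Turing-machine transliteration, the digit
#' grammars, the color family (yellow/orange/gold), simple and probabilistic
#' describing grammars, the three-branch color swarm, the reinforcement
#' closure, the root grammar, the square-counting metaphor pair, and the
#' digit-orange composition set.
#'
#' @return named list of single-string grammar texts.
#' @export
arg_fixtures <- function() {
  list(
    fig1_draw = "A = B C D. B = DrawSquare. C = DrawCircle. D = DrawTriangle.",
    fig1_spot = "A = B C D. B = SpotSquare. C = SpotCircle. D = SpotTriangle.",
    fig1_mix = "A = B C D. B = DrawSquare. C = SpotCircle. D = DrawTriangle.",
    fig2_a = "A = B C. B = DrawSquare. C = DrawCircle.",
    fig2_b = "A = B C. B = DrawCircle. C = DrawSquare.",
    fig2_c = "A = B C. B = DrawSquare. C = D. D = DrawCircle.",
    fig2_d = "A = B C. B = D. D = DrawSquare. C = DrawCircle.",
    fig3_look = "A = Look B. B = See C. C = Describe.",
    fig4_a = "A = .3 B | .7 C. B = DrawSquare. C = DrawCircle.",
    fig4_b = "A = .3 B | .7 C. B = SpotSquare. C = SpotCircle.",
    fig4_c = paste("A = B | C | D | E. B = DrawSquare. C = DrawCircle.",
                   "D = DrawTriangle. E = Look."),
    fig5_loop = "A = DrawSquare A.",
    fig5_gated = "A = SpotCircle B. B = DrawSquare A.",
    fig6_turing = paste(
      "b = Pe R Pe R P0 R R P0 L L o.",
      "o = 1 R Px L L L o | 0 q.",
      "q = Any R R q | None P1 L p.",
      "Any = 0 | 1.",
      "p = x E R q | e R f | None L L p.",
      "f = Any R R f | None P0 L L o."),
    fig7_digits = "A = B | C. B = 0 | 1. C = B A.",
    fig7_mixed = "A = B | C. B = SpotSquare | DrawCircle. C = B A.",
    fig8_yellow = "A = B A. B = .5 C | .5 D. C = PrintGreenPoint. D = PrintRedPoint.",
    fig8_orange = "A = B A. B = .61 C | .39 D. C = PrintGreenPoint. D = PrintRedPoint.",
    fig8_gold = "A = B A. B = .54 C | .46 D. C = PrintGreenPoint. D = PrintRedPoint.",
    fig9_simple = "A = PrintGreenPoint.",
    fig9_desc = "A = QuoteA B. B = QuotePrintGreenPoint.",
    fig10_orange = "A = .61 B | .39 C. B = PrintGreenPoint. C = PrintRedPoint.",
    fig10_desc = paste(
      "A = B C D. B = QuoteA E. E = F G. F = QuotePoint61 QuoteB.",
      "G = QuotePoint39 QuoteC. C = QuoteB H. H = QuotePrintGreenPoint.",
      "D = QuoteC I. I = QuotePrintRedPoint."),
    fig11_swarm = paste(
      "A = B | C | D.",
      "B = .5 E | .5 F. E = SpotGreenPoint. F = SpotRedPoint.",
      "C = .6 G | .4 H. G = SpotGreenPoint. H = SpotRedPoint.",
      "D = .9 J | .1 K. J = SpotGreenPoint. K = SpotRedPoint."),
    fig12_reinforce = paste(
      "A = B C. B = .6 D | .4 E. D = SpotGreenPoint. E = SpotRedPoint.",
      "C = F G H. F = QuoteA J. J = K L. K = QuotePoint6 QuoteC.",
      "L = QuotePoint4 QuoteD. G = QuoteC M. M = QuotePrintGreenPoint.",
      "H = QuoteD N. N = QuotePrintRedPoint."),
    fig13_root = paste(
      "A = .5 B | .5 C. B = Symbol D. D = .5 E | .5 F. E = Weight G.",
      "G = .5 Symbol | .5 H. H = Symbol G. F = E D. C = B A."),
    fig14_counter = "A = B C. B = DrawSquare. C = DrawSquare.",
    fig14_metaphor = paste(
      "A = B C D. B = QuoteA E. E = QuoteB QuoteC. C = QuoteB F.",
      "F = UnquoteDrawSquare DrawCircle. D = QuoteC G.",
      "G = UnquoteDrawSquare DrawCircle."),
    fig15_digit = "A = B | C. B = 0 | 1. C = B A.",
    fig15_compose = paste(
      "A = B C D. B = QuoteA E. E = QuoteB QuoteC. C = QuoteB F.",
      "F = Quote0 J. J = Unquote1 K. D = QuoteC G. G = QuoteB H.",
      "H = QuoteA. K = L M N. L = QuoteD O. O = P Q.",
      "P = QuotePoint61 QuoteE. Q = QuotePoint39 QuoteF. M = QuoteE R.",
      "R = QuotePrintGreenPoint. N = QuoteF S. S = QuotePrintRedPoint."),
    fig15_static = paste(
      "A = B | C. B = 0 | D. C = B A.",
      "D = .61 E | .39 F. E = PrintGreenPoint. F = PrintRedPoint."),
    fig15_orange = "A = .61 B | .39 C. B = PrintGreenPoint. C = PrintRedPoint."
  )
}

#' Write the fixture set to disk
#'
#' Writes one plain-text `.arg` file per fixture grammar plus the default
#' terminal registry as `registry.yaml`. Idempotent: repeated calls
#' overwrite with identical content.
#'
#' @param outdir writable directory (created if missing).
#' @return (invisibly) the named list of file paths written.
#' @export
generate_fixtures <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fx <- arg_fixtures()
  paths <- lapply(names(fx), function(nm) {
    p <- file.path(outdir, paste0(nm, ".arg"))
    writeLines(fx[[nm]], p)
    p
  })
  names(paths) <- names(fx)
  reg <- file.path(outdir, "registry.yaml")
  yaml::write_yaml(as.list(arg_registry()), reg)
  paths$registry <- reg
  invisible(paths)
}

#' Read a grammar file
#'
#' Reads a plain-text `.arg` grammar file (UTF-8, the package's notation)
#' and parses it.
#'
#' @param path file path.
#' @param registry terminal registry; either an [arg_registry()]-style named
#'   vector or a path to a YAML map `{terminal: sensor|actuator}`.
#' @export
read_grammar <- function(path, registry = arg_registry()) {
  if (is.character(registry) && length(registry) == 1 && file.exists(registry))
    registry <- unlist(yaml::read_yaml(registry))
  parse_grammar(paste(readLines(path, warn = FALSE), collapse = "\n"),
                registry = registry)
}

#' Write a grammar file
#'
#' @param g grammar.
#' @param path destination `.arg` file.
#' @export
write_grammar <- function(g, path) {
  writeLines(serialize_grammar(g), path)
  invisible(path)
}
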