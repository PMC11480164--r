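# Modal mu-calculus over linear labeled transition systems.
#
# AST nodes are plain lists with an `op` field:
#   tt | ff | var | not | and | or | dia | box | mu | nu
# `dia`/`box` carry an action name or the wildcard "-" (any action).
# `mu`/`nu` carry a bound variable name and a body. The presence/absence
# macros expand to fixpoints but keep a `macro` field so they print back in
# macro form and support witness extraction.

#' Formula constructors
#'
#' Build modal mu-calculus formula ASTs programmatically. `f_presence(a)`
#' expands to `min X . (<a> tt or <-> X)` ("action `a` occurs somewhere along
#' the series") and `f_absence(a)` to its negation; both remember their macro
#' form for printing and witnesses.
#'
#' @param a action name (or `"-"` for any action).
#' @param phi,psi subformulas.
#' @param var bound variable name.
#' @param name variable name.
#' @return a formula AST (list).
#' @name formula-constructors
NULL

#' @rdname formula-constructors
#' @export
f_tt <- function() list(op = "tt")
#' @rdname formula-constructors
#' @export
f_ff <- function() list(op = "ff")
#' @rdname formula-constructors
#' @export
f_var <- function(name) list(op = "var", name = name)
#' @rdname formula-constructors
#' @export
f_not <- function(phi) list(op = "not", phi = phi)
#' @rdname formula-constructors
#' @export
f_and <- function(phi, psi) list(op = "and", lhs = phi, rhs = psi)
#' @rdname formula-constructors
#' @export
f_or <- function(phi, psi) list(op = "or", lhs = phi, rhs = psi)
#' @rdname formula-constructors
#' @export
f_dia <- function(a, phi) list(op = "dia", act = a, phi = phi)
#' @rdname formula-constructors
#' @export
f_box <- function(a, phi) list(op = "box", act = a, phi = phi)
#' @rdname formula-constructors
#' @export
f_mu <- function(var, phi) list(op = "mu", var = var, phi = phi)
#' @rdname formula-constructors
#' @export
f_nu <- function(var, phi) list(op = "nu", var = var, phi = phi)

#' @rdname formula-constructors
#' @export
f_presence <- function(a) {
  node <- f_mu("X", f_or(f_dia(a, f_tt()), f_dia("-", f_var("X"))))
  node$macro <- "presence"; node$act <- a
  node
}

#' @rdname formula-constructors
#' @export
f_absence <- function(a) {
  node <- f_not(f_presence(a))
  node$macro <- "absence"; node$act <- a
  node
}

#' Fold a list of formulas with a binary connective
#' @param phis list of formulas (non-empty).
#' @param f binary constructor, [f_and] or [f_or].
#' @return left-associated combination.
#' @export
f_fold <- function(phis, f = f_or) Reduce(f, phis)

# ---------------------------------------------------------------- parsing --

.token_re <- paste0(
  "(?:\\s+)|",                       # whitespace (dropped)
  "(min|max|not|and|or|tt|ff|presence|absence)(?![A-Za-z0-9_])|",
  "([A-Za-z0-9_]+)|",                # identifier (variable or action)
  "(<|>|\\[|\\]|\\(|\\)|\\.|-)"      # punctuation
)

tokenize_formula <- function(text) {
  toks <- list(); pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(text, regexpr(.token_re, substring(text, pos), perl = TRUE))
    frag <- substring(text, pos)
    hit <- regexpr(.token_re, frag, perl = TRUE)
    if (hit != 1L) stop(sprintf("syntax error at position %d: '%s'",
                                pos, substr(text, pos, pos + 8)))
    lex <- regmatches(frag, hit)
    if (!grepl("^\\s+$", lex)) {
      type <- if (lex %in% c("min", "max", "not", "and", "or", "tt", "ff",
                             "presence", "absence")) "kw"
              else if (grepl("^[A-Za-z0-9_]+$", lex)) "ident"
              else "punct"
      toks[[length(toks) + 1L]] <- list(lex = lex, type = type, pos = pos)
    }
    pos <- pos + nchar(lex)
  }
  toks
}

#' Parse a formula from its concrete syntax
#'
#' Grammar (precedence `not` > `and` > `or`; fixpoint bodies extend as far
#' right as possible; parentheses allowed):
#' \preformatted{phi ::= min X . phi | max X . phi | or-expr
#' or  ::= and ('or' and)*
#' and ::= unary ('and' unary)*
#' unary ::= not unary | <a> unary | [a] unary | atom
#' atom ::= tt | ff | X | presence(a) | absence(a) | ( phi )}
#' where `a` is an action name or the wildcard `-`. The macros expand as
#' `presence(a) == min X . (<a> tt or <-> X)` and
#' `absence(a) == not presence(a)`.
#'
#' Fixpoint bodies must be syntactically monotone: negation may only be
#' applied to closed subformulas. Non-monotone input is rejected with the
#' offending variable named.
#'
#' @param text formula source text.
#' @return a formula AST.
#' @examples
#' parse_formula("presence(mean__high) and not absence(mean__low)")
#' @export
parse_formula <- function(text) {
  toks <- tokenize_formula(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  take <- function(lex = NULL) {
    t <- peek()
    if (is.null(t)) stop("syntax error: unexpected end of input")
    if (!is.null(lex) && t$lex != lex)
      stop(sprintf("syntax error at position %d: expected '%s', saw '%s'",
                   t$pos, lex, t$lex))
    i <<- i + 1L
    t
  }
  parse_action <- function() {
    t <- take()
    if (t$type == "ident" || t$lex == "-") t$lex
    else stop(sprintf("syntax error at position %d: expected action, saw '%s'",
                      t$pos, t$lex))
  }
  parse_phi <- function() {
    t <- peek()
    if (!is.null(t) && t$lex %in% c("min", "max")) {
      op <- take()$lex
      v <- take()
      if (v$type != "ident")
        stop(sprintf("syntax error at position %d: expected variable", v$pos))
      take(".")
      body <- parse_phi()
      if (op == "min") f_mu(v$lex, body) else f_nu(v$lex, body)
    } else parse_or()
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.null(t <- peek()) && t$lex == "or") {
      take(); node <- f_or(node, parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_unary()
    while (!is.null(t <- peek()) && t$lex == "and") {
      take(); node <- f_and(node, parse_unary())
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) stop("syntax error: unexpected end of input")
    if (t$lex == "not") { take(); f_not(parse_unary()) }
    else if (t$lex == "<") {
      take(); a <- parse_action(); take(">"); f_dia(a, parse_unary())
    } else if (t$lex == "[") {
      take(); a <- parse_action(); take("]"); f_box(a, parse_unary())
    } else parse_atom()
  }
  parse_atom <- function() {
    t <- take()
    switch(t$lex,
      tt = f_tt(), ff = f_ff(),
      presence = { take("("); a <- parse_action(); take(")"); f_presence(a) },
      absence  = { take("("); a <- parse_action(); take(")"); f_absence(a) },
      "(" = { node <- parse_phi(); take(")"); node },
      {
        if (t$type != "ident")
          stop(sprintf("syntax error at position %d: unexpected '%s'",
                       t$pos, t$lex))
        f_var(t$lex)
      })
  }
  node <- parse_phi()
  if (!is.null(t <- peek()))
    stop(sprintf("syntax error at position %d: trailing '%s'", t$pos, t$lex))
  check_monotone(node)
  node
}

#' Free variables of a formula
#' @param phi formula AST.
#' @return character vector of free variable names.
#' @export
free_vars <- function(phi) {
  switch(phi$op,
    tt = , ff = character(),
    var = phi$name,
    not = free_vars(phi$phi),
    and = , or = union(free_vars(phi$lhs), free_vars(phi$rhs)),
    dia = , box = free_vars(phi$phi),
    mu = , nu = setdiff(free_vars(phi$phi), phi$var),
    stop("unknown node op: ", phi$op))
}

#' Check syntactic monotonicity
#'
#' Every fixpoint body must be monotone in its bound variable; this is
#' guaranteed by requiring negation to apply only to closed subformulas.
#'
#' @param phi formula AST.
#' @return the formula, invisibly; errors naming the offending variable.
#' @export
check_monotone <- function(phi) {
  walk <- function(node) {
    if (node$op == "not") {
      fv <- free_vars(node$phi)
      if (length(fv))
        stop("non-monotone formula: negation applied to open subformula ",
             "with variable(s) ", paste(fv, collapse = ", "))
    }
    for (child in node[names(node) %in% c("phi", "lhs", "rhs")]) walk(child)
  }
  walk(phi)
  invisible(phi)
}

# ------------------------------------------------------------- formatting --

#' Print a formula in its concrete syntax
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(phi))`
#' reproduces `phi` for any well-formed formula.
#'
#' @param phi formula AST.
#' @return a single string.
#' @export
format_formula <- function(phi) fmt_prec(phi, 0L)

fmt_prec <- function(node, ctx) {
  wrap <- function(s, prec) if (prec < ctx) paste0("(", s, ")") else s
  if (!is.null(node$macro))
    return(wrap(sprintf("%s(%s)", node$macro, node$act), 4L))
  switch(node$op,
    tt = "tt", ff = "ff",
    var = node$name,
    mu  = wrap(sprintf("min %s . %s", node$var, fmt_prec(node$phi, 0L)), 0L),
    nu  = wrap(sprintf("max %s . %s", node$var, fmt_prec(node$phi, 0L)), 0L),
    or  = wrap(paste(fmt_prec(node$lhs, 1L), "or", fmt_prec(node$rhs, 2L)), 1L),
    and = wrap(paste(fmt_prec(node$lhs, 2L), "and", fmt_prec(node$rhs, 3L)), 2L),
    not = wrap(paste("not", fmt_prec(node$phi, 3L)), 3L),
    dia = wrap(sprintf("<%s> %s", node$act, fmt_prec(node$phi, 3L)), 3L),
    box = wrap(sprintf("[%s] %s", node$act, fmt_prec(node$phi, 3L)), 3L),
    stop("unknown node op: ", node$op))
}

# ------------------------------------------------------------- evaluation --

#' Model-check a formula on a patient LTS
#'
#' Standard semantics on the finite state space `0..N`:
#' * `<a> phi` — some `a`-labeled transition leads to a `phi`-state;
#' * `[a] phi` — all `a`-labeled transitions lead to `phi`-states
#'   (vacuously true when there are none);
#' * the wildcard `-` matches any label;
#' * `min`/`max` fixpoints are computed by Kleene iteration from the empty /
#'   full state set; each fixpoint converges in at most `n_states + 1`
#'   body evaluations on this lattice (asserted).
#'
#' @param lts a `patient_lts`.
#' @param formula a closed, monotone formula AST (or its source text).
#' @return an object of class `check_result`: list with `satisfied` (does
#'   the initial state 0 satisfy the formula), `satisfying_states` (integer
#'   vector of 0-based states), `witness` (for satisfied presence-style
#'   formulas, the shortest action prefix reaching the first satisfying
#'   occurrence; otherwise `NULL`) and `iterations` (the largest fixpoint
#'   iteration count, for the termination bound).
#' @examples
#' lts <- structure(list(patient_id = "p", actions = c("a", "b"),
#'                       n_states = 3L), class = "patient_lts")
#' evaluate_formula(lts, "presence(b)")$satisfied
#' @export
evaluate_formula <- function(lts, formula) {
  validate_lts(lts)
  if (is.character(formula)) formula <- parse_formula(formula)
  fv <- free_vars(formula)
  if (length(fv)) stop("free variable(s) at evaluation: ",
                       paste(fv, collapse = ", "))
  check_monotone(formula)
  n <- lts$n_states
  iters <- 0L
  eval_node <- function(node, env) {
    switch(node$op,
      tt  = rep.int(TRUE, n),
      ff  = rep.int(FALSE, n),
      var = env[[node$name]] %||% stop("free variable: ", node$name),
      not = !eval_node(node$phi, env),
      and = eval_node(node$lhs, env) & eval_node(node$rhs, env),
      or  = eval_node(node$lhs, env) | eval_node(node$rhs, env),
      dia = {
        sub <- eval_node(node$phi, env)
        lab <- node$act == "-" | lts$actions == node$act
        c(lab & sub[-1L], FALSE)
      },
      box = {
        sub <- eval_node(node$phi, env)
        lab <- node$act == "-" | lts$actions == node$act
        c(!lab | sub[-1L], TRUE)
      },
      mu  = kleene(node, env, rep.int(FALSE, n)),
      nu  = kleene(node, env, rep.int(TRUE, n)),
      stop("unknown node op: ", node$op))
  }
  kleene <- function(node, env, x) {
    k <- 0L
    repeat {
      env[[node$var]] <- x
      nx <- eval_node(node$phi, env)
      k <- k + 1L
      if (identical(nx, x)) break
      x <- nx
      if (k > n + 1L) stop("fixpoint failed to converge within bound")
    }
    iters <<- max(iters, k)
    x
  }
  sat <- eval_node(formula, list())
  structure(list(satisfied = sat[1L],
                 satisfying_states = which(sat) - 1L,
                 witness = if (sat[1L]) witness_prefix(lts, formula),
                 iterations = iters),
            class = "check_result")
}

#' @export
print.check_result <- function(x, ...) {
  cat("Property", if (x$satisfied) "SATISFIED" else "NOT satisfied",
      sprintf("(%d satisfying states, max fixpoint iterations %d)\n",
              length(x$satisfying_states), x$iterations))
  if (!is.null(x$witness))
    cat("witness prefix:", paste(x$witness, collapse = "."), "\n")
  invisible(x)
}

# Shortest prefix after which a presence-style formula (and/or combinations
# of presence atoms, tt, ff) is satisfied; NULL when the formula has another
# shape or cannot be satisfied. Length-0 prefix means satisfied immediately.
witness_prefix <- function(lts, formula) {
  k <- prefix_len(lts, formula)
  if (is.null(k) || !is.finite(k)) return(NULL)
  lts$actions[seq_len(k)]
}

prefix_len <- function(lts, node) {
  if (!is.null(node$macro) && node$macro == "presence") {
    hit <- if (node$act == "-") 1L else which(lts$actions == node$act)[1]
    return(if (is.na(hit)) Inf else as.numeric(hit))
  }
  switch(node$op,
    tt  = 0,
    ff  = Inf,
    and = {
      a <- prefix_len(lts, node$lhs); b <- prefix_len(lts, node$rhs)
      if (is.null(a) || is.null(b)) NULL else max(a, b)
    },
    or  = {
      a <- prefix_len(lts, node$lhs); b <- prefix_len(lts, node$rhs)
      if (is.null(a) || is.null(b)) NULL else min(a, b)
    },
    NULL)
}
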