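# Independent oracles and random-case generators.
#
# The model-checker oracle deliberately uses different machinery from the
# implementation: the implementation computes global Kleene iterations over
# vectorized state sets, while the oracle walks the unique maximal trace of
# the chain backwards, solving each fixpoint state-by-state (on an acyclic
# chain the value at state i depends only on states >= i, so a single
# backward sweep with a per-state boolean iteration decides it).

make_chain <- function(actions, pid = "p") {
  structure(list(patient_id = pid, actions = actions,
                 n_states = length(actions) + 1L),
            class = "patient_lts")
}

oracle_eval <- function(lts, phi) {
  acts <- lts$actions
  n <- lts$n_states
  # value of `node` at state index i (1-based), env: var -> logical vector
  eval_at <- function(node, i, env) {
    switch(node$op,
      tt  = TRUE, ff = FALSE,
      var = env[[node$name]][i],
      not = !eval_at(node$phi, i, env),
      and = eval_at(node$lhs, i, env) && eval_at(node$rhs, i, env),
      or  = eval_at(node$lhs, i, env) || eval_at(node$rhs, i, env),
      dia = i < n && (node$act == "-" || acts[i] == node$act) &&
              eval_at(node$phi, i + 1L, env),
      box = !(i < n && (node$act == "-" || acts[i] == node$act)) ||
              eval_at(node$phi, i + 1L, env),
      mu  = fix_vec(node, env, FALSE)[i],
      nu  = fix_vec(node, env, TRUE)[i],
      stop("oracle: unknown op ", node$op))
  }
  fix_vec <- function(node, env, init) {
    vec <- rep(init, n)
    for (i in n:1) {
      repeat {
        env2 <- env
        env2[[node$var]] <- vec
        b <- eval_at(node$phi, i, env2)
        if (identical(b, vec[i])) break
        vec[i] <- b
      }
    }
    vec
  }
  vapply(seq_len(n), function(i) eval_at(phi, i, list()), logical(1))
}

# Random linear chain with <= max_len transitions over a small alphabet.
rand_chain <- function(max_len = 30L, alphabet = letters[1:6]) {
  len <- sample(1:max_len, 1)
  make_chain(sample(alphabet, len, replace = TRUE))
}

# Random closed, syntactically monotone formula of bounded depth.
# `not` is only applied to closed subformulas (generated with vars = NULL).
rand_formula <- function(depth, alphabet = letters[1:6], vars = character()) {
  ra <- function() sample(c(alphabet, "-"), 1)
  leaves <- c("tt", "ff", "presence", "absence", if (length(vars)) "var")
  if (depth <= 0L) {
    op <- sample(leaves, 1)
  } else {
    op <- sample(c(leaves, "and", "or", "dia", "box", "not", "mu", "nu"), 1)
  }
  switch(op,
    tt = f_tt(), ff = f_ff(),
    presence = f_presence(ra()), absence = f_absence(ra()),
    var = f_var(sample(vars, 1)),
    and = f_and(rand_formula(depth - 1L, alphabet, vars),
                rand_formula(depth - 1L, alphabet, vars)),
    or  = f_or(rand_formula(depth - 1L, alphabet, vars),
               rand_formula(depth - 1L, alphabet, vars)),
    dia = f_dia(ra(), rand_formula(depth - 1L, alphabet, vars)),
    box = f_box(ra(), rand_formula(depth - 1L, alphabet, vars)),
    not = f_not(rand_formula(depth - 1L, alphabet, character())),
    mu  = { v <- paste0("V", length(vars) + 1L)
            f_mu(v, rand_formula(depth - 1L, alphabet, c(vars, v))) },
    nu  = { v <- paste0("V", length(vars) + 1L)
            f_nu(v, rand_formula(depth - 1L, alphabet, c(vars, v))) })
}

# Brute-force modal level: explicit frequency table, ties to higher ordinal.
oracle_modal <- function(levels) {
  cand <- sort(unique(levels), decreasing = TRUE)
  counts <- vapply(cand, function(l) sum(levels == l), integer(1))
  cand[which.max(counts)]  # which.max takes first = highest ordinal on ties
}

# Brute-force confusion tally: per-patient loop, no vectorized set logic.
oracle_confusion <- function(pred, labels) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    truth <- labels$status[labels$patient_id == pred$patient_id[i]]
    call <- pred$call[i]
    if (call == "MAP" && truth == "MAP") tp <- tp + 1L
    else if (call == "MAP") fp <- fp + 1L
    else if (truth == "MAP") fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
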