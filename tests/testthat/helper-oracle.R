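# Independent oracles. These never call the closed-form risk path they are
# used to check.

# Evidence atoms for one exposure pattern (named integer/NA vector or 1-row
# data frame): known-present exposures become e_* facts, unknown exposures
# become u_* facts, scalar level L asserts the nested e_*_ge1..geL atoms.
pattern_facts <- function(kb, pattern) {
  if (is.data.frame(pattern))
    pattern <- stats::setNames(as.integer(unlist(pattern[1L, , drop = FALSE])),
                               names(pattern))
  facts <- character(0)
  for (f in kb$factors) {
    if (f$kind == "synergy") next
    s <- fallrisk:::slugify(f$name)
    x <- pattern[[f$name]]
    if (is.na(x)) {
      facts <- c(facts, sprintf("u_%s(X)", s))
    } else if (f$kind == "dichotomous") {
      if (x == 1L) facts <- c(facts, sprintf("e_%s(X)", s))
    } else if (x > 0L) {
      facts <- c(facts, sprintf("e_%s_ge%d(X)", s, seq_len(x)))
    }
  }
  facts
}

# Brute-force probability of `query` under the distribution semantics:
# enumerate every outcome combination of the probabilistic rules, forward-
# chain the selected rules plus the facts to a fixpoint, and sum the weights
# of the worlds that entail the query.
lpad_world_prob <- function(program, facts, query = "fall(X)") {
  rules <- program$rules
  # prune rules that can never fire given the facts
  possible <- facts
  repeat {
    grown <- possible
    for (r in rules) if (all(r$body %in% grown)) grown <- union(grown, r$head)
    if (length(grown) == length(possible)) break
    possible <- grown
  }
  live <- Filter(function(r) all(r$body %in% possible), rules)
  if (length(live) == 0L) return(0)
  probs <- vapply(live, function(r) r$annotation, numeric(1))
  coins <- which(probs < 1)
  nc <- length(coins)
  stopifnot(nc <= 20L)  # keep enumeration tractable; models are built small
  nw <- 2L^nc
  sel <- matrix(TRUE, nw, length(live))
  w <- rep(1, nw)
  if (nc > 0L) {
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nc)))
    for (j in seq_len(nc)) {
      sel[, coins[j]] <- grid[, j]
      w <- w * ifelse(grid[, j], probs[coins[j]], 1 - probs[coins[j]])
    }
  }
  atom_names <- unique(c(facts, vapply(live, function(r) r$head, character(1)),
                         unlist(lapply(live, function(r) r$body))))
  truth <- matrix(FALSE, nw, length(atom_names),
                  dimnames = list(NULL, atom_names))
  if (length(facts)) truth[, facts] <- TRUE
  repeat {
    n_true <- sum(truth)
    for (i in seq_along(live)) {
      r <- live[[i]]
      ok <- sel[, i]
      for (b in r$body) ok <- ok & truth[, b]
      truth[, r$head] <- truth[, r$head] | ok
    }
    if (sum(truth) == n_true) break
  }
  if (!query %in% atom_names) return(0)
  sum(w[truth[, query]])
}

# Monte-Carlo route: resolve unknown exposures by sampling them at their
# prevalences, then draw outcomes through the latent-event mechanism.
mc_risk <- function(model, pattern, n_draws, seed) {
  if (is.data.frame(pattern))
    pattern <- stats::setNames(as.integer(unlist(pattern[1L, , drop = FALSE])),
                               names(pattern))
  kb <- model$kb_ref
  set.seed(seed)
  df <- as.data.frame(lapply(names(pattern), function(nm) {
    x <- pattern[[nm]]
    if (!is.na(x)) return(rep(as.integer(x), n_draws))
    f <- fallrisk:::get_factor(kb, nm)
    if (f$kind == "dichotomous") rbinom(n_draws, 1L, f$prevalence)
    else sample(0:f$max_level, n_draws, replace = TRUE, prob = f$level_prevalence)
  }), check.names = FALSE, optional = TRUE)
  names(df) <- names(pattern)
  mean(sample_outcomes(model, df, seed + 1L))
}

# Exhaustive pair-counting AUC (Mann-Whitney oracle).
pair_count_auc <- function(predicted, outcome) {
  pos <- predicted[outcome == 1]; neg <- predicted[outcome == 0]
  num <- 0
  for (x in pos) num <- num + sum(x > neg) + 0.5 * sum(x == neg)
  num / (length(pos) * length(neg))
}
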