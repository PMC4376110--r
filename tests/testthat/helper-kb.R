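# Knowledge-base builders used across the suite.

kb_one_dich <- function(or = 3, p = 0.5, c0 = 0.2, name = "factor a") {
  knowledge_base(list(risk_factor(name, "dichotomous", or, prevalence = p)),
                 baseline_c0 = c0)
}

kb_two_factor_fixture <- function() {
  knowledge_base(list(
    risk_factor("history of falls", "dichotomous", 3, prevalence = 0.5),
    risk_factor("gait problems", "dichotomous", 2, prevalence = 0.25)),
    baseline_c0 = 0.2)
}

# Random small knowledge base with a fixed baseline; mixes all three kinds.
# Scalars capped at 2 levels and synergies at 3 members so the brute-force
# world enumeration stays tractable.
random_kb <- function(seed, max_factors = 6L) {
  set.seed(seed)
  n <- sample.int(max_factors, 1L)
  factors <- list()
  dich_names <- character(0)
  for (i in seq_len(n)) {
    nm <- paste0("f", i)
    kind <- sample(c("dichotomous", "scalar", "synergy"), 1L,
                   prob = c(0.6, 0.25, 0.15))
    if (kind == "synergy" && length(dich_names) < 2L) kind <- "dichotomous"
    if (kind == "dichotomous") {
      factors[[length(factors) + 1L]] <-
        risk_factor(nm, "dichotomous", runif(1, 1, 4),
                    prevalence = runif(1, 0.05, 0.6))
      dich_names <- c(dich_names, nm)
    } else if (kind == "scalar") {
      m <- sample(1:2, 1L)
      lp <- runif(m + 1L); lp <- lp / sum(lp)
      factors[[length(factors) + 1L]] <-
        risk_factor(nm, "scalar", runif(m, 1, 3), max_level = m,
                    level_prevalence = lp)
    } else {
      k <- if (length(dich_names) >= 3L) sample(2:3, 1L) else 2L
      members <- sample(dich_names, k)
      factors[[length(factors) + 1L]] <-
        risk_factor(nm, "synergy", runif(1, 1, 2), members = members)
      dich_names <- setdiff(dich_names, members)  # one synergy set per member
    }
  }
  knowledge_base(factors, baseline_c0 = runif(1, 0.05, 0.4))
}

observable_factors <- function(kb) {
  kinds <- vapply(kb$factors, function(f) f$kind, character(1))
  nms <- vapply(kb$factors, function(f) f$name, character(1))
  nms[kinds != "synergy"]
}

# Every exposure pattern over the observable factors; NA rows are unknowns.
all_exposure_patterns <- function(kb, include_unknown = TRUE) {
  states <- lapply(kb$factors, function(f) {
    if (f$kind == "synergy") return(NULL)
    s <- if (f$kind == "dichotomous") 0:1 else 0:f$max_level
    if (include_unknown) c(s, NA_integer_) else s
  })
  states <- states[!vapply(states, is.null, logical(1))]
  names(states) <- observable_factors(kb)
  out <- expand.grid(states, KEEP.OUT.ATTRS = FALSE)
  names(out) <- observable_factors(kb)
  out
}

# Probability of each fully observed pattern under independent exposures.
pattern_probabilities <- function(kb, patterns) {
  p <- rep(1, nrow(patterns))
  for (f in kb$factors) {
    if (f$kind == "synergy") next
    x <- patterns[[f$name]]
    p <- p * if (f$kind == "dichotomous") ifelse(x == 1, f$prevalence, 1 - f$prevalence)
             else f$level_prevalence[x + 1L]
  }
  p
}

# Exact AUC of the model's own risks against outcomes generated from them,
# from the discrete pattern distribution (independent of any ROC code).
exact_model_auc <- function(kb, model) {
  pat <- all_exposure_patterns(kb, include_unknown = FALSE)
  pi_w <- pattern_probabilities(kb, pat)
  r <- predict_risk(model, pat)
  p1 <- pi_w * r; p0 <- pi_w * (1 - r)
  num <- 0
  for (i in seq_along(r)) {
    num <- num + p1[i] * sum(p0[r < r[i]]) + 0.5 * p1[i] * sum(p0[r == r[i]])
  }
  num / (sum(p1) * sum(p0))
}
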