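#' Convert an odds ratio into a probability contribution
#'
#' The engine's central transform. Under the noisy-OR model with baseline
#' contribution `c0`, a subject exposed to exactly one factor with
#' contribution `C` falls with probability `1 - (1 - c0)(1 - C)`; equating
#' the odds ratio of that probability against the unexposed baseline `c0` to
#' the literature odds ratio and solving for `C` gives
#'
#' \deqn{C = \frac{c_0 (OR - 1)}{1 + c_0 (OR - 1)}.}
#'
#' `C` is 0 exactly when `OR = 1` and increases strictly with `OR`,
#' approaching 1. Odds ratios below 1 (protective factors) have no
#' counterpart in this model and are rejected.
#'
#' @param odds_ratio Numeric vector, each `>= 1`.
#' @param c0 Baseline contribution, strictly in `(0, 1)`.
#' @return Contribution(s) in `[0, 1)`.
#' @seealso [or_from_contribution()], its exact inverse.
#' @export
#' @examples
#' contribution_from_or(3, c0 = 0.2)   # 2/7
contribution_from_or <- function(odds_ratio, c0) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0 || c0 >= 1)
    stop_input("c0 must be strictly between 0 and 1 (got %s)", format(c0))
  if (any(!is.finite(odds_ratio)) || any(odds_ratio < 1))
    stop_input("odds ratios must be finite and >= 1; protective factors are unsupported")
  k <- c0 * (odds_ratio - 1)
  k / (1 + k)
}

#' Recover the odds ratio implied by a contribution
#'
#' Exact inverse of [contribution_from_or()]:
#' `OR = [1 - (1 - c0)(1 - C)] / [c0 (1 - C)]`, i.e. the odds of the
#' one-exposure fall probability over the baseline odds.
#'
#' @param c Contribution(s) in `[0, 1)`.
#' @param c0 Baseline contribution, strictly in `(0, 1)`.
#' @return Odds ratio(s) `>= 1`.
#' @export
or_from_contribution <- function(c, c0) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0 || c0 >= 1)
    stop_input("c0 must be strictly between 0 and 1 (got %s)", format(c0))
  if (any(!is.finite(c)) || any(c < 0) || any(c >= 1))
    stop_input("contributions must lie in [0, 1)")
  (1 - (1 - c0) * (1 - c)) / (c0 * (1 - c))
}

# Model with a given c0 (no calibration); internal building block.
build_model <- function(kb, c0) {
  contribs <- lapply(kb$factors, function(f) contribution_from_or(f$odds_ratios, c0))
  names(contribs) <- factor_names(kb)
  structure(list(c0 = c0, contributions = contribs, kb_ref = kb),
            class = "risk_model")
}

#' Compile a knowledge base into a risk model
#'
#' Fixes the baseline contribution `C0` — either the knowledge base's
#' `baseline_c0` or, when absent, the value calibrated by [calibrate_c0()]
#' so that the model's expected population incidence equals
#' `target_incidence` — and converts every per-factor (per-level) odds ratio
#' into a probability contribution at that `C0`.
#'
#' @param kb A validated [knowledge_base()].
#' @param tolerance Calibration tolerance on the incidence residual.
#' @return A `risk_model`: baseline `c0`, named list `contributions`
#'   (one value per dichotomous factor, one per level for scalar/synergy),
#'   and `kb_ref`, the source knowledge base.
#' @export
#' @examples
#' kb <- knowledge_base(list(
#'   risk_factor("history of falls", "dichotomous", 3, prevalence = 0.5)),
#'   baseline_c0 = 0.2)
#' compile_model(kb)$contributions
compile_model <- function(kb, tolerance = 1e-9) {
  validate_knowledge_base(kb)
  c0 <- kb$baseline_c0 %||% calibrate_c0(kb, tolerance = tolerance)
  build_model(kb, c0)
}

# --- subject profiles -------------------------------------------------------

#' Construct a subject health profile
#'
#' A profile maps factor names to exposure states: for dichotomous factors
#' `"present"`, `"absent"` or `"unknown"` (also accepted: 1/0/`NA`,
#' `TRUE`/`FALSE`); for scalar factors an integer level in `0..max_level` or
#' `"unknown"`/`NA`. Synergy factors carry no direct state — their level is
#' derived from the member factors. Factors not mentioned are treated as
#' unknown (the missing-data case the engine is designed for).
#'
#' @param ... Named states, or a single named list/vector.
#' @return An object of class `subject_profile` (a named list).
#' @export
#' @examples
#' subject_profile("history of falls" = "present", age = 2,
#'                 "vision impairment" = "unknown")
subject_profile <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)))
    args <- as.list(args[[1]])
  if (length(args) && (is.null(names(args)) || any(!nzchar(names(args)))))
    stop_input("all profile entries must be named by factor")
  structure(args, class = "subject_profile")
}

# Normalize one state value to integer (0/1/level) or NA (unknown).
normalize_state <- function(value, f) {
  if (length(value) != 1L) stop_input("factor '%s': state must be a single value", f$name)
  if (is.na(value)) return(NA_integer_)
  if (is.character(value)) {
    v <- tolower(value)
    if (v == "unknown") return(NA_integer_)
    if (f$kind == "dichotomous") {
      if (v == "present") return(1L)
      if (v == "absent") return(0L)
      stop_input("factor '%s': unrecognized state '%s'", f$name, value)
    }
    value <- suppressWarnings(as.numeric(value))
    if (is.na(value)) stop_input("factor '%s': unrecognized state", f$name)
  }
  if (is.logical(value)) value <- as.integer(value)
  v <- as.numeric(value)
  if (v != round(v)) stop_input("factor '%s': state must be an integer level", f$name)
  v <- as.integer(v)
  max_ok <- if (f$kind == "dichotomous") 1L else f$max_level
  if (v < 0L || v > max_ok)
    stop_input("factor '%s': level %d outside 0..%d", f$name, v, max_ok)
  v
}

# Profile -> one-row data.frame over all observable (non-synergy) factors.
profile_to_frame <- function(kb, profile) {
  nms <- factor_names(kb)
  kinds <- vapply(kb$factors, function(f) f$kind, character(1))
  bad <- setdiff(names(profile), nms)
  if (length(bad)) stop_input("unknown factor(s) in profile: %s", paste(bad, collapse = ", "))
  syn_named <- intersect(names(profile), nms[kinds == "synergy"])
  if (length(syn_named))
    stop_input("synergy factor(s) %s take no direct state; set their members instead",
               paste(syn_named, collapse = ", "))
  obs <- nms[kinds != "synergy"]
  row <- lapply(obs, function(nm) {
    if (nm %in% names(profile)) normalize_state(profile[[nm]], get_factor(kb, nm))
    else NA_integer_
  })
  names(row) <- obs
  if (length(row) == 0L) return(as.data.frame(matrix(nrow = 1L, ncol = 0L)))
  as.data.frame(row, check.names = FALSE, optional = TRUE)
}

# --- the noisy-OR computation ----------------------------------------------

# Survival ladder for per-level contributions: surv[l + 1] = prod_{k<=l}(1 - C_k).
level_survival <- function(C) c(1, cumprod(1 - C))

# Joint value of one synergy group for a single member-state pattern:
# expectation, over unknown members at their prevalences, of
# prod_{present members}(1 - C_member) * prod_{k <= level(q)}(1 - C_syn_k),
# with level(q) = max(q - 1, 0). Exact under the model's distribution
# semantics: unknown members couple their own fall rules with the synergy
# level through the same exposure event.
synergy_group_value <- function(states, p_mem, C_mem, syn_surv) {
  unk <- which(is.na(states))
  base_present <- which(!is.na(states) & states == 1L)
  u <- length(unk)
  val <- 0
  for (mask in seq_len(2^u) - 1L) {
    on <- if (u) unk[bitwAnd(mask, bitwShiftL(1L, seq_len(u) - 1L)) > 0L] else integer(0)
    off <- setdiff(unk, on)
    w <- prod(p_mem[on]) * prod(1 - p_mem[off])
    if (w == 0) next
    q <- length(base_present) + length(on)
    lev <- max(q - 1L, 0L)
    val <- val + w * prod(1 - C_mem[c(base_present, on)]) * syn_surv[lev + 1L]
  }
  val
}

# n x n_factors multiplier matrix (synergy columns hold the group residual so
# that row products reproduce the joint value exactly).
multiplier_matrix <- function(model, frame) {
  kb <- model$kb_ref
  nms <- factor_names(kb)
  n <- nrow(frame)
  M <- matrix(1, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  for (f in kb$factors) {
    C <- model$contributions[[f$name]]
    if (f$kind == "dichotomous") {
      x <- frame[[f$name]]
      if (is.null(x)) x <- rep(NA_integer_, n)
      if (any(!is.na(x) & !(x %in% c(0L, 1L))))
        stop_input("factor '%s': dichotomous states must be 0, 1 or NA", f$name)
      if (anyNA(x) && is.null(f$prevalence))
        stop_input("factor '%s': unknown exposure but no prevalence configured", f$name)
      m <- ifelse(is.na(x), 1 - f$prevalence * C, 1 - C * x)
      M[, f$name] <- m
    } else if (f$kind == "scalar") {
      x <- frame[[f$name]]
      if (is.null(x)) x <- rep(NA_integer_, n)
      if (any(!is.na(x) & (x < 0 | x > f$max_level)))
        stop_input("factor '%s': scalar level outside 0..%d", f$name, f$max_level)
      surv <- level_survival(C)
      if (anyNA(x)) {
        if (is.null(f$level_prevalence))
          stop_input("factor '%s': unknown level but no level_prevalence configured", f$name)
        expm <- sum(f$level_prevalence * surv)
      }
      M[, f$name] <- ifelse(is.na(x), if (anyNA(x)) expm else 1, surv[x + 1L])
    } else { # synergy
      mem <- f$members
      p_mem <- vapply(mem, function(nm) get_factor(kb, nm)$prevalence %||% NA_real_, numeric(1))
      C_mem <- vapply(mem, function(nm) model$contributions[[nm]], numeric(1))
      syn_surv <- level_survival(C)
      S <- vapply(mem, function(nm) {
        x <- frame[[nm]]
        if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
      }, integer(n))
      if (n == 1L) S <- matrix(S, nrow = 1L, dimnames = list(NULL, mem))
      if (anyNA(S) && anyNA(p_mem[apply(is.na(S), 2, any)]))
        stop_input("factor '%s': unknown synergy member without prevalence", f$name)
      # group value per unique member-state pattern, divided by the members'
      # own (already applied) marginal multipliers
      key <- apply(S, 1L, paste, collapse = ",")
      for (k in unique(key)) {
        idx <- which(key == k)
        st <- S[idx[1L], ]
        g <- synergy_group_value(st, p_mem, C_mem, syn_surv)
        marg <- prod(ifelse(is.na(st), 1 - p_mem * C_mem, 1 - C_mem * st))
        M[idx, f$name] <- g / marg
      }
    }
  }
  M
}

#' Assess the fall risk of one subject
#'
#' Closed-form noisy-OR combination: the probability of at least one fall in
#' the prediction span is `1 - (1 - c0) * prod(multipliers)`, with one
#' survival multiplier per factor — `(1 - C)` when present, 1 when absent,
#' the prevalence-marginalized expectation when unknown; scalar factors
#' multiply `(1 - C_k)` over all levels up to the subject's; a synergy factor
#' acts as a scalar at level `max(q - 1, 0)` for `q` present members, with
#' unknown members marginalized jointly with their own multipliers (exact
#' under the model's distribution semantics).
#'
#' @param model A compiled `risk_model` (see [compile_model()]).
#' @param profile A [subject_profile()] (or named list); unmentioned factors
#'   are unknown.
#' @return A `risk_assessment`: `probability`, named
#'   `per_factor_multipliers`, and `c0`.
#' @export
#' @examples
#' kb <- knowledge_base(list(
#'   risk_factor("gait problems", "dichotomous", 3, prevalence = 0.5)),
#'   baseline_c0 = 0.2)
#' m <- compile_model(kb)
#' fall_risk(m, subject_profile("gait problems" = "present"))
fall_risk <- function(model, profile = subject_profile()) {
  stopifnot(inherits(model, "risk_model"))
  frame <- profile_to_frame(model$kb_ref, profile)
  M <- multiplier_matrix(model, frame)
  mult <- M[1L, ]
  p <- 1 - (1 - model$c0) * prod(mult)
  structure(list(probability = unname(p),
                 per_factor_multipliers = mult,
                 c0 = model$c0),
            class = "risk_assessment")
}

#' Predict fall risks for a cohort table
#'
#' Vectorized form of [fall_risk()]: `newdata` has one row per subject and
#' one column per observable factor (exact factor names; `NA` = unknown;
#' dichotomous 0/1, scalar level). Columns absent from the table are treated
#' as unknown.
#'
#' @param model A compiled `risk_model`.
#' @param newdata Data frame of exposure states.
#' @return Numeric vector of fall probabilities, one per row.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "risk_model"), is.data.frame(newdata))
  kinds <- vapply(model$kb_ref$factors, function(f) f$kind, character(1))
  obs <- factor_names(model$kb_ref)[kinds != "synergy"]
  bad <- setdiff(names(newdata), c(obs, "outcome", "predicted"))
  if (length(bad)) stop_input("unknown column(s): %s", paste(bad, collapse = ", "))
  M <- multiplier_matrix(model, newdata)
  mult <- rep(1, nrow(M))
  for (j in seq_len(ncol(M))) mult <- mult * M[, j]
  as.numeric(1 - (1 - model$c0) * mult)
}

#' Expected population incidence of a model
#'
#' The mean fall probability over a population with independent exposures at
#' the knowledge-base prevalences, in closed form: every factor enters at its
#' prevalence-weighted expected multiplier (equivalently, the risk of the
#' all-unknown profile — marginalizing an exposure and averaging over it are
#' the same operation).
#'
#' @param model A compiled `risk_model` whose knowledge base carries
#'   prevalences for all factors.
#' @return Expected incidence in `(0, 1)`.
#' @export
expected_incidence <- function(model) {
  fall_risk(model, subject_profile())$probability
}

#' Calibrate the baseline contribution by bisection
#'
#' Solves `expected_incidence(model(c0)) = target_incidence` for `c0` on the
#' bracket `(1e-12, 1 - 1e-12)`. Every contribution increases with `c0`, so
#' the expected incidence is strictly increasing and bisection converges;
#' iteration stops when the incidence residual is within `tolerance`.
#'
#' @param kb A [knowledge_base()] with prevalences for all factors.
#' @param tolerance Absolute tolerance on the incidence residual
#'   (default `1e-9`).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return The calibrated `c0`.
#' @export
#' @examples
#' kb <- knowledge_base(list(), target_incidence = 0.31)
#' calibrate_c0(kb)   # baseline-only: c0 equals the target
calibrate_c0 <- function(kb, tolerance = 1e-9, max_iter = 200L) {
  validate_knowledge_base(kb)
  target <- kb$target_incidence
  obj <- function(c0) expected_incidence(build_model(kb, c0)) - target
  lo <- 1e-12; hi <- 1 - 1e-12
  f_lo <- obj(lo)
  if (f_lo > tolerance)
    stop_numeric("target incidence %.6g is below the minimum achievable risk %.6g",
                 target, f_lo + target)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- obj(mid)
    if (abs(f_mid) <= tolerance) return(mid)
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  stop_numeric("calibration did not converge within %d iterations (residual %.3g)",
               max_iter, obj((lo + hi) / 2))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Noisy-OR fall-risk model: C0 = %.9g, %d factors\n",
              x$c0, length(x$contributions)))
  invisible(x)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Fall risk: %.4f (baseline C0 = %.4f)\n", x$probability, x$c0))
  applied <- x$per_factor_multipliers[x$per_factor_multipliers < 1]
  if (length(applied)) {
    cat("Risk-increasing multipliers:\n")
    for (nm in names(sort(applied)))
      cat(sprintf("  %-36s %.6f\n", nm, applied[[nm]]))
  }
  invisible(x)
}
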