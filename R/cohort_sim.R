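#' Sample exposure profiles from the knowledge-base prevalences
#'
#' Each dichotomous factor is present independently with its prevalence;
#' each scalar level is drawn from its level distribution. This is exactly
#' the population the model's expected incidence and the unknown-exposure
#' marginalization assume.
#'
#' @param kb A [knowledge_base()] with prevalences for all factors.
#' @param n Number of subjects.
#' @param seed Integer seed (required: cohorts must be reproducible).
#' @return Data frame, one row per subject, one column per observable
#'   (non-synergy) factor.
#' @export
sample_exposures <- function(kb, n, seed) {
  validate_knowledge_base(kb)
  stopifnot(n >= 1)
  with_seed(seed, {
    cols <- list()
    for (f in kb$factors) {
      if (f$kind == "synergy") next
      if (f$kind == "dichotomous") {
        if (is.null(f$prevalence))
          stop_input("factor '%s': no prevalence configured, cannot sample", f$name)
        cols[[f$name]] <- stats::rbinom(n, 1L, f$prevalence)
      } else {
        if (is.null(f$level_prevalence))
          stop_input("factor '%s': no level_prevalence configured, cannot sample", f$name)
        cols[[f$name]] <- sample(0:f$max_level, n, replace = TRUE,
                                 prob = f$level_prevalence)
      }
    }
    as.data.frame(cols, check.names = FALSE, optional = TRUE)
  })
}

#' Sample fall outcomes through the latent-event mechanism
#'
#' Outcomes are generated the way the model defines the fall event: one
#' latent baseline event with probability `c0`, one latent event with
#' probability `C` for every active factor rule (each level up to the
#' subject's for scalar factors; synergy levels from the member count), and
#' the outcome is their union. Marginally each outcome is Bernoulli with
#' parameter `fall_risk`, but the mechanism — not the closed form — does
#' the sampling.
#'
#' @param model A compiled `risk_model`.
#' @param profiles Fully observed exposure data frame (no `NA`s), as from
#'   [sample_exposures()].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
sample_outcomes <- function(model, profiles, seed) {
  stopifnot(inherits(model, "risk_model"), is.data.frame(profiles))
  if (anyNA(profiles))
    stop_input("profiles contain unknown exposures; outcomes require fully observed profiles")
  kb <- model$kb_ref
  n <- nrow(profiles)
  with_seed(seed, {
    fell <- stats::rbinom(n, 1L, model$c0)
    for (f in kb$factors) {
      C <- model$contributions[[f$name]]
      active_levels <- function(lev) {
        for (k in seq_along(C)) {
          act <- lev >= k
          if (any(act)) {
            d <- integer(n)
            d[act] <- stats::rbinom(sum(act), 1L, C[k])
            fell <<- pmax(fell, d)
          }
        }
      }
      if (f$kind == "dichotomous") {
        x <- profiles[[f$name]]
        if (is.null(x)) stop_input("profiles lack column '%s'", f$name)
        active_levels(as.integer(x))
      } else if (f$kind == "scalar") {
        active_levels(as.integer(profiles[[f$name]]))
      } else {
        q <- rowSums(as.matrix(profiles[, f$members, drop = FALSE]))
        active_levels(pmax(q - 1L, 0L))
      }
    }
    as.integer(fell)
  })
}

#' Replace observed exposures by unknowns, completely at random
#'
#' @param profiles Exposure data frame.
#' @param rate_per_factor Named numeric vector/list of per-factor missingness
#'   probabilities in `[0, 1]`; unnamed factors keep rate 0. A single
#'   unnamed number applies to every factor.
#' @param seed Integer seed.
#' @return The data frame with entries independently set to `NA`.
#' @export
inject_missingness <- function(profiles, rate_per_factor, seed) {
  stopifnot(is.data.frame(profiles))
  rates <- unlist(rate_per_factor)
  if (length(rates) == 1L && is.null(names(rates)))
    rates <- stats::setNames(rep(rates, ncol(profiles)), names(profiles))
  if (any(!is_probability(rates)))
    stop_input("missingness rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(profiles))
  if (length(bad)) stop_input("missingness rate for unknown factor(s): %s",
                              paste(bad, collapse = ", "))
  with_seed(seed, {
    for (nm in names(rates)) {
      if (rates[[nm]] == 0) next
      hit <- stats::runif(nrow(profiles)) < rates[[nm]]
      profiles[[nm]][hit] <- NA
    }
    profiles
  })
}

#' Simulate a full synthetic cohort
#'
#' Chains [sample_exposures()], [sample_outcomes()] and (optionally)
#' [inject_missingness()] under one seed and records the closed-form true
#' risks, giving every downstream stage — prediction, LPAD equivalence,
#' validation metrics — a cohort whose generating process is exactly the
#' model's own statistical structure.
#'
#' @param model A compiled `risk_model`.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param missingness Optional rates for [inject_missingness()].
#' @return A `simulated_cohort`: `profiles` (true exposures),
#'   `observed_profiles`, `outcomes`, `true_risks`, `seed`.
#' @export
simulate_cohort <- function(model, n, seed, missingness = NULL) {
  kb <- model$kb_ref
  profiles <- sample_exposures(kb, n, seed)
  outcomes <- sample_outcomes(model, profiles, seed + 1L)
  observed <- if (is.null(missingness)) profiles
              else inject_missingness(profiles, missingness, seed + 2L)
  structure(list(profiles = profiles,
                 observed_profiles = observed,
                 outcomes = outcomes,
                 true_risks = predict_risk(model, profiles),
                 seed = seed),
            class = "simulated_cohort")
}

#' Write / read a cohort as CSV (+ metadata sidecar)
#'
#' The CSV has one column per factor (exact factor names, `NA` for unknown)
#' plus an `outcome` column; the seed and any metadata go to a
#' `<path>.meta.json` sidecar so a cohort file is self-describing.
#'
#' @param cohort A `simulated_cohort`, or a data frame already containing an
#'   `outcome` column.
#' @param path CSV output path.
#' @param observed Write the missingness-injected profiles (default) or the
#'   true ones.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, observed = TRUE) {
  if (inherits(cohort, "simulated_cohort")) {
    df <- if (observed) cohort$observed_profiles else cohort$profiles
    df$outcome <- cohort$outcomes
    meta <- list(seed = cohort$seed, n = nrow(df), observed = observed)
  } else {
    df <- cohort
    if (is.null(df$outcome)) stop_input("cohort data frame needs an 'outcome' column")
    meta <- list(n = nrow(df))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_input("cohort file not found: %s", path)
  utils::read.csv(path, check.names = FALSE)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: n = %d, faller fraction %.3f, mean true risk %.3f (seed %d)\n",
              length(x$outcomes), mean(x$outcomes), mean(x$true_risks), x$seed))
  invisible(x)
}
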