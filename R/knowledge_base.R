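#' Define a single risk factor
#'
#' A risk factor is the unit of knowledge the engine consumes: a named
#' condition with literature odds ratio(s), its population prevalence, and a
#' kind that determines how it enters the noisy-OR combination.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{`dichotomous`}{present/absent; one odds ratio, one prevalence.}
#'   \item{`scalar`}{graded exposure at levels `0..max_level`; one odds ratio
#'     per level increment (a single value is replicated across levels, the
#'     usual reading of a per-unit odds ratio) and a prevalence distribution
#'     over the levels.}
#'   \item{`synergy`}{an interaction among a set of dichotomous member
#'     factors. With `q` members present the synergy acts as a scalar factor
#'     at level `max(q - 1, 0)`: extra risk begins only when at least two
#'     members co-occur. Its prevalence is never stored; it derives from the
#'     members' prevalences under independent exposure.}
#' }
#'
#' All odds ratios must be `>= 1`: the contribution transform has no mechanism
#' for protective factors (see [load_knowledge_base()] for the clamping
#' escape hatch).
#'
#' @param name Unique factor name (free text; slugified for LPAD atoms).
#' @param kind One of `"dichotomous"`, `"scalar"`, `"synergy"`.
#' @param odds_ratio Numeric vector of odds ratios, each `>= 1`. Length 1 for
#'   dichotomous; length `max_level` (or 1, replicated) for scalar; length
#'   `S - 1` (or 1, replicated) for a synergy over `S` members.
#' @param prevalence Exposure probability in `[0, 1]` (dichotomous only).
#' @param max_level Maximum exposure level `m >= 1` (scalar only).
#' @param level_prevalence Probability distribution over levels `0..m`,
#'   length `m + 1`, summing to 1 (scalar only).
#' @param members Character vector of member factor names, length `>= 2`
#'   (synergy only).
#' @param reversibility Optional metadata tag: `"surely_reversible"`,
#'   `"subject_specific_reversible"` or `"irreversible"`. Carried, unused by
#'   the risk computation.
#' @param setting Optional metadata tag, e.g. `"community_dwelling"`.
#' @param level_map Optional estimator hook for scalar factors: a list
#'   `list(offset =, scale =)` mapping a raw measurement to a level via
#'   `clamp(floor((value + offset) * scale), 0, max_level)`; see
#'   [map_value_to_level()].
#' @return An object of class `risk_factor`.
#' @seealso [knowledge_base()], [load_knowledge_base()]
#' @export
#' @examples
#' risk_factor("history of falls", "dichotomous", odds_ratio = 2.8,
#'             prevalence = 0.3)
risk_factor <- function(name, kind = c("dichotomous", "scalar", "synergy"),
                        odds_ratio, prevalence = NULL, max_level = NULL,
                        level_prevalence = NULL, members = NULL,
                        reversibility = NULL, setting = NULL,
                        level_map = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("risk factor name must be a non-empty string")
  or <- as.numeric(odds_ratio)
  if (kind == "scalar") {
    if (is.null(max_level) || max_level < 1 || max_level != round(max_level))
      stop_input("factor '%s': scalar factors need a positive integer max_level", name)
    max_level <- as.integer(max_level)
    if (length(or) == 1L) or <- rep(or, max_level)
  }
  if (kind == "synergy") {
    if (is.null(members) || length(members) < 2L)
      stop_input("factor '%s': synergy factors need >= 2 members", name)
    members <- as.character(members)
    max_level <- length(members) - 1L
    if (length(or) == 1L) or <- rep(or, max_level)
  }
  structure(
    list(name = name, kind = kind, odds_ratios = or,
         prevalence = if (!is.null(prevalence)) as.numeric(prevalence),
         max_level = max_level,
         level_prevalence = if (!is.null(level_prevalence)) as.numeric(level_prevalence),
         members = members,
         reversibility = reversibility, setting = setting,
         level_map = level_map),
    class = "risk_factor")
}

#' Assemble a knowledge base
#'
#' A knowledge base bundles the risk-factor specifications with the
#' calibration settings for the baseline contribution `C0`: either a target
#' annual faller incidence (solved for `C0` by bisection at compile time) or
#' a fixed `baseline_c0` that skips calibration.
#'
#' @param factors List of [risk_factor()] objects.
#' @param target_incidence Annual proportion of people with at least one
#'   fall, strictly in `(0, 1)`; the calibration target. Default `0.31`.
#' @param baseline_c0 Optional fixed baseline contribution in `(0, 1)`; when
#'   set, calibration is skipped.
#' @param prediction_span Label for the prediction horizon the odds ratios
#'   and incidence refer to (the engine itself is time-span-agnostic).
#' @param metadata Optional named list carried verbatim (e.g. provenance
#'   notes in the packaged file).
#' @return An object of class `knowledge_base`, already validated.
#' @seealso [validate_knowledge_base()], [compile_model()]
#' @export
knowledge_base <- function(factors = list(), target_incidence = 0.31,
                           baseline_c0 = NULL,
                           prediction_span = "12 months",
                           metadata = NULL) {
  kb <- structure(
    list(schema_version = 1L,
         factors = factors,
         target_incidence = as.numeric(target_incidence),
         baseline_c0 = if (!is.null(baseline_c0)) as.numeric(baseline_c0),
         prediction_span = prediction_span,
         metadata = metadata),
    class = "knowledge_base")
  validate_knowledge_base(kb)
  kb
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: unique names, kind-specific field
#' shapes, odds ratios `>= 1`, probabilities in range, scalar level
#' distributions summing to 1 (tolerance 1e-9), synergy members resolvable,
#' dichotomous, and belonging to at most one synergy set.
#'
#' @param kb A `knowledge_base`.
#' @return `kb`, invisibly, if valid; otherwise an error naming the offending
#'   factor and rule.
#' @export
validate_knowledge_base <- function(kb) {
  if (!inherits(kb, "knowledge_base")) stop_input("not a knowledge_base object")
  ti <- kb$target_incidence
  if (!is.numeric(ti) || length(ti) != 1L || !is.finite(ti) || ti <= 0 || ti >= 1)
    stop_input("target_incidence must be strictly between 0 and 1 (got %s)", format(ti))
  if (!is.null(kb$baseline_c0)) {
    c0 <- kb$baseline_c0
    if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0 || c0 >= 1)
      stop_input("baseline_c0 must be strictly between 0 and 1 (got %s)", format(c0))
  }
  nms <- vapply(kb$factors, function(f) f$name, character(1))
  if (anyDuplicated(nms))
    stop_input("duplicate factor name(s): %s",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  kinds <- vapply(kb$factors, function(f) f$kind, character(1))
  claimed <- character(0)  # members already used by a synergy factor
  for (f in kb$factors) {
    if (any(!is.finite(f$odds_ratios)) || length(f$odds_ratios) == 0L)
      stop_input("factor '%s': odds ratios must be finite numbers", f$name)
    if (any(f$odds_ratios < 1))
      stop_input(paste0("factor '%s': odds ratio %s is < 1; protective factors are ",
                        "unsupported by the contribution transform ",
                        "(use clamp_protective to map them to 1)"),
                 f$name, format(min(f$odds_ratios)))
    switch(f$kind,
      dichotomous = {
        if (length(f$odds_ratios) != 1L)
          stop_input("factor '%s': dichotomous factors take exactly one odds ratio", f$name)
        if (!is.null(f$level_prevalence) || !is.null(f$members))
          stop_input("factor '%s': dichotomous factors cannot carry level_prevalence or members", f$name)
        if (!is.null(f$prevalence) && !is_probability(f$prevalence))
          stop_input("factor '%s': prevalence must be in [0, 1]", f$name)
      },
      scalar = {
        if (length(f$odds_ratios) != f$max_level)
          stop_input("factor '%s': scalar factors need one odds ratio per level (max_level = %d, got %d)",
                     f$name, f$max_level, length(f$odds_ratios))
        lp <- f$level_prevalence
        if (!is.null(lp)) {
          if (length(lp) != f$max_level + 1L)
            stop_input("factor '%s': level_prevalence must have length max_level + 1 = %d",
                       f$name, f$max_level + 1L)
          if (any(!is_probability(lp)))
            stop_input("factor '%s': level_prevalence entries must be in [0, 1]", f$name)
          if (abs(sum(lp) - 1) > 1e-9)
            stop_input("factor '%s': level_prevalence sums to %.12g, not 1 (tolerance 1e-9)",
                       f$name, sum(lp))
        }
      },
      synergy = {
        if (!is.null(f$prevalence))
          stop_input("factor '%s': synergy prevalence is derived from members, never stored", f$name)
        missing <- setdiff(f$members, nms)
        if (length(missing))
          stop_input("factor '%s': synergy member(s) not found in knowledge base: %s",
                     f$name, paste(missing, collapse = ", "))
        mk <- kinds[match(f$members, nms)]
        if (any(mk != "dichotomous"))
          stop_input("factor '%s': synergy members must be dichotomous (offending: %s)",
                     f$name, paste(f$members[mk != "dichotomous"], collapse = ", "))
        dup <- intersect(f$members, claimed)
        if (length(dup))
          stop_input("factor '%s': member(s) %s already belong to another synergy factor",
                     f$name, paste(dup, collapse = ", "))
        claimed <- c(claimed, f$members)
        if (length(f$odds_ratios) != f$max_level)
          stop_input("factor '%s': synergy over %d members needs %d per-level odds ratios (got %d)",
                     f$name, length(f$members), f$max_level, length(f$odds_ratios))
      })
  }
  invisible(kb)
}

factor_names <- function(kb) vapply(kb$factors, function(f) f$name, character(1))

get_factor <- function(kb, name) {
  i <- match(name, factor_names(kb))
  if (is.na(i)) stop_input("unknown factor '%s'", name)
  kb$factors[[i]]
}

#' Read a knowledge base from a YAML/JSON file
#'
#' The file is a single structured document with a `factors` list and a
#' `calibration` block (see the packaged `extdata/default_kb.yaml` for the
#' schema; JSON is a YAML subset and is accepted unchanged).
#'
#' @param path Path to the file.
#' @param clamp_protective If `TRUE`, odds ratios `< 1` are clamped to 1 with
#'   a warning instead of being rejected.
#' @return A validated [knowledge_base()].
#' @export
load_knowledge_base <- function(path, clamp_protective = FALSE) {
  if (!file.exists(path)) stop_input("knowledge base file not found: %s", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_input("cannot parse '%s': %s", path, conditionMessage(e)))
  if (!is.list(doc)) stop_input("'%s': top level must be a mapping", path)
  cal <- doc$calibration %||% list()
  raw_factors <- doc$factors %||% list()
  factors <- lapply(raw_factors, function(rec) {
    if (is.null(rec$name)) stop_input("'%s': a factor record is missing the 'name' key", path)
    if (is.null(rec$kind)) stop_input("'%s': factor '%s' is missing the 'kind' key", path, rec$name)
    or <- rec$odds_ratio %||% rec$odds_ratios
    if (is.null(or)) stop_input("'%s': factor '%s' is missing 'odds_ratio'", path, rec$name)
    or <- unlist(or, use.names = FALSE)
    if (clamp_protective && any(or < 1)) {
      warning(sprintf("factor '%s': clamping %d protective odds ratio(s) to 1",
                      rec$name, sum(or < 1)), call. = FALSE)
      or <- pmax(or, 1)
    }
    risk_factor(name = rec$name, kind = rec$kind, odds_ratio = or,
                prevalence = rec$prevalence,
                max_level = rec$max_level,
                level_prevalence = if (!is.null(rec$level_prevalence))
                  unlist(rec$level_prevalence, use.names = FALSE),
                members = if (!is.null(rec$members))
                  unlist(rec$members, use.names = FALSE),
                reversibility = rec$reversibility, setting = rec$setting,
                level_map = rec$level_map)
  })
  knowledge_base(factors = factors,
                 target_incidence = cal$target_incidence %||% 0.31,
                 baseline_c0 = cal$baseline_c0,
                 prediction_span = doc$prediction_span %||% "12 months",
                 metadata = doc$metadata)
}

#' Write a knowledge base to a YAML file
#'
#' Round-trip safe: [load_knowledge_base()] on the written file reproduces
#' the original object (values written with 17 significant digits).
#'
#' @param kb A validated [knowledge_base()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  validate_knowledge_base(kb)
  recs <- lapply(kb$factors, function(f) {
    rec <- list(name = f$name, kind = f$kind)
    rec$odds_ratio <- if (length(f$odds_ratios) == 1L) f$odds_ratios else as.list(f$odds_ratios)
    if (!is.null(f$prevalence)) rec$prevalence <- f$prevalence
    if (f$kind == "scalar") rec$max_level <- f$max_level
    if (!is.null(f$level_prevalence)) rec$level_prevalence <- as.list(f$level_prevalence)
    if (!is.null(f$members)) rec$members <- as.list(f$members)
    if (!is.null(f$reversibility)) rec$reversibility <- f$reversibility
    if (!is.null(f$setting)) rec$setting <- f$setting
    if (!is.null(f$level_map)) rec$level_map <- f$level_map
    rec
  })
  doc <- list(schema_version = kb$schema_version,
              prediction_span = kb$prediction_span)
  if (!is.null(kb$metadata)) doc$metadata <- kb$metadata
  doc$calibration <- c(list(target_incidence = kb$target_incidence),
                       if (!is.null(kb$baseline_c0)) list(baseline_c0 = kb$baseline_c0))
  doc$factors <- recs
  txt <- yaml::as.yaml(doc, precision = 17L)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) stop_input("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' The packaged default knowledge base
#'
#' The 27 community-dwelling fall-risk factors of the underlying ontology
#' (24 dichotomous, 2 scalar — age and number of medications — and the
#' comorbidity synergy). Odds-ratio and prevalence values in the packaged
#' file are editable placeholders in realistic ranges (the file says so in
#' its `metadata.values_status` key); replace them with values transcribed
#' from a quantitative source before clinical use.
#'
#' @return A validated [knowledge_base()] with 27 factors.
#' @export
#' @examples
#' kb <- default_knowledge_base()
#' table(vapply(kb$factors, function(f) f$kind, character(1)))
default_knowledge_base <- function() {
  path <- system.file("extdata", "default_kb.yaml", package = "fallrisk", mustWork = TRUE)
  load_knowledge_base(path)
}

#' Map a raw measurement to a scalar factor level
#'
#' Estimator hook: applies the factor's configured affine-clamp table,
#' `level = clamp(floor((value + offset) * scale), 0, max_level)`. The
#' mapping is configuration, never hard-coded; factors without a `level_map`
#' reject raw values.
#'
#' @param factor A scalar [risk_factor()] with a `level_map`.
#' @param value Raw measurement (e.g. age in years).
#' @return Integer level in `0..max_level`.
#' @export
map_value_to_level <- function(factor, value) {
  if (factor$kind != "scalar") stop_input("factor '%s' is not scalar", factor$name)
  lm <- factor$level_map
  if (is.null(lm)) stop_input("factor '%s' has no level_map configured", factor$name)
  lev <- floor((value + lm$offset) * lm$scale)
  as.integer(pmin(pmax(lev, 0), factor$max_level))
}

#' @export
print.knowledge_base <- function(x, ...) {
  kinds <- vapply(x$factors, function(f) f$kind, character(1))
  cat(sprintf("Fall-risk knowledge base: %d factors (%d dichotomous, %d scalar, %d synergy)\n",
              length(x$factors), sum(kinds == "dichotomous"),
              sum(kinds == "scalar"), sum(kinds == "synergy")))
  if (is.null(x$baseline_c0))
    cat(sprintf("Calibration: target incidence %.4g over %s\n",
                x$target_incidence, x$prediction_span))
  else
    cat(sprintf("Calibration: fixed baseline C0 = %.6g\n", x$baseline_c0))
  invisible(x)
}

#' @export
print.risk_factor <- function(x, ...) {
  cat(sprintf("<risk_factor> %s (%s), OR = %s\n", x$name, x$kind,
              paste(format(x$odds_ratios), collapse = ", ")))
  invisible(x)
}
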