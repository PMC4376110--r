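#' @name lpad
#' @title Logic programs with annotated disjunctions (LPAD)
#' @description
#' A compiled risk model can be exported as an equivalent probabilistic logic
#' program in cplint-style syntax: rules `head(X) : p :- body.` under the
#' distribution semantics. The program is an output artifact — risk
#' computation always uses the closed form — but the two are provably
#' equivalent (the test suite enumerates rule-outcome worlds of generated
#' programs and checks agreement with [fall_risk()]).
NULL

lpad_rule <- function(head, annotation, body = character(0)) {
  list(head = head, annotation = annotation, body = body)
}

# Annotations are stored at the printed 12-significant-digit precision so the
# rendered text and the rule list are exact round-trip images of each other.
ann_value <- function(p) as.numeric(format_annotation(p))

render_rule <- function(rule) {
  head <- sprintf("%s : %s", rule$head, format_annotation(rule$annotation))
  if (length(rule$body) == 0L) paste0(head, ".")
  else paste0(head, " :- ", paste(rule$body, collapse = ", "), ".")
}

new_lpad_program <- function(rules) {
  for (r in rules)
    if (!is.finite(r$annotation) || r$annotation <= 0 || r$annotation > 1)
      stop_input("LPAD annotation must lie in (0, 1] (rule '%s')", r$head)
  text <- paste0(paste(vapply(rules, render_rule, character(1)), collapse = "\n"), "\n")
  structure(list(rules = rules, text = text), class = "lpad_program")
}

#' Generate the LPAD equivalent of a risk model
#'
#' Emits, in knowledge-base order: the baseline rule `fall(X) : c0.`; for
#' each dichotomous factor a prevalence rule `e_<f>(X) : p :- u_<f>(X).`
#' (active when the exposure is undetermined, i.e. `u_<f>(X)` holds) and a
#' risk rule `fall(X) : C :- e_<f>(X).`; for each scalar factor a chain of
#' conditional-prevalence rules over the nested level atoms
#' `e_<f>_ge<k>(X)` (so an undetermined level reproduces the full level
#' distribution) and one risk rule per level; for each synergy factor
#' deterministic level rules derived from every subset of member exposure
#' atoms (level `>= l` iff at least `l + 1` members present) and one risk
#' rule per level. Rules whose annotation would be exactly 0 (odds ratio 1,
#' prevalence 0) are omitted: they can never affect the query.
#'
#' Factor names are slugified (lowercase, non-alphanumeric runs to `_`) into
#' predicate names. Annotations carry 12 significant digits; generation is
#' deterministic, so identical models yield byte-identical text.
#'
#' @param model A compiled `risk_model`.
#' @return An `lpad_program`: `rules` (list of
#'   `{head, annotation, body}`) and `text` (one rule per line).
#' @seealso [parse_lpad()], [write_lpad()]
#' @export
#' @examples
#' kb <- knowledge_base(list(
#'   risk_factor("gait problems", "dichotomous", 3, prevalence = 0.5)),
#'   baseline_c0 = 0.2)
#' cat(generate_lpad(compile_model(kb))$text)
generate_lpad <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  kb <- model$kb_ref
  rules <- list(lpad_rule("fall(X)", ann_value(model$c0)))
  add <- function(head, p, body = character(0)) {
    if (p > 0) rules[[length(rules) + 1L]] <<- lpad_rule(head, ann_value(p), body)
  }
  for (f in kb$factors) {
    s <- slugify(f$name)
    C <- model$contributions[[f$name]]
    if (f$kind == "dichotomous") {
      if (!is.null(f$prevalence))
        add(sprintf("e_%s(X)", s), f$prevalence, sprintf("u_%s(X)", s))
      add("fall(X)", C, sprintf("e_%s(X)", s))
    } else if (f$kind == "scalar") {
      if (!is.null(f$level_prevalence)) {
        tail_p <- rev(cumsum(rev(f$level_prevalence)))  # P(level >= k), k = 0..m
        for (k in seq_len(f$max_level)) {
          denom <- tail_p[k]          # P(level >= k - 1)
          if (denom <= 0) break
          q <- min(tail_p[k + 1L] / denom, 1)
          body <- if (k == 1L) sprintf("u_%s(X)", s)
                  else c(sprintf("e_%s_ge%d(X)", s, k - 1L), sprintf("u_%s(X)", s))
          add(sprintf("e_%s_ge%d(X)", s, k), q, body)
          if (q == 0) break
        }
      }
      for (k in seq_len(f$max_level))
        add("fall(X)", C[k], sprintf("e_%s_ge%d(X)", s, k))
    } else { # synergy: level >= l iff any l + 1 members jointly present
      mem_atoms <- sprintf("e_%s(X)", vapply(f$members, slugify, character(1)))
      for (l in seq_len(f$max_level)) {
        for (subset in utils::combn(length(mem_atoms), l + 1L, simplify = FALSE))
          add(sprintf("e_%s_ge%d(X)", s, l), 1, mem_atoms[subset])
      }
      for (l in seq_len(f$max_level))
        add("fall(X)", C[l], sprintf("e_%s_ge%d(X)", s, l))
    }
  }
  new_lpad_program(rules)
}

#' Parse an LPAD program text
#'
#' Inverse of the renderer: recovers the rule list from program text in the
#' generated dialect (`head(X) : p.` / `head(X) : p :- b1(X), b2(X).`; blank
#' lines and `%` comments ignored). Annotations are parsed at full printed
#' precision, so `parse_lpad(generate_lpad(m)$text)` reproduces the rule
#' list exactly.
#'
#' @param text A single string (or character vector of lines).
#' @return An `lpad_program`.
#' @export
parse_lpad <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  atom_re <- "[a-z][A-Za-z0-9_]*\\(X\\)"
  rule_re <- sprintf("^\\s*(%s)\\s*:\\s*([0-9.eE+-]+)\\s*(?::-\\s*(%s(?:\\s*,\\s*%s)*))?\\s*\\.\\s*$",
                     atom_re, atom_re, atom_re)
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^\\s*%", ln)) next
    m <- regmatches(ln, regexec(rule_re, ln, perl = TRUE))[[1]]
    if (length(m) == 0L)
      stop_input("LPAD parse error at line %d: %s", i, trimws(ln))
    ann <- suppressWarnings(as.numeric(m[3]))
    if (is.na(ann) || ann <= 0 || ann > 1)
      stop_input("LPAD parse error at line %d: annotation '%s' not in (0, 1]", i, m[3])
    body <- if (nzchar(m[4])) trimws(strsplit(m[4], ",")[[1]]) else character(0)
    rules[[length(rules) + 1L]] <- lpad_rule(m[2], ann, body)
  }
  new_lpad_program(rules)
}

#' Write an LPAD program to a .pl file
#'
#' @param program An `lpad_program`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lpad <- function(program, path) {
  stopifnot(inherits(program, "lpad_program"))
  cat(program$text, file = path)
  invisible(path)
}

#' @export
print.lpad_program <- function(x, ...) {
  cat(sprintf("LPAD program, %d rules:\n", length(x$rules)))
  cat(x$text)
  invisible(x)
}
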