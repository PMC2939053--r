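#' Construct a receptor-class rule
#'
#' A declarative class definition over domain content, corrected
#' transmembrane-helix count and signal-peptide status.  A protein matches
#' when it has at least one hit from EACH required accession group, no hit
#' from the forbidden set, and satisfies the TM and signal-peptide
#' constraints.
#'
#' @param name Unique class name.
#' @param required List of character vectors; each vector is one required
#'   accession group.
#' @param forbidden Character vector of forbidden accessions.
#' @param tm TM-count constraint from [tm_exactly()], [tm_at_least()] or
#'   [tm_any()]; evaluated on corrected helices.
#' @param sp Signal-peptide constraint: `"any"`, `"required"` or
#'   `"forbidden"`.
#' @return A `class_rule` object.
#' @export
class_rule <- function(name, required = list(), forbidden = character(),
                       tm = tm_any(), sp = c("any", "required", "forbidden")) {
  sp <- match.arg(sp)
  required <- lapply(required, as.character)
  if (length(required) == 0L && length(forbidden) == 0L &&
      tm$op == "any" && sp == "any")
    abort("rule '%s' constrains nothing", name)
  structure(list(name = name, required = required,
                 forbidden = as.character(forbidden), tm = tm, sp = sp),
            class = "class_rule")
}

#' TM-count constraints for class rules
#' @param k Helix count.
#' @return Constraint object used by [class_rule()].
#' @export
tm_exactly <- function(k) list(op = "eq", k = as.integer(k))

#' @rdname tm_exactly
#' @export
tm_at_least <- function(k) list(op = "ge", k = as.integer(k))

#' @rdname tm_exactly
#' @export
tm_any <- function() list(op = "any", k = NA_integer_)

#' @export
print.class_rule <- function(x, ...) {
  req <- if (length(x$required)) {
    paste(vapply(x$required, function(g) paste0("{", paste(g, collapse = ","), "}"),
                 character(1)), collapse = " & ")
  } else "-"
  tm <- switch(x$tm$op, any = "any", eq = sprintf("=%d", x$tm$k),
               ge = sprintf(">=%d", x$tm$k))
  cat(sprintf("<class_rule> %s: req %s; forbid {%s}; TM %s; SP %s\n",
              x$name, req, paste(x$forbidden, collapse = ","), tm, x$sp))
  invisible(x)
}

#' Built-in receptor-class rule set
#'
#' The receptor classes used throughout the census.  An LRR protein has at
#' least one hit from the three Pfam LRR families; an LRR-receptor
#' additionally has exactly one (corrected) transmembrane helix.  Toll-like
#' receptors add an intracellular TIR domain (PF01582), LRR-receptor
#' kinases a protein kinase domain (PF07714 or PF00069).  Secreted LRR
#' proteins have a signal peptide and no transmembrane helix.  Further
#' classes cover LRR-containing adenylate/guanylate cyclases (catalytic
#' domain PF00211), NBS-LRR resistance-protein architectures (NB-ARC
#' PF00931 + LRR), NACHT-domain proteins (PF05729) alone and in
#' combination with LRR, STAND proteins (HET + NACHT + WD-repeat), LysM
#' receptor kinases, and single-domain screens for the classical animal
#' pattern-recognition accessory domains (immunoglobulin PF00047, C-type
#' lectin PF00059, TIR PF01582, NOD PF06816, NODP PF07684, ITAM
#' PF02189/PF10538, Pyrin PF02758, CARD PF00619).
#'
#' Pfam does not pin unique accessions for the HET, WD-repeat and LysM
#' domain names; the defaults below are the canonical families and are
#' arguments so users can retarget them.
#'
#' @param lrr_accessions LRR accessions (default [lrr_pfam()]).
#' @param kinase_accessions Protein kinase accessions.
#' @param het_accessions,wd_accessions,lysm_accessions Accessions for the
#'   HET, WD-repeat and LysM domains.
#' @return A named `rule_set` (list of [class_rule()]).
#' @export
#' @examples
#' rules <- builtin_rules()
#' names(rules)
builtin_rules <- function(lrr_accessions = lrr_pfam(),
                          kinase_accessions = c("PF07714", "PF00069"),
                          het_accessions = "PF06985",
                          wd_accessions = "PF00400",
                          lysm_accessions = "PF01476") {
  stopifnot(length(lrr_accessions) > 0L)
  lrr <- list(lrr_accessions)
  rules <- list(
    class_rule("LRR_PROTEIN", required = lrr),
    class_rule("LRR_RECEPTOR", required = lrr, tm = tm_exactly(1)),
    class_rule("TLR", required = c(lrr, list("PF01582")), tm = tm_exactly(1)),
    class_rule("LRR_RK", required = c(lrr, list(kinase_accessions)),
               tm = tm_exactly(1)),
    class_rule("SECRETED_LRR", required = lrr, tm = tm_exactly(0),
               sp = "required"),
    class_rule("LRR_AC", required = c(lrr, list("PF00211"))),
    class_rule("AC_PROTEIN", required = list("PF00211")),
    class_rule("NBS_LRR", required = c(list("PF00931"), lrr)),
    class_rule("NACHT_PROTEIN", required = list("PF05729")),
    class_rule("LRR_NACHT", required = c(lrr, list("PF05729"))),
    class_rule("STAND", required = list(het_accessions, "PF05729",
                                        wd_accessions)),
    class_rule("LYSM_RK", required = list(lysm_accessions, kinase_accessions),
               tm = tm_exactly(1)),
    class_rule("PRR_IG", required = list("PF00047")),
    class_rule("PRR_LECTIN_C", required = list("PF00059")),
    class_rule("PRR_TIR", required = list("PF01582")),
    class_rule("PRR_NOD", required = list("PF06816")),
    class_rule("PRR_NODP", required = list("PF07684")),
    class_rule("PRR_ITAM", required = list(c("PF02189", "PF10538"))),
    class_rule("PRR_PYRIN", required = list("PF02758")),
    class_rule("PRR_CARD", required = list("PF00619"))
  )
  rule_set(rules)
}

#' Bundle class rules into a rule set
#'
#' @param rules List of [class_rule()] objects with unique names.
#' @return A named `rule_set`.
#' @export
rule_set <- function(rules) {
  nm <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    abort("duplicate rule name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(setNames(rules, nm), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d classes: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Serialize a rule set to / from YAML
#'
#' Round-trippable structured-config form so users can add classes without
#' code changes.  TM constraints are encoded as `any`, `eq:k` or `ge:k`.
#'
#' @param rules A `rule_set`.
#' @param path Output (input) file path.
#' @return `write_rules()` the path invisibly; `read_rules()` a `rule_set`.
#' @export
write_rules <- function(rules, path) {
  enc <- lapply(unname(rules), function(r) {
    list(name = r$name,
         required = lapply(r$required, as.list),
         forbidden = as.list(r$forbidden),
         tm = if (r$tm$op == "any") "any" else sprintf("%s:%d", r$tm$op, r$tm$k),
         sp = r$sp)
  })
  write_atomic(function(tmp) yaml::write_yaml(list(classes = enc), tmp), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$classes)) abort("'%s': no 'classes' key", path)
  rule_set(lapply(raw$classes, function(r) {
    tm <- if (identical(r$tm, "any") || is.null(r$tm)) {
      tm_any()
    } else {
      parts <- strsplit(r$tm, ":")[[1L]]
      if (length(parts) != 2L || !parts[[1L]] %in% c("eq", "ge"))
        abort("'%s': bad tm constraint '%s' in rule '%s'", path, r$tm, r$name)
      list(op = parts[[1L]], k = as.integer(parts[[2L]]))
    }
    class_rule(r$name,
               required = lapply(r$required, unlist),
               forbidden = unlist(r$forbidden) %||% character(),
               tm = tm, sp = r$sp %||% "any")
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
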