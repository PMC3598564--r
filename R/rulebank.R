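#' Load a PDDI rulebank
#'
#' Reads and validates a rulebank: the set of potential drug-drug
#' interaction (PDDI) rules the screening engine evaluates, together with a
#' generic-ingredient drug dictionary. The built-in bank encodes 18
#' clinically important interactions, 13 of which are evaluable from
#' dispensing claims (they carry recommended therapeutic alternatives
#' specified a priori); the remaining 5 are education-only: their
#' recommended management (monitoring, dose holds, patient counselling)
#' leaves no footprint in claims.
#'
#' A rule has two disjoint generic-drug sets (`set_a`, the object drug
#' side; `set_b`, the precipitant side), a severity level, management
#' strategies, a map from each interacting drug to its recommended
#' alternatives, and a set of line-of-business codes for which the plan
#' suppresses alerts (the managed Medicaid plan did not alert on the
#' benzodiazepine-azole interaction).
#'
#' @param path Path to a YAML or JSON rule file. `NULL` (default) loads the
#'   built-in bank.
#' @return An object of class `ddi_rulebank`: a list with elements
#'   `rules` (named list of `ddi_rule` objects, ordered by `rule_id`) and
#'   `drugs` (a tibble dictionary with columns `drug_id`, `generic_name`,
#'   `class_tags` (list-column), `maintenance`).
#' @examples
#' bank <- load_rulebank()
#' length(bank$rules)            # 18
#' sum(rule_tbl(bank)$evaluable) # 13
#' @export
load_rulebank <- function(path = NULL) {
  path <- path %||% pddialert_extdata("rulebank.yaml")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules_raw <- raw$rules %||% list()
  if (length(rules_raw) == 0L) {
    warn("rule file contains no rules")
  }
  rules <- lapply(rules_raw, new_ddi_rule)
  ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate rule_id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "pddialert_validation_error")
  }
  rules <- setNames(rules, ids)[order(ids)]
  drugs <- parse_drug_dictionary(raw$drugs %||% list())
  bank <- structure(list(rules = rules, drugs = drugs), class = "ddi_rulebank")
  validate_rulebank(bank)
  bank
}

new_ddi_rule <- function(x) {
  for (f in c("rule_id", "display_name", "set_a", "set_b", "severity", "evaluable")) {
    if (is.null(x[[f]])) {
      abort(sprintf("rule '%s': missing field '%s'",
                    x$rule_id %||% "<unnamed>", f),
            class = "pddialert_validation_error")
    }
  }
  strategies <- lapply(x$strategies %||% list(), function(s) {
    kind <- s$kind %||% abort(sprintf("rule '%s': strategy without kind", x$rule_id),
                              class = "pddialert_validation_error")
    kinds <- c("continue_educate", "modify_dose", "monitor",
               "change_alternative", "hold_discontinue")
    if (!kind %in% kinds) {
      abort(sprintf("rule '%s': unknown strategy kind '%s'", x$rule_id, kind),
            class = "pddialert_validation_error")
    }
    list(kind = kind, text = s$text %||% "")
  })
  alternatives <- lapply(x$alternatives %||% list(),
                         function(a) unique(unlist(a, use.names = FALSE)))
  structure(list(
    rule_id = as.character(x$rule_id),
    display_name = as.character(x$display_name),
    set_a = unique(unlist(x$set_a, use.names = FALSE)),
    set_b = unique(unlist(x$set_b, use.names = FALSE)),
    severity = match.arg(x$severity, c("major", "moderate", "minor")),
    evaluable = isTRUE(x$evaluable),
    strategies = strategies,
    alternatives = alternatives,
    plan_exclusions = unique(unlist(x$plan_exclusions %||% character(),
                                    use.names = FALSE)) %||% character()
  ), class = "ddi_rule")
}

parse_drug_dictionary <- function(drugs_raw) {
  if (length(drugs_raw) == 0L) {
    return(tibble::tibble(drug_id = character(), generic_name = character(),
                          class_tags = list(), maintenance = logical()))
  }
  out <- tibble::tibble(
    drug_id = vapply(drugs_raw, function(d) as.character(d$drug_id), ""),
    generic_name = vapply(drugs_raw, function(d) as.character(d$generic_name), ""),
    class_tags = lapply(drugs_raw, function(d) unlist(d$class_tags, use.names = FALSE) %||% character()),
    maintenance = vapply(drugs_raw, function(d) isTRUE(d$maintenance), NA)
  )
  if (anyDuplicated(out$drug_id)) {
    abort("duplicate drug_id in dictionary", class = "pddialert_validation_error")
  }
  if (any(!nzchar(out$generic_name))) {
    abort("drug dictionary entry with empty generic_name",
          class = "pddialert_validation_error")
  }
  out
}

#' Validate a rulebank
#'
#' Enforces the structural invariants every rule must satisfy: non-empty,
#' disjoint drug sets; evaluable rules carry at least one alternative; no
#' recommended alternative belongs to the rule's own interacting sets; every
#' drug with a change-therapy strategy maps to an alternative; every drug a
#' rule references appears in the dictionary with at least one class tag.
#'
#' @param bank A `ddi_rulebank`.
#' @return The bank, invisibly; errors of class `pddialert_validation_error`
#'   name the offending rule and field.
#' @export
validate_rulebank <- function(bank) {
  stopifnot(inherits(bank, "ddi_rulebank"))
  dict_ids <- bank$drugs$drug_id
  has_tags <- lengths(bank$drugs$class_tags) > 0
  for (rule in bank$rules) {
    id <- rule$rule_id
    fail <- function(field, msg) {
      abort(sprintf("rule '%s', field '%s': %s", id, field, msg),
            class = "pddialert_validation_error")
    }
    if (length(rule$set_a) == 0L) fail("set_a", "empty drug set")
    if (length(rule$set_b) == 0L) fail("set_b", "empty drug set")
    if (length(intersect(rule$set_a, rule$set_b)) > 0L) {
      fail("set_b", "overlaps set_a")
    }
    alts <- unique(unlist(rule$alternatives, use.names = FALSE))
    if (rule$evaluable && length(alts) == 0L) {
      fail("alternatives", "evaluable rule without recommended alternatives")
    }
    both <- union(rule$set_a, rule$set_b)
    if (length(intersect(alts, both)) > 0L) {
      fail("alternatives",
           sprintf("alternative(s) %s belong to the rule's interacting sets",
                   paste(intersect(alts, both), collapse = ", ")))
    }
    if (any(vapply(rule$strategies, function(s) s$kind == "change_alternative", NA)) &&
        length(alts) == 0L) {
      fail("alternatives", "change-therapy strategy but no alternatives")
    }
    referenced <- union(both, alts)
    if (nrow(bank$drugs) > 0L) {
      unknown <- setdiff(referenced, dict_ids)
      if (length(unknown)) {
        fail("drugs", sprintf("not in dictionary: %s", paste(unknown, collapse = ", ")))
      }
      untagged <- referenced[!has_tags[match(referenced, dict_ids)]]
      if (length(untagged)) {
        fail("drugs", sprintf("dictionary entries without class tags: %s",
                              paste(untagged, collapse = ", ")))
      }
    }
  }
  invisible(bank)
}

#' Serialize a rulebank to YAML
#'
#' Inverse of [load_rulebank()]: `load_rulebank(write_rulebank(bank, f))`
#' reproduces `bank` field for field.
#'
#' @param bank A `ddi_rulebank`.
#' @param path Output file path (`.yaml` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_rulebank <- function(bank, path) {
  stopifnot(inherits(bank, "ddi_rulebank"))
  raw <- list(
    rules = lapply(unname(bank$rules), function(r) {
      list(rule_id = r$rule_id, display_name = r$display_name,
           set_a = as.list(r$set_a), set_b = as.list(r$set_b),
           severity = r$severity, evaluable = r$evaluable,
           plan_exclusions = as.list(r$plan_exclusions),
           strategies = r$strategies,
           alternatives = lapply(r$alternatives, as.list))
    }),
    drugs = lapply(seq_len(nrow(bank$drugs)), function(i) {
      list(drug_id = bank$drugs$drug_id[i],
           generic_name = bank$drugs$generic_name[i],
           class_tags = as.list(bank$drugs$class_tags[[i]]),
           maintenance = bank$drugs$maintenance[i])
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' All drug ids a rulebank can reference
#'
#' Union of every rule's interacting sets and recommended alternatives: the
#' superset of ids the detection engine may match or the outcome module may
#' count as a change.
#'
#' @param bank A `ddi_rulebank` (or bare list of `ddi_rule`).
#' @return Character vector of drug ids, sorted.
#' @export
drugs_in_scope <- function(bank) {
  rules <- if (inherits(bank, "ddi_rulebank")) bank$rules else bank
  sort(unique(unlist(lapply(rules, function(r) {
    c(r$set_a, r$set_b, unlist(r$alternatives, use.names = FALSE))
  }), use.names = FALSE)))
}

#' One-row-per-rule summary of a rulebank
#'
#' @param bank A `ddi_rulebank`.
#' @return Tibble with columns `rule_id`, `display_name`, `severity`,
#'   `evaluable`, set sizes, and number of distinct alternatives.
#' @export
rule_tbl <- function(bank) {
  stopifnot(inherits(bank, "ddi_rulebank"))
  tibble::tibble(
    rule_id = vapply(bank$rules, `[[`, "", "rule_id"),
    display_name = vapply(bank$rules, `[[`, "", "display_name"),
    severity = vapply(bank$rules, `[[`, "", "severity"),
    evaluable = vapply(bank$rules, `[[`, NA, "evaluable"),
    n_set_a = lengths(lapply(bank$rules, `[[`, "set_a")),
    n_set_b = lengths(lapply(bank$rules, `[[`, "set_b")),
    n_alternatives = vapply(bank$rules, function(r) {
      length(unique(unlist(r$alternatives, use.names = FALSE)))
    }, 0L)
  )
}

#' Recommended alternatives for the drugs involved in an event
#'
#' The alternatives map is keyed by the interacting drug actually dispensed:
#' for a statin-azole event the recommendation depends on which statin (and
#' which azole) the patient received. This returns the union of the
#' alternatives for the involved drugs.
#'
#' @param rule A `ddi_rule`.
#' @param drug_ids Character vector of involved drug ids (typically the
#'   event's first and second drug).
#' @return Character vector of alternative drug ids (possibly empty).
#' @export
rule_alternatives <- function(rule, drug_ids) {
  stopifnot(inherits(rule, "ddi_rule"))
  unique(unlist(rule$alternatives[intersect(drug_ids, names(rule$alternatives))],
                use.names = FALSE)) %||% character()
}

#' @export
print.ddi_rulebank <- function(x, ...) {
  cat(sprintf("<ddi_rulebank> %d rules (%d evaluable), %d drugs in dictionary\n",
              length(x$rules),
              sum(vapply(x$rules, `[[`, NA, "evaluable")),
              nrow(x$drugs)))
  print(rule_tbl(x), n = length(x$rules))
  invisible(x)
}

#' @export
print.ddi_rule <- function(x, ...) {
  cat(sprintf("<ddi_rule> %s [%s%s]\n  %s  +  %s\n", x$display_name, x$severity,
              if (x$evaluable) "" else ", education-only",
              paste(x$set_a, collapse = ", "), paste(x$set_b, collapse = ", ")))
  invisible(x)
}
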