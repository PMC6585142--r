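#' Define a form item
#'
#' Items are the ordered building blocks of a [form_schema()]. `skip` is a
#' quoted expression over *earlier* item ids; when it evaluates `TRUE` the
#' item is not asked. `compute` marks an engine-calculated field (a function
#' of the answers so far). `range` is a blocking entry constraint;
#' `plausible` is a softer band that produces a non-blocking warning when
#' exceeded (the on-screen "check your response" prompt), distinct from a
#' range violation.
#'
#' @param id Unique item id.
#' @param prompt Display prompt.
#' @param type One of `"text"`, `"numeric"`, `"integer"`, `"date"`,
#'   `"datetime"`, `"choice"`.
#' @param choices Allowed values for `"choice"` items.
#' @param range Length-2 numeric bounds for numeric/integer items.
#' @param plausible Length-2 numeric soft bounds.
#' @param required Must be answered before the form can advance.
#' @param double_entry Second confirmatory entry must match the first.
#' @param skip Quoted expression; `TRUE` skips the item.
#' @param compute Function of the partial answers producing the value.
#' @param needs Item ids a computed field reads; it is filled once all are
#'   answered.
#' @return A list of class `form_item`.
#' @export
form_item <- function(id, prompt = id,
                      type = c("text", "numeric", "integer", "date", "datetime", "choice"),
                      choices = NULL, range = NULL, plausible = NULL,
                      required = TRUE, double_entry = FALSE,
                      skip = NULL, compute = NULL, needs = character()) {
  structure(list(
    id = id, prompt = prompt, type = match.arg(type), choices = choices,
    range = range, plausible = plausible, required = required,
    double_entry = double_entry, skip = skip, compute = compute, needs = needs
  ), class = "form_item")
}

#' Assemble and check a form schema
#'
#' Enforces the structural invariants: unique ids, skip predicates that
#' reference only earlier items, and computed fields whose inputs are
#' resolvable (earlier ids).
#'
#' @param items List of [form_item()] in presentation order.
#' @return A list of class `form_schema`.
#' @export
form_schema <- function(items) {
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate form item id(s)", call. = FALSE)
  for (i in seq_along(items)) {
    sk <- items[[i]]$skip
    if (!is.null(sk)) {
      refs <- all.vars(sk)
      ahead <- setdiff(refs, ids[seq_len(i - 1L)])
      if (length(ahead)) {
        stop("skip predicate of '", ids[i], "' references non-earlier item(s): ",
             paste(ahead, collapse = ", "), call. = FALSE)
      }
    }
    ahead <- setdiff(items[[i]]$needs, ids[seq_len(i - 1L)])
    if (length(ahead)) {
      stop("computed field '", ids[i], "' needs non-earlier item(s): ",
           paste(ahead, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(items = items, ids = ids), class = "form_schema")
}

answer_env <- function(schema, answers) {
  env <- new.env(parent = baseenv())
  for (id in schema$ids) {
    assign(id, if (id %in% names(answers)) answers[[id]] else NA, envir = env)
  }
  env
}

item_skipped <- function(schema, item, answers) {
  if (is.null(item$skip)) return(FALSE)
  isTRUE(eval(item$skip, answer_env(schema, answers)))
}

#' Next item to present
#'
#' Returns the id of the first item, in schema order, that is neither
#' answered nor skipped by its predicate, or `"done"` when no such item
#' remains. Engine-computed items are resolved in passing, so the engine
#' never hands them to the assessor.
#'
#' @param schema A [form_schema()].
#' @param answers Named list of answers so far.
#' @return An item id, or `"done"`.
#' @export
next_item <- function(schema, answers = list()) {
  unknown <- setdiff(names(answers), schema$ids)
  if (length(unknown)) {
    stop("answers reference unknown item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (item in schema$items) {
    if (item$id %in% names(answers)) next
    if (item_skipped(schema, item, answers)) next
    if (!is.null(item$compute)) next  # engine fills these, never asked
    return(item$id)
  }
  "done"
}

#' Validate a single response
#'
#' Applies the blocking constraints (type, choice set, range, double-entry
#' match) and the non-blocking plausibility band. A violation report names
#' the item and the rule so the engine (or a data-entry clerk) can act on
#' it.
#'
#' @param item A [form_item()].
#' @param value The entered value.
#' @param previous_entry For double-entry items, the first entry to match.
#' @return List with `accepted` (logical), `violations` and `warnings`
#'   (data frames with columns `item`, `rule`, `message`).
#' @export
validate_response <- function(item, value, previous_entry = NULL) {
  viol <- list(); warn <- list()
  add <- function(store, rule, message) {
    c(store, list(data.frame(item = item$id, rule = rule, message = message,
                             stringsAsFactors = FALSE)))
  }
  if (item$type %in% c("numeric", "integer")) {
    if (!is.numeric(value) || is.na(value)) {
      viol <- add(viol, "type", "numeric value required")
    } else {
      if (item$type == "integer" && value != round(value)) {
        viol <- add(viol, "type", "whole number required")
      }
      if (!is.null(item$range) && (value < item$range[1] || value > item$range[2])) {
        viol <- add(viol, "range",
                    sprintf("%g outside [%g, %g]", value, item$range[1], item$range[2]))
      } else if (!is.null(item$plausible) &&
                 (value < item$plausible[1] || value > item$plausible[2])) {
        warn <- add(warn, "plausibility",
                    sprintf("%g outside usual range [%g, %g] - please re-check",
                            value, item$plausible[1], item$plausible[2]))
      }
    }
  } else if (item$type == "choice") {
    if (!is.character(value) || length(value) != 1L || !value %in% item$choices) {
      viol <- add(viol, "choice",
                  paste("value must be one of", paste(item$choices, collapse = "/")))
    }
  }
  if (item$double_entry && !is.null(previous_entry) &&
      !isTRUE(all.equal(value, previous_entry))) {
    viol <- add(viol, "double_entry", "entries do not match")
  }
  bindr <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(item = character(), rule = character(), message = character())
  list(accepted = length(viol) == 0L, violations = bindr(viol), warnings = bindr(warn))
}

#' Drive a form to completion
#'
#' Repeatedly asks [next_item()] and obtains answers from `answer_fun(item,
#' answers)`, enforcing constraints the way the guided mobile form does:
#' a rejected response is an error (the app does not advance past it), and
#' computed fields are filled automatically when their section is reached.
#' The result therefore never leaves a required, non-skipped item
#' unanswered -- the structural mechanism behind the mobile arm's complete
#' records.
#'
#' @param schema A [form_schema()].
#' @param answer_fun Function `(item, answers) -> value`.
#' @return Named list of answers (computed fields included; skipped items
#'   absent).
#' @export
run_form <- function(schema, answer_fun) {
  answers <- list()
  items_by_id <- stats::setNames(schema$items, schema$ids)
  fill_computed <- function(answers) {
    for (item in schema$items) {
      if (!is.null(item$compute) && !item$id %in% names(answers) &&
          all(item$needs %in% names(answers)) &&
          !item_skipped(schema, item, answers)) {
        answers[[item$id]] <- item$compute(answers)
      }
    }
    answers
  }
  repeat {
    answers <- fill_computed(answers)
    nid <- next_item(schema, answers)
    if (identical(nid, "done")) break
    item <- items_by_id[[nid]]
    value <- answer_fun(item, answers)
    chk <- validate_response(item, value)
    if (!chk$accepted) {
      stop("response to '", nid, "' rejected: ",
           paste(chk$violations$message, collapse = "; "), call. = FALSE)
    }
    if (item$double_entry) {
      second <- answer_fun(item, answers)
      chk2 <- validate_response(item, second, previous_entry = value)
      if (!chk2$accepted) {
        stop("double entry for '", nid, "' failed: ",
             paste(chk2$violations$message, collapse = "; "), call. = FALSE)
      }
    }
    answers[[nid]] <- value
  }
  fill_computed(answers)
}

#' The bundled newborn assessment form
#'
#' A reconstruction of the guided assessment flow covering every field the
#' completeness audit and the classifier reference: identifiers, birth and
#' assessment datetimes, the LMP date behind the gestational-age
#' auto-calculation, double-entered weights, foot length, temperature, the
#' 60-second breath count, the eight danger-sign observations, the two
#' five-item feeding checklists, and a small-baby-care section that is
#' skipped for infants not classified small. The exact item list and
#' ordering of the original form are not published; this schema is
#' reconstructive and schema-generic code never depends on it.
#'
#' @param config A [classification_config()] supplying the thresholds used
#'   by the computed fields and the small-baby skip rule.
#' @return A [form_schema()].
#' @export
cncp_form_schema <- function(config = classification_config()) {
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  yesno <- c("yes", "no")
  items <- list(
    form_item("infant_id", "Infant ID", "text"),
    form_item("sex", "Sex of infant", "choice",
              choices = c("female", "male", "unrecorded")),
    form_item("birth_datetime", "Date and time of birth", "datetime"),
    form_item("assessment_datetime", "Date and time of this assessment", "datetime"),
    form_item("postnatal_age_days", "Postnatal age (days)", "integer",
              needs = c("birth_datetime", "assessment_datetime"),
              compute = function(a) postnatal_age_days(a$birth_datetime, a$assessment_datetime)),
    form_item("lmp_known", "Does the mother recall her last menstrual period?",
              "choice", choices = yesno),
    form_item("lmp_date", "First day of last menstrual period", "date",
              skip = quote(lmp_known == "no")),
    form_item("ga_weeks", "Gestational age (weeks)", "numeric",
              skip = quote(lmp_known == "no"), needs = c("lmp_date", "birth_datetime"),
              compute = function(a) {
                round_half_up(gestational_age_weeks(a$lmp_date,
                                                    as.Date(a$birth_datetime, tz = "UTC")), 1)
              }),
    form_item("birth_weight_known", "Is the birth weight known?", "choice",
              choices = yesno),
    form_item("birth_weight_g", "Birth weight (g) - enter twice", "numeric",
              range = c(200, 8000), plausible = c(800, 5500), double_entry = TRUE,
              skip = quote(birth_weight_known == "no")),
    form_item("current_weight_g", "Current weight (g) - enter twice", "numeric",
              range = c(200, 8000), plausible = c(800, 5500), double_entry = TRUE),
    form_item("weight_change_pct", "Weight change since birth (%)", "numeric",
              skip = quote(birth_weight_known == "no"),
              needs = c("birth_weight_g", "current_weight_g"),
              compute = function(a) {
                round_half_up(weight_change_percent(a$birth_weight_g, a$current_weight_g), 1)
              }),
    form_item("foot_length_mm", "Foot length (mm)", "numeric",
              range = c(30, 120), plausible = c(55, 95)),
    form_item("temperature_c", "Axillary temperature (degrees C)", "numeric",
              range = c(25, 45), plausible = c(34, 41)),
    form_item("breath_count_60s", "Breaths counted in 60 seconds", "integer",
              range = c(0, 200), plausible = c(20, 120))
  )
  for (nm in sign_names()) {
    items <- c(items, list(
      form_item(paste0("sign_", nm), paste("Danger sign:", gsub("_", " ", nm)),
                "choice", choices = yesno)))
  }
  for (nm in feeding_intolerance_items()) {
    items <- c(items, list(
      form_item(paste0("fi_", nm), paste("Feeding intolerance:", gsub("_", " ", nm)),
                "choice", choices = yesno)))
  }
  for (nm in breastfeeding_items()) {
    items <- c(items, list(
      form_item(paste0("bf_", nm), paste("Breastfeeding:", gsub("_", " ", nm)),
                "choice", choices = yesno)))
  }
  lbw <- config$lbw_threshold_g
  foot_thr <- config$foot_length_threshold_mm
  items <- c(items, list(
    form_item("is_small", "Small infant (auto)", "choice", choices = yesno,
              needs = c("current_weight_g", "foot_length_mm"),
              compute = function(a) {
                bw <- num(a$birth_weight_g); fl <- num(a$foot_length_mm)
                small <- isTRUE(bw < lbw) || isTRUE(fl < foot_thr)
                if (small) "yes" else "no"
              }),
    # small-baby-care section, skipped for non-small infants
    form_item("kmc_counseled", "Kangaroo mother care demonstrated to mother?",
              "choice", choices = yesno, skip = quote(is_small == "no")),
    form_item("skin_to_skin_hours", "Skin-to-skin contact per day (hours)",
              "numeric", range = c(0, 24), skip = quote(is_small == "no"))
  ))
  form_schema(items)
}
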