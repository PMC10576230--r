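#' Participant demographics
#'
#' Self-reported demographics attached to a session. Only the PD status is
#' mandatory (it is the label); every other field may be left unspecified,
#' mirroring a capture form with a "prefer not to answer" option.
#'
#' @param pd_status Logical scalar: self-reported Parkinson disease status.
#' @param age Age in years (18-120) or `NA` for unspecified.
#' @param gender One of `"male"`, `"female"`, `"other"`, `"unspecified"`.
#' @param race One of `"white"`, `"asian"`, `"american_indian_alaska_native"`,
#'   `"other"`, `"unspecified"`.
#' @return A `pd_demographics_record` object.
#' @export
#' @examples
#' demographics(pd_status = TRUE, age = 68, gender = "male")
demographics <- function(pd_status, age = NA, gender = "unspecified",
                         race = "unspecified") {
  if (length(pd_status) != 1L || is.na(pd_status) || !is.logical(pd_status)) {
    rlang::abort("`pd_status` must be TRUE or FALSE (it is the label and cannot be unspecified)")
  }
  if (!is.na(age)) {
    if (!is.numeric(age) || length(age) != 1L || age < 18 || age > 120) {
      rlang::abort("`age` must be in 18-120 years, or NA for unspecified")
    }
    age <- as.integer(age)
  } else {
    age <- NA_integer_
  }
  gender <- rlang::arg_match(gender, c("male", "female", "other", "unspecified"))
  race <- rlang::arg_match(
    race, c("white", "asian", "american_indian_alaska_native", "other", "unspecified")
  )
  structure(
    list(pd_status = pd_status, age = age, gender = gender, race = race),
    class = "pd_demographics_record"
  )
}

#' Mouse tracing trial
#'
#' One tracing trial: the stimulus specification plus the cursor samples the
#' capture client recorded at a fixed interval (500 ms in the reference
#' protocol).
#'
#' @param spec The [path_spec()] traced in this trial.
#' @param samples A data frame with columns `x`, `y` (pixels), `t`
#'   (milliseconds since trial start, strictly increasing from 0) and
#'   `inside` (logical ribbon membership). Coordinates are canonicalized to
#'   2 decimal places and timestamps to integers.
#' @return A `pd_mouse_trial` object.
#' @export
mouse_trial <- function(spec, samples) {
  if (!inherits(spec, "path_spec")) rlang::abort("`spec` must be a path_spec")
  samples <- tibble::as_tibble(samples)
  need <- c("x", "y", "t", "inside")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    rlang::abort(paste0("`samples` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  samples <- tibble::tibble(
    x = round(as.numeric(samples$x), 2),
    y = round(as.numeric(samples$y), 2),
    t = as.integer(round(samples$t)),
    inside = as.logical(samples$inside)
  )
  if (nrow(samples) < 2L) rlang::abort("a mouse trial needs at least 2 samples")
  if (anyNA(samples)) rlang::abort("mouse samples must not contain missing values")
  if (samples$t[1] < 0L) rlang::abort("timestamps must be non-negative")
  if (any(diff(samples$t) <= 0L)) {
    rlang::abort("mouse sample timestamps must be strictly increasing")
  }
  structure(list(spec = spec, samples = samples), class = "pd_mouse_trial")
}

#' Keyboard tapping trial
#'
#' One tapping trial of 10 prompts. A prompt window runs from onset until
#' the prompted key is pressed or the timeout elapses; every press of a
#' different key inside the window is a false press, and a prompt is
#' `resolved` if the prompted key was pressed before timeout.
#'
#' @param level Difficulty level: `"constant"` (one key throughout),
#'   `"alternating"` (two keys, alternating), or `"random"` (a fresh random
#'   key every prompt).
#' @param prompts A data frame with one row per prompt: `prompted_key`
#'   (single character), `resolved` (logical), `response_time` (ms since
#'   prompt onset, `NA` iff unresolved) and `presses` (list column of data
#'   frames with `key` and `t`).
#' @param timeout_ms Prompt window length in milliseconds.
#' @return A `pd_keyboard_trial` object.
#' @export
keyboard_trial <- function(level = c("constant", "alternating", "random"),
                           prompts, timeout_ms = 5000) {
  level <- rlang::arg_match(level)
  prompts <- tibble::as_tibble(prompts)
  need <- c("prompted_key", "resolved", "response_time", "presses")
  miss <- setdiff(need, names(prompts))
  if (length(miss) > 0) {
    rlang::abort(paste0("`prompts` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  prompts <- tibble::tibble(
    prompted_key = as.character(prompts$prompted_key),
    resolved = as.logical(prompts$resolved),
    response_time = as.integer(round(prompts$response_time)),
    presses = lapply(prompts$presses, function(p) {
      if (is.data.frame(p) && identical(names(p), c("key", "t")) &&
          is.character(p$key) && is.integer(p$t)) {
        tibble::new_tibble(list(key = p$key, t = p$t), nrow = nrow(p))
      } else {
        p <- as.data.frame(p)
        tibble::new_tibble(
          list(key = as.character(p$key), t = as.integer(round(p$t))),
          nrow = nrow(p)
        )
      }
    })
  )
  if (any(nchar(prompts$prompted_key) != 1L)) {
    rlang::abort("prompted keys must be single characters")
  }
  bad_rt <- prompts$resolved != !is.na(prompts$response_time)
  if (any(bad_rt)) {
    rlang::abort("`response_time` must be present iff the prompt is resolved")
  }
  if (any(prompts$response_time > timeout_ms, na.rm = TRUE)) {
    rlang::abort("`response_time` cannot exceed the timeout")
  }
  keys <- prompts$prompted_key
  if (level == "constant" && length(unique(keys)) != 1L) {
    rlang::abort("constant level must prompt a single key throughout")
  }
  if (level == "alternating") {
    pair <- unique(keys)
    if (length(pair) != 2L || !all(keys == rep_len(keys[1:2], length(keys)))) {
      rlang::abort("alternating level must alternate between exactly 2 keys")
    }
  }
  structure(
    list(level = level, timeout_ms = as.integer(timeout_ms), prompts = prompts),
    class = "pd_keyboard_trial"
  )
}

#' False presses per prompt
#'
#' Counts, for each prompt of a keyboard trial, the presses whose key differs
#' from the prompted key.
#'
#' @param trial A [keyboard_trial()].
#' @return Integer vector, one count per prompt.
#' @export
false_presses <- function(trial) {
  if (!inherits(trial, "pd_keyboard_trial")) {
    rlang::abort("`trial` must be a keyboard_trial")
  }
  vapply(
    seq_len(nrow(trial$prompts)),
    function(i) sum(trial$prompts$presses[[i]]$key != trial$prompts$prompted_key[i]),
    integer(1)
  )
}

#' Full test session
#'
#' One participant's complete record: demographics, screen geometry, the
#' three mouse trials (line, sine, spiral — in that canonical order) and the
#' three keyboard trials (constant, alternating, random).
#'
#' @param session_id Opaque identifier string.
#' @param demographics A [demographics()] record.
#' @param screen A [screen_geometry()].
#' @param mouse_trials List of exactly 3 [mouse_trial()] objects with shapes
#'   line, sine, spiral in order.
#' @param keyboard_trials List of exactly 3 [keyboard_trial()] objects with
#'   levels constant, alternating, random in order.
#' @return A `pd_session` object.
#' @export
session <- function(session_id, demographics, screen, mouse_trials,
                    keyboard_trials) {
  if (!is.character(session_id) || length(session_id) != 1L || !nzchar(session_id)) {
    rlang::abort("`session_id` must be a non-empty string")
  }
  if (!inherits(demographics, "pd_demographics_record")) {
    rlang::abort("`demographics` must be built with demographics()")
  }
  if (!inherits(screen, "screen_geometry")) {
    rlang::abort("`screen` must be a screen_geometry")
  }
  if (length(mouse_trials) != 3L ||
      !all(vapply(mouse_trials, inherits, logical(1), "pd_mouse_trial"))) {
    rlang::abort("`mouse_trials` must be a list of exactly 3 mouse trials")
  }
  shapes <- vapply(mouse_trials, function(tr) tr$spec$shape, character(1))
  if (!identical(shapes, c("line", "sine", "spiral"))) {
    rlang::abort("mouse trials must be line, sine, spiral in canonical order")
  }
  if (length(keyboard_trials) != 3L ||
      !all(vapply(keyboard_trials, inherits, logical(1), "pd_keyboard_trial"))) {
    rlang::abort("`keyboard_trials` must be a list of exactly 3 keyboard trials")
  }
  levels <- vapply(keyboard_trials, function(tr) tr$level, character(1))
  if (!identical(levels, c("constant", "alternating", "random"))) {
    rlang::abort("keyboard trials must be constant, alternating, random in canonical order")
  }
  names(mouse_trials) <- shapes
  names(keyboard_trials) <- levels
  structure(
    list(
      session_id = session_id, demographics = demographics, screen = screen,
      mouse_trials = mouse_trials, keyboard_trials = keyboard_trials
    ),
    class = "pd_session"
  )
}

#' @export
print.pd_session <- function(x, ...) {
  cat(sprintf(
    "<pd_session> %s | pd_status=%s | screen %dx%d | %d mouse trials, %d keyboard trials\n",
    x$session_id, x$demographics$pd_status, x$screen$width, x$screen$height,
    length(x$mouse_trials), length(x$keyboard_trials)
  ))
  invisible(x)
}

#' Validate a session against the full data-model invariants
#'
#' Re-checks every structural invariant, including the cross-cutting ones a
#' constructor cannot see: each keyboard trial has exactly 10 prompts, and
#' each mouse trial starts within 2 ribbon half-widths of the path start.
#'
#' @param s A `pd_session`.
#' @return `s`, invisibly; aborts with a descriptive message on violation.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "pd_session")) rlang::abort("`s` must be a pd_session")
  for (lv in names(s$keyboard_trials)) {
    n <- nrow(s$keyboard_trials[[lv]]$prompts)
    if (n != 10L) {
      rlang::abort(sprintf("keyboard trial '%s' must have exactly 10 prompts, found %d", lv, n))
    }
  }
  for (sh in names(s$mouse_trials)) {
    tr <- s$mouse_trials[[sh]]
    cl <- instantiate_path(tr$spec, s$screen, n = 256)
    hw <- ribbon_half_width(tr$spec, s$screen)
    d0 <- sqrt((tr$samples$x[1] - cl$x[1])^2 + (tr$samples$y[1] - cl$y[1])^2)
    if (d0 > 2 * hw) {
      rlang::abort(sprintf(
        "mouse trial '%s' starts %.1f px from the path start (limit %.1f px)",
        sh, d0, 2 * hw
      ))
    }
  }
  invisible(s)
}

# ---- JSON serialization -----------------------------------------------------

# Recursively sort named lists by name so serialization is canonical.
sort_keys <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, sort_keys)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
  }
  x
}

spec_to_list <- function(spec) {
  list(
    shape = spec$shape, margin_frac = spec$margin_frac,
    base_y_frac = spec$base_y_frac, amplitude_frac = spec$amplitude_frac,
    n_periods = spec$n_periods, n_turns = spec$n_turns,
    half_width_frac = spec$half_width_frac
  )
}

session_to_list <- function(s) {
  dem <- s$demographics
  list(
    session_id = s$session_id,
    demographics = list(
      pd_status = dem$pd_status,
      age = if (is.na(dem$age)) NULL else dem$age,
      gender = dem$gender, race = dem$race
    ),
    screen = list(width = s$screen$width, height = s$screen$height),
    mouse_trials = lapply(unname(s$mouse_trials), function(tr) {
      list(
        spec = spec_to_list(tr$spec),
        samples = lapply(seq_len(nrow(tr$samples)), function(i) {
          list(
            x = tr$samples$x[i], y = tr$samples$y[i],
            t = tr$samples$t[i], inside = tr$samples$inside[i]
          )
        })
      )
    }),
    keyboard_trials = lapply(unname(s$keyboard_trials), function(tr) {
      list(
        level = tr$level, timeout_ms = tr$timeout_ms,
        prompts = lapply(seq_len(nrow(tr$prompts)), function(i) {
          p <- tr$prompts[i, ]
          list(
            prompted_key = p$prompted_key,
            resolved = p$resolved,
            response_time = if (is.na(p$response_time)) NULL else p$response_time,
            presses = lapply(seq_len(nrow(p$presses[[1]])), function(j) {
              list(key = p$presses[[1]]$key[j], t = p$presses[[1]]$t[j])
            })
          )
        })
      )
    })
  )
}

#' Serialize a session to canonical JSON
#'
#' The serialization is canonical — keys sorted, timestamps integers,
#' coordinates at 2 decimal places, unspecified demographics as `null` — so
#' writing is a fixed point: re-serializing a written session is
#' byte-identical, and `read_session(write_session(s))` equals `s`.
#'
#' @param s A `pd_session`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
write_session <- function(s, path = NULL) {
  if (!inherits(s, "pd_session")) rlang::abort("`s` must be a pd_session")
  txt <- jsonlite::toJSON(
    sort_keys(session_to_list(s)),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# field accessor that aborts with the JSON path of the offending field
json_field <- function(obj, field, path, required = TRUE) {
  if (is.null(obj[[field]])) {
    if (required) {
      rlang::abort(sprintf("schema violation: missing required field at %s.%s", path, field))
    }
    return(NULL)
  }
  obj[[field]]
}

warn_unknown <- function(obj, known, path) {
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    rlang::warn(sprintf(
      "ignoring unknown field(s) at %s: %s", path, paste(extra, collapse = ", ")
    ))
  }
}

parse_spec <- function(obj, path) {
  known <- c("shape", "margin_frac", "base_y_frac", "amplitude_frac",
             "n_periods", "n_turns", "half_width_frac")
  warn_unknown(obj, known, path)
  path_spec(
    shape = json_field(obj, "shape", path),
    margin_frac = json_field(obj, "margin_frac", path),
    base_y_frac = json_field(obj, "base_y_frac", path),
    amplitude_frac = json_field(obj, "amplitude_frac", path),
    n_periods = json_field(obj, "n_periods", path),
    n_turns = json_field(obj, "n_turns", path),
    half_width_frac = json_field(obj, "half_width_frac", path)
  )
}

#' Read and validate a session from JSON
#'
#' Parses a session-log JSON document (a file path or a JSON string) and
#' enforces every data-model invariant. Schema violations abort with the
#' JSON path of the offending field; unknown fields are ignored with a
#' warning.
#'
#' @param input Path to a JSON file, or a JSON string.
#' @return A validated `pd_session`.
#' @export
read_session <- function(input) {
  txt <- if (length(input) == 1L && !grepl("^\\s*\\{", input) && file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "\n")
  } else {
    paste(input, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  session_from_list(doc)
}

session_from_list <- function(doc) {
  warn_unknown(doc, c("session_id", "demographics", "screen",
                      "mouse_trials", "keyboard_trials"), "$")
  dem_obj <- json_field(doc, "demographics", "$")
  warn_unknown(dem_obj, c("pd_status", "age", "gender", "race"), "demographics")
  dem <- demographics(
    pd_status = json_field(dem_obj, "pd_status", "demographics"),
    age = dem_obj$age %||% NA,
    gender = dem_obj$gender %||% "unspecified",
    race = dem_obj$race %||% "unspecified"
  )
  scr_obj <- json_field(doc, "screen", "$")
  scr <- screen_geometry(
    json_field(scr_obj, "width", "screen"),
    json_field(scr_obj, "height", "screen")
  )
  mt_objs <- json_field(doc, "mouse_trials", "$")
  if (length(mt_objs) != 3L) {
    rlang::abort(sprintf(
      "schema violation at mouse_trials: expected exactly 3 trials, found %d",
      length(mt_objs)
    ))
  }
  mts <- lapply(seq_along(mt_objs), function(i) {
    path <- sprintf("mouse_trials[%d]", i)
    obj <- mt_objs[[i]]
    warn_unknown(obj, c("spec", "samples"), path)
    spec <- parse_spec(json_field(obj, "spec", path), paste0(path, ".spec"))
    rows <- json_field(obj, "samples", path)
    samples <- tibble::tibble(
      x = vapply(rows, function(r) as.numeric(json_field(r, "x", path)), numeric(1)),
      y = vapply(rows, function(r) as.numeric(json_field(r, "y", path)), numeric(1)),
      t = vapply(rows, function(r) as.numeric(json_field(r, "t", path)), numeric(1)),
      inside = vapply(rows, function(r) as.logical(json_field(r, "inside", path)), logical(1))
    )
    if (any(diff(samples$t) <= 0)) {
      rlang::abort(sprintf("schema violation at %s.samples: timestamps must be strictly increasing", path))
    }
    mouse_trial(spec, samples)
  })
  kt_objs <- json_field(doc, "keyboard_trials", "$")
  if (length(kt_objs) != 3L) {
    rlang::abort(sprintf(
      "schema violation at keyboard_trials: expected exactly 3 trials, found %d",
      length(kt_objs)
    ))
  }
  kts <- lapply(seq_along(kt_objs), function(i) {
    path <- sprintf("keyboard_trials[%d]", i)
    obj <- kt_objs[[i]]
    warn_unknown(obj, c("level", "timeout_ms", "prompts"), path)
    rows <- json_field(obj, "prompts", path)
    prompts <- tibble::tibble(
      prompted_key = vapply(rows, function(r) as.character(json_field(r, "prompted_key", path)), character(1)),
      resolved = vapply(rows, function(r) as.logical(json_field(r, "resolved", path)), logical(1)),
      response_time = vapply(rows, function(r) {
        v <- r$response_time
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1)),
      presses = lapply(rows, function(r) {
        ps <- json_field(r, "presses", path)
        tibble::tibble(
          key = vapply(ps, function(p) as.character(json_field(p, "key", path)), character(1)),
          t = vapply(ps, function(p) as.numeric(json_field(p, "t", path)), numeric(1))
        )
      })
    )
    keyboard_trial(
      level = json_field(obj, "level", path),
      prompts = prompts,
      timeout_ms = obj$timeout_ms %||% 5000
    )
  })
  s <- session(
    session_id = json_field(doc, "session_id", "$"),
    demographics = dem, screen = scr,
    mouse_trials = mts, keyboard_trials = kts
  )
  validate_session(s)
  s
}

#' Write a cohort as newline-delimited JSON
#'
#' @param cohort List of `pd_session` objects.
#' @param path Output file path (one canonical JSON document per line).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, write_session, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from newline-delimited JSON
#'
#' @param path File with one session JSON document per line.
#' @return List of validated `pd_session` objects, classed `pd_cohort`.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  structure(lapply(lines, read_session), class = "pd_cohort")
}

#' Recompute ribbon-membership flags from geometry
#'
#' The capture client may have judged inside/outside itself; this recomputes
#' every `inside` flag from the trial's stimulus geometry, making the
#' pipeline robust to either convention. The number of flags changed is
#' attached as attribute `"flags_changed"`. The operation is idempotent.
#'
#' @param s A `pd_session`.
#' @param metric Membership convention passed to [is_inside_ribbon()].
#' @return The session with recomputed flags and attribute `"flags_changed"`.
#' @export
recompute_inside_flags <- function(s, metric = c("band", "euclidean")) {
  metric <- rlang::arg_match(metric)
  if (!inherits(s, "pd_session")) rlang::abort("`s` must be a pd_session")
  changed <- 0L
  for (sh in names(s$mouse_trials)) {
    tr <- s$mouse_trials[[sh]]
    new_inside <- is_inside_ribbon(tr$samples$x, tr$samples$y, tr$spec, s$screen,
                                   metric = metric)
    changed <- changed + sum(new_inside != tr$samples$inside)
    s$mouse_trials[[sh]]$samples$inside <- new_inside
  }
  attr(s, "flags_changed") <- changed
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
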