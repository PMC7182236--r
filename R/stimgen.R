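#' Define an FPVS experiment design
#'
#' An experiment design fixes the rapid-serial-visual-presentation (RSVP)
#' timing and the factorial condition structure: faces are shown at
#' `stimulation_rate` Hz in triplets, and in regular conditions the first
#' face of every triplet carries one designated expression, so that
#' expression recurs at the regularity rate `stimulation_rate /
#' regularity_divisor`.
#'
#' @param stimulation_rate Face presentation rate in Hz.
#' @param trial_duration RSVP duration per trial in seconds. Must contain
#'   a whole number of triplets.
#' @param regularity_divisor Cycles per regularity period (3: every third
#'   face is the regular one).
#' @param refresh_rate Display refresh rate in frames per second; must be
#'   divisible by `stimulation_rate`.
#' @param orientations,regularities,variabilities Factor levels crossed
#'   into the condition cells. `regularities` may contain expression
#'   categories (regular conditions) and `"irregular"`; `variabilities`
#'   is `"none"` when identity variability is not manipulated.
#' @param trials_per_condition Trials per condition cell.
#' @param expressions Expression categories available in the stream.
#' @param filler_only Expressions that may never occupy a regular
#'   (triplet-first) position.
#' @param identities Named list mapping each variability level to its
#'   identity pool; a single-identity pool means every cycle of a trial
#'   shows that identity.
#' @param target_policy `NULL` (passive viewing) or a list with
#'   `target_trials_per_condition`, `max_targets_per_trial`,
#'   `min_target_interval` (msec, onset to onset) and
#'   `target_duration_frames`.
#' @return An object of class `fpvs_spec`.
#' @seealso [preset_spec()] for the four built-in designs.
#' @export
experiment_spec <- function(stimulation_rate, trial_duration,
                            regularity_divisor = 3, refresh_rate = 60,
                            orientations = c("upright", "inverted"),
                            regularities = c("angry", "neutral", "irregular"),
                            variabilities = "none",
                            trials_per_condition = 1,
                            expressions = c("angry", "neutral", "happy"),
                            filler_only = "happy",
                            identities = list(none = "id01"),
                            target_policy = NULL) {
  n_cycles <- stimulation_rate * trial_duration
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    abort("`stimulation_rate * trial_duration` must be a whole number of cycles.",
          class = "fpvs_config_error")
  }
  if (round(n_cycles) %% regularity_divisor != 0) {
    abort("`trial_duration` must hold a whole number of triplets.",
          class = "fpvs_config_error")
  }
  if (abs(refresh_rate / stimulation_rate -
          round(refresh_rate / stimulation_rate)) > 1e-9) {
    abort("`refresh_rate` must be divisible by `stimulation_rate`.",
          class = "fpvs_config_error")
  }
  regular_set <- setdiff(expressions, filler_only)
  bad_reg <- setdiff(setdiff(regularities, "irregular"), regular_set)
  if (length(bad_reg)) {
    abort(paste0("Regularity level(s) not permitted as regular expressions: ",
                 paste(bad_reg, collapse = ", ")), class = "fpvs_config_error")
  }
  missing_ids <- setdiff(variabilities, names(identities))
  if (length(missing_ids)) {
    abort(paste0("No identity pool for variability level(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "fpvs_config_error")
  }
  conditions <- tidyr::expand_grid(orientation = orientations,
                                   regularity = regularities,
                                   variability = variabilities)
  conditions$condition <- condition_label(conditions)
  if (nrow(conditions) == 0) {
    abort("Design has zero conditions.", class = "fpvs_config_error")
  }
  if (!is.null(target_policy)) {
    need <- c("target_trials_per_condition", "max_targets_per_trial",
              "min_target_interval", "target_duration_frames")
    if (!all(need %in% names(target_policy))) {
      abort("`target_policy` is missing required fields.",
            class = "fpvs_config_error")
    }
    if (target_policy$target_trials_per_condition > trials_per_condition) {
      abort("More target trials requested than trials per condition.",
            class = "fpvs_config_error")
    }
  }
  structure(
    list(stimulation_rate = stimulation_rate,
         regularity_rate = stimulation_rate / regularity_divisor,
         regularity_divisor = regularity_divisor,
         trial_duration = trial_duration,
         refresh_rate = refresh_rate,
         conditions = conditions,
         trials_per_condition = trials_per_condition,
         expressions = expressions,
         filler_only = filler_only,
         regular_set = regular_set,
         identities = identities,
         target_policy = target_policy),
    class = "fpvs_spec")
}

condition_label <- function(cells) {
  lab <- paste(cells$orientation, cells$regularity, sep = ".")
  ifelse(cells$variability == "none", lab,
         paste(lab, cells$variability, sep = "."))
}

#' @export
print.fpvs_spec <- function(x, ...) {
  cat(sprintf("<fpvs_spec> %g Hz stream, %g Hz regularity, %g s trials\n",
              x$stimulation_rate, x$regularity_rate, x$trial_duration))
  cat(sprintf("  %d conditions x %d trials; expressions: %s\n",
              nrow(x$conditions), x$trials_per_condition,
              paste(x$expressions, collapse = ", ")))
  if (is.null(x$target_policy)) cat("  passive viewing (no targets)\n")
  else cat(sprintf("  targets: %d trials/condition, min interval %g ms\n",
                   x$target_policy$target_trials_per_condition,
                   x$target_policy$min_target_interval))
  invisible(x)
}

#' Built-in experiment presets
#'
#' Loads one of the four shipped designs: `pilot1` (15 Hz stream, 5 Hz
#' regularity, 3.8 s trials, 9 identities, 96 trials in each of 6
#' conditions), `pilot2` (as pilot1 but one identity per trial crossed as
#' a high/low expression-dissimilarity factor, 48 trials in each of 12
#' cells), `exp1` (6 Hz stream, 2 Hz regularity, 7 s trials, 800 ms
#' minimum target interval) and `exp2` (as exp1, passive viewing, 30
#' trials per cell, i.e. 60 per orientation-by-regularity condition).
#'
#' @param name One of `"pilot1"`, `"pilot2"`, `"exp1"`, `"exp2"`.
#' @param path Optional path to a YAML preset file with the same layout
#'   as the shipped `presets.yaml`.
#' @return An [experiment_spec()] object.
#' @examples
#' preset_spec("pilot1")
#' @export
preset_spec <- function(name, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "presets.yaml", package = "fpvs",
                        mustWork = TRUE)
  }
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets)) {
    abort(paste0("Unknown preset '", name, "'. Available: ",
                 paste(names(presets), collapse = ", ")),
          class = "fpvs_config_error")
  }
  p <- presets[[name]]
  experiment_spec(
    stimulation_rate = p$stimulation_rate,
    trial_duration = p$trial_duration,
    regularity_divisor = p$regularity_divisor,
    refresh_rate = p$refresh_rate,
    orientations = unlist(p$orientations),
    regularities = unlist(p$regularities),
    variabilities = unlist(p$variabilities),
    trials_per_condition = p$trials_per_condition,
    expressions = unlist(p$expressions),
    filler_only = unlist(p$filler_only),
    identities = lapply(p$identities, unlist),
    target_policy = p$target_policy
  )
}

# Balanced draw of `k` distinct categories per triplet: always take the
# categories with the largest remaining quota, random tie-break.
draw_balanced <- function(counts, k) {
  ord <- order(counts + runif(length(counts)) * 0.5, decreasing = TRUE)
  ord[seq_len(k)]
}

#' Build one stimulus sequence
#'
#' Generates the ordered cycle entries (identity, expression, orientation)
#' for a single trial of the given condition. In regular conditions every
#' triplet-first cycle carries the regular expression and the two filler
#' positions are balanced over the remaining categories; in irregular
#' conditions each triplet holds three distinct categories in random
#' order. Filler-only expressions (happy, disgusted) never occupy a
#' triplet-first position. When several identities are available, no
#' identity-plus-expression token of one triplet recurs in the next.
#'
#' @param condition A one-row tibble or named list with `orientation`,
#'   `regularity` and `variability`.
#' @param spec An [experiment_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `cycle`, `triplet`, `position`,
#'   `identity`, `expression`, `orientation`; the condition cell and the
#'   (initially empty) target onsets are attached as attributes.
#' @examples
#' sq <- build_sequence(list(orientation = "upright", regularity = "angry",
#'                           variability = "none"),
#'                      preset_spec("pilot1"), seed = 1)
#' nrow(sq)  # 57 cycles = 15 Hz x 3.8 s
#' @export
build_sequence <- function(condition, spec, seed = NULL) {
  cond <- as.list(condition)[c("orientation", "regularity", "variability")]
  if (anyNA(match(condition_label(as_tibble(cond)), spec$conditions$condition))) {
    abort(paste0("Condition not in design: ", condition_label(as_tibble(cond))),
          class = "fpvs_config_error")
  }
  with_seed(seed, {
    n_cycles <- as.integer(round(spec$stimulation_rate * spec$trial_duration))
    n_trip <- n_cycles %/% spec$regularity_divisor
    d <- spec$regularity_divisor
    exprs <- spec$expressions
    regular_ok <- spec$regular_set

    expression <- character(n_cycles)
    if (cond$regularity != "irregular") {
      fillers <- setdiff(exprs, cond$regularity)
      quota <- setNames(rep(0, length(fillers)), fillers)
      # even split of the (d-1) * n_trip filler slots over filler categories
      for (t in seq_len(n_trip)) {
        pick <- fillers[draw_balanced(-quota, d - 1)]
        quota[pick] <- quota[pick] + 1
        expression[(t - 1) * d + 1] <- cond$regularity
        expression[(t - 1) * d + 1 + seq_len(d - 1)] <- sample(pick)
      }
    } else {
      omit_quota <- setNames(rep(0, length(exprs)), exprs)
      for (t in seq_len(n_trip)) {
        if (length(exprs) > d) {
          # drop categories so that omissions stay balanced, but keep at
          # least one regular-capable category for the first position
          repeat {
            omit <- exprs[draw_balanced(-omit_quota, length(exprs) - d)]
            cats <- setdiff(exprs, omit)
            if (any(cats %in% regular_ok)) break
          }
          omit_quota[omit] <- omit_quota[omit] + 1
        } else {
          cats <- exprs
        }
        first <- sample(intersect(cats, regular_ok), 1)
        expression[(t - 1) * d + 1] <- first
        expression[(t - 1) * d + 1 + seq_len(d - 1)] <- sample(setdiff(cats, first))
      }
    }

    ids <- spec$identities[[cond$variability]]
    identity <- character(n_cycles)
    if (length(ids) == 1L) {
      identity[] <- ids
    } else {
      prev_tokens <- character(0)
      for (t in seq_len(n_trip)) {
        idx <- (t - 1) * d + seq_len(d)
        cur_tokens <- character(0)
        for (i in idx) {
          cand <- ids[!paste(ids, expression[i]) %in% c(prev_tokens, cur_tokens)]
          if (!length(cand)) cand <- ids  # degenerate pools: constraint waived
          identity[i] <- if (length(cand) == 1L) cand else sample(cand, 1)
          cur_tokens <- c(cur_tokens, paste(identity[i], expression[i]))
        }
        prev_tokens <- cur_tokens
      }
    }

    out <- tibble(
      cycle = seq_len(n_cycles),
      triplet = rep(seq_len(n_trip), each = d),
      position = rep(seq_len(d), n_trip),
      identity = identity,
      expression = expression,
      orientation = cond$orientation
    )
    attr(out, "condition") <- cond
    attr(out, "target_onsets") <- numeric(0)
    class(out) <- c("fpvs_sequence", class(out))
    out
  })
}

#' Build a full session plan
#'
#' Generates `trials_per_condition` sequences for every condition cell and
#' randomizes their order. The result is a nested tibble: one row per
#' trial with the condition factors, the cycle table as a list column and
#' the (initially empty) target onsets.
#'
#' @inheritParams build_sequence
#' @param seed Optional integer seed; the same seed reproduces the plan
#'   exactly.
#' @return A tibble of class `fpvs_plan` with columns `trial`,
#'   `orientation`, `regularity`, `variability`, `condition`, `cycles`
#'   (list of tibbles) and `targets` (list of numeric onset vectors, ms).
#' @examples
#' plan <- build_session_plan(preset_spec("pilot1"), seed = 1)
#' nrow(plan)  # 576
#' @export
build_session_plan <- function(spec, seed = NULL) {
  cells <- spec$conditions
  if (nrow(cells) == 0) abort("Design has zero conditions.",
                              class = "fpvs_config_error")
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(cells)), function(i) {
      purrr::map(seq_len(spec$trials_per_condition), function(j) {
        sq <- build_sequence(cells[i, ], spec)
        tibble(orientation = cells$orientation[i],
               regularity = cells$regularity[i],
               variability = cells$variability[i],
               condition = cells$condition[i],
               cycles = list(sq), targets = list(numeric(0)))
      })
    })
    plan <- dplyr::bind_rows(purrr::list_flatten(rows))
    plan <- plan[sample.int(nrow(plan)), ]
    plan <- dplyr::mutate(plan, trial = dplyr::row_number(), .before = 1)
    class(plan) <- c("fpvs_plan", class(plan))
    attr(plan, "spec") <- spec
    plan
  })
}

#' Schedule detection targets onto a session plan
#'
#' Marks the configured number of trials per condition as target trials
#' and draws 1 to `max_targets_per_trial` onset times per target trial,
#' uniformly over all frame-aligned placements that keep consecutive
#' onsets at least `min_target_interval` ms apart and the whole target
#' inside the RSVP window. With no target policy (passive viewing) the
#' plan is returned unchanged.
#'
#' @param plan A plan from [build_session_plan()].
#' @param spec The [experiment_spec()] used to build it.
#' @param seed Optional integer seed.
#' @return The plan with the `targets` list column filled (onsets in ms
#'   from RSVP onset) and a logical `target_trial` column.
#' @export
schedule_targets <- function(plan, spec, seed = NULL) {
  pol <- spec$target_policy
  if (is.null(pol)) {
    plan$target_trial <- FALSE
    return(plan)
  }
  frame_ms <- 1000 / spec$refresh_rate
  n_frames <- as.integer(round(spec$trial_duration * 1000 / frame_ms))
  n_onset <- n_frames - pol$target_duration_frames + 1L  # onset frames 0-based
  s <- as.integer(ceiling(pol$min_target_interval / frame_ms))
  k_max_feasible <- 1L + (n_onset - 1L) %/% s
  if (k_max_feasible < 1L) {
    abort(sprintf(
      "Target scheduling infeasible: %g ms interval does not fit a %g s trial.",
      pol$min_target_interval, spec$trial_duration),
      class = "fpvs_scheduling_error")
  }
  k_cap <- min(pol$max_targets_per_trial, k_max_feasible)
  with_seed(seed, {
    plan$target_trial <- FALSE
    for (cell in unique(plan$condition)) {
      idx <- which(plan$condition == cell)
      chosen <- sample(idx, pol$target_trials_per_condition)
      plan$target_trial[chosen] <- TRUE
      for (i in chosen) {
        k <- sample.int(k_cap, 1)
        # uniform draw over frame sets with all onset gaps >= s frames
        y <- sort(sample.int(n_onset - (k - 1L) * (s - 1L), k)) - 1L
        frames <- y + (seq_len(k) - 1L) * (s - 1L)
        plan$targets[[i]] <- frames * frame_ms
      }
    }
    plan
  })
}

#' NTSC luminance of an RGB triplet
#'
#' The effective luminance of a pixel under the standard NTSC grayscale
#' conversion, `0.2989 R + 0.5870 G + 0.1140 B`, unrounded.
#'
#' @param red,green,blue Channel values in `[0, 255]` (vectorized).
#' @return Numeric luminance values.
#' @examples
#' rgb_to_luminance(128, 128, 196)  # the turquoise target dot
#' @export
rgb_to_luminance <- function(red, green, blue) {
  v <- c(red, green, blue)
  if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 255)) {
    abort("RGB channels must be numeric in [0, 255].",
          class = "fpvs_validation_error")
  }
  0.2989 * red + 0.5870 * green + 0.1140 * blue
}

#' Flatten a session plan to one row per cycle
#'
#' @param plan An `fpvs_plan`.
#' @return A tibble with trial, condition factors, cycle-level columns and
#'   the trial's target onsets collapsed into a `;`-separated string.
#' @export
plan_to_table <- function(plan) {
  flat <- dplyr::mutate(as_tibble(plan),
                        target_onsets = purrr::map_chr(
                          .data$targets,
                          ~ paste(format(.x, trim = TRUE), collapse = ";")),
                        targets = NULL,
                        orientation = NULL)  # kept per cycle
  dplyr::mutate(
    tidyr::unnest(flat, "cycles"),
    target_onsets = dplyr::if_else(.data$target_onsets == "", NA_character_,
                                   .data$target_onsets))
}

#' Write a session plan to TSV and/or JSON
#'
#' @param plan An `fpvs_plan`.
#' @param tsv,json Output paths (either may be `NULL`).
#' @return The plan, invisibly.
#' @export
write_session_plan <- function(plan, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(plan_to_table(plan), tsv)
  if (!is.null(json)) {
    obj <- purrr::map(seq_len(nrow(plan)), function(i) {
      list(trial = plan$trial[i], condition = plan$condition[i],
           orientation = plan$orientation[i], regularity = plan$regularity[i],
           variability = plan$variability[i],
           targets_ms = plan$targets[[i]],
           cycles = as.data.frame(plan$cycles[[i]][
             c("cycle", "identity", "expression", "orientation")]))
    })
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(plan)
}

# All within-trial consecutive target-onset gaps of a plan, in ms,
# rounded to the nanosecond to undo float error in the frame-to-ms
# conversion (gaps are exact frame multiples by construction).
target_gaps <- function(plan) {
  g <- unlist(purrr::map(plan$targets, function(x) if (length(x) > 1) diff(x)))
  round(g * 1e6) / 1e6
}
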