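# Wheelchair Skills Test (WST) scoring: the 15-skill capacity sheet, the
# 0/1/2 scale, and the total-capacity percentage
# (100 * sum of scores / (2 * number of skills)).

WST_SKILLS <- data.frame(
  skill_id = 1:15,
  skill_name = c(
    "Rolls forward 10 m",
    "Rolls backward 5 m",
    "Turns 90 degrees by moving forward",
    "Turns 90 degrees by moving backward",
    "Turns 180 degrees in place",
    "Maneuvers sideways",
    "Gets through gate",
    "Rolls 100 m",
    "Avoids moving obstacles",
    "Ascends small ramp",
    "Descends small ramp",
    "Ascends long curved ramp",
    "Descends long curved ramp",
    "Rolls 2 m across side-slope",
    "Rolls 2 m on uneven surface"
  ),
  stringsAsFactors = FALSE
)

#' The 15 Wheelchair Skills Test skills used for capacity scoring
#'
#' @return a data frame with columns `skill_id` (1–15) and `skill_name`.
#' @export
wst_skills <- function() WST_SKILLS

#' Validate a raw score list into a skill sheet
#'
#' The capacity scale scores each skill 2 (pass: completed safely and
#' without difficulty), 1 (pass with difficulty: collisions, excessive time
#' or effort) or 0 (fail: aborted as unsafe). A valid sheet holds exactly
#' one score per skill.
#'
#' @param scores integer vector of exactly 15 values, each 0, 1 or 2,
#'   ordered by skill id.
#' @param interface_label which input method produced the scores
#'   (free text, e.g. `"head"` or `"voice"`).
#' @param subject_label free-text subject identifier.
#' @return a `wst_sheet` object: the skill table with a `score` column plus
#'   label attributes.
#' @export
#' @examples
#' validate_sheet(rep(2, 15), interface_label = "head")
validate_sheet <- function(scores, interface_label = "",
                           subject_label = "") {
  n_skills <- nrow(WST_SKILLS)
  if (length(scores) != n_skills) {
    hf_stop(sprintf("expected %d skill scores, got %d",
                    n_skills, length(scores)), "hf_validation_error")
  }
  bad <- which(!(scores %in% c(0, 1, 2)))
  if (length(bad) > 0) {
    hf_stop(sprintf("skill %d ('%s') has score %s; scores must be 0, 1 or 2",
                    bad[1], WST_SKILLS$skill_name[bad[1]],
                    format(scores[bad[1]])),
            "hf_validation_error")
  }
  sheet <- cbind(WST_SKILLS, data.frame(score = as.integer(scores)))
  structure(sheet, class = c("wst_sheet", "data.frame"),
            interface_label = interface_label,
            subject_label = subject_label)
}

# Truncate (toward zero) to one decimal, matching how the printed capacity
# totals are reported (26/30 -> 86.6, not 86.7).
truncate_one_decimal <- function(x) trunc(x * 10) / 10

#' Total WST capacity percentage
#'
#' Capacity is the sum of the individual skill scores divided by twice the
#' number of skills (the maximum attainable sum), as a percentage: with the
#' 15-skill sheet, `100 * sum(scores) / 30`. The displayed value truncates
#' to one decimal; the exact value is retained alongside.
#'
#' @param sheet a [validate_sheet()] result.
#' @return a `capacity_result` list with elements `percent` (exact),
#'   `display` (one-decimal string), `sum_scores` and `n_skills`.
#' @export
#' @examples
#' total_capacity(validate_sheet(c(2,2,2,1,2,1,2,2,2,2,2,2,2,2,2)))
total_capacity <- function(sheet) {
  stopifnot(inherits(sheet, "wst_sheet"))
  n_skills <- nrow(sheet)
  s <- sum(sheet$score)
  percent <- 100 * s / (2 * n_skills)
  structure(
    list(percent = percent,
         display = sprintf("%.1f", truncate_one_decimal(percent)),
         sum_scores = s, n_skills = n_skills,
         interface_label = attr(sheet, "interface_label"),
         subject_label = attr(sheet, "subject_label")),
    class = "capacity_result"
  )
}

#' @export
print.capacity_result <- function(x, ...) {
  lab <- paste(c(x$subject_label, x$interface_label)[
    nzchar(c(x$subject_label, x$interface_label))], collapse = ", ")
  cat(sprintf("Total WST capacity: %s%% (%d/%d points%s)\n",
              x$display, x$sum_scores, 2 * x$n_skills,
              if (nzchar(lab)) paste0("; ", lab) else ""))
  invisible(x)
}

#' Side-by-side comparison of skill sheets
#'
#' Lays out several sheets' per-skill scores in parallel columns, one per
#' sheet, with each sheet's total capacity attached, so different input
#' interfaces (or subjects) can be compared skill by skill.
#'
#' @param sheets a list of [validate_sheet()] results sharing the skill
#'   list. Columns are named from each sheet's subject/interface labels
#'   (falling back to `sheet1`, `sheet2`, ...).
#' @return a data frame with columns `skill_id`, `skill_name` and one score
#'   column per sheet, ordered by skill id, with a `totals` attribute (named
#'   numeric vector of exact capacity percentages) and a `totals_display`
#'   attribute (one-decimal strings).
#' @export
compare_interfaces <- function(sheets) {
  if (length(sheets) == 0) {
    out <- WST_SKILLS[0, ]
    attr(out, "totals") <- numeric(0)
    attr(out, "totals_display") <- character(0)
    return(out)
  }
  for (s in sheets) {
    if (!inherits(s, "wst_sheet")) {
      hf_stop("all elements must be validated skill sheets",
              "hf_validation_error")
    }
    if (!identical(s$skill_name, WST_SKILLS$skill_name)) {
      hf_stop("sheets do not share the same skill list", "hf_validation_error")
    }
  }
  labels <- vapply(seq_along(sheets), function(i) {
    lab <- paste(c(attr(sheets[[i]], "subject_label"),
                   attr(sheets[[i]], "interface_label"))[
      nzchar(c(attr(sheets[[i]], "subject_label"),
               attr(sheets[[i]], "interface_label")))], collapse = "_")
    if (nzchar(lab)) lab else sprintf("sheet%d", i)
  }, character(1))
  labels <- make.unique(labels)
  out <- WST_SKILLS
  for (i in seq_along(sheets)) out[[labels[i]]] <- sheets[[i]]$score
  caps <- vapply(sheets, function(s) total_capacity(s)$percent, numeric(1))
  names(caps) <- labels
  attr(out, "totals") <- caps
  attr(out, "totals_display") <-
    stats::setNames(sprintf("%.1f", truncate_one_decimal(caps)), labels)
  out
}

#' Read a skill sheet from CSV
#'
#' Expects columns `skill_id`, `skill_name`, `score` (the layout written by
#' [write_sheet_csv()]); `skill_name` is optional and, when present, only
#' checked for order.
#'
#' @param path CSV file path.
#' @param interface_label,subject_label labels to attach.
#' @return a `wst_sheet`.
#' @export
read_sheet_csv <- function(path, interface_label = "", subject_label = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("skill_id", "score") %in% names(df))) {
    hf_stop("sheet CSV needs columns skill_id, score", "hf_shape_error")
  }
  df <- df[order(df$skill_id), ]
  if (!identical(as.integer(df$skill_id), WST_SKILLS$skill_id)) {
    hf_stop("sheet CSV must contain skill ids 1 through 15 exactly once",
            "hf_validation_error")
  }
  validate_sheet(df$score, interface_label = interface_label,
                 subject_label = subject_label)
}

#' Write a skill sheet to CSV
#'
#' @param sheet a `wst_sheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sheet_csv <- function(sheet, path) {
  stopifnot(inherits(sheet, "wst_sheet"))
  utils::write.csv(as.data.frame(sheet)[, c("skill_id", "skill_name",
                                            "score")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load the published example skill sheets bundled with the package
#'
#' Four reference capacity sheets (two subjects x head/voice interfaces)
#' shipped as plain-text CSVs, used by the examples and the reproduction
#' script.
#'
#' @return a named list of `wst_sheet` objects
#'   (`volunteerA_head`, `volunteerA_voice`, `volunteerB_head`,
#'   `volunteerB_voice`).
#' @export
example_sheets <- function() {
  dir <- system.file("extdata", "wst", package = "handsfree")
  names <- c("volunteerA_head", "volunteerA_voice",
             "volunteerB_head", "volunteerB_voice")
  out <- lapply(names, function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    read_sheet_csv(file.path(dir, paste0(nm, ".csv")),
                   interface_label = parts[2], subject_label = parts[1])
  })
  stats::setNames(out, names)
}
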